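## Readers and writers for the plain-text formats the toolkit touches:
## FASTA ortholog clusters, Newick trees, and TSV locus tables.

VALID_BASES <- c("A", "C", "G", "T", "N", "-")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct an ortholog cluster
#'
#' An ortholog cluster holds one coding sequence per sample under a shared
#' cluster identifier. Sequences are stored as uppercase DNA strings over
#' `A,C,G,T,N,-`; sample identifiers must be unique, non-empty and free of
#' whitespace.
#'
#' @param cluster_id single string naming the cluster.
#' @param sequences named character vector, names are sample identifiers.
#' @return An object of class `ortho_cluster`: a list with elements
#'   `cluster_id` and `seq` (the named sequence vector).
#' @export
ortho_cluster <- function(cluster_id, sequences) {
  stopifnot(is.character(cluster_id), length(cluster_id) == 1L)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || any(grepl("\\s", ids)))
    stop("sample identifiers must be non-empty tokens without whitespace")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample identifier in cluster '%s': %s",
                 cluster_id, ids[duplicated(ids)][1L]))
  if (any(!nzchar(sequences)))
    stop(sprintf("empty sequence in cluster '%s'", cluster_id))
  bad <- grepl(sprintf("[^%s]", paste(VALID_BASES, collapse = "")), sequences)
  if (any(bad))
    stop(sprintf("sequence '%s' contains characters outside A,C,G,T,N,-",
                 ids[bad][1L]))
  structure(list(cluster_id = cluster_id, seq = sequences),
            class = "ortho_cluster")
}

#' @export
print.ortho_cluster <- function(x, ...) {
  cat(sprintf("ortho_cluster '%s': %d sequences (lengths %s)\n",
              x$cluster_id, length(x$seq),
              paste(range(nchar(x$seq)), collapse = "-")))
  invisible(x)
}

#' Number of sequences in a cluster
#' @param x an `ortho_cluster`.
#' @export
length.ortho_cluster <- function(x) length(x$seq)

normalize_dna <- function(s, where = "sequence") {
  s <- toupper(s)
  s <- gsub("U", "T", s, fixed = TRUE)
  has_ambig <- grepl(paste0("[", paste(IUPAC_AMBIG, collapse = ""), "]"), s)
  if (any(has_ambig)) {
    warning(sprintf("%s: IUPAC ambiguity codes mapped to N", where),
            call. = FALSE)
    s <- chartr(paste(IUPAC_AMBIG, collapse = ""),
                strrep("N", length(IUPAC_AMBIG)), s)
  }
  s
}

#' Read an ortholog cluster from a FASTA file
#'
#' Headers start with `>`; the token up to the first whitespace is the sample
#' identifier (any remainder is discarded). Sequences are uppercased, `U` is
#' mapped to `T`, and IUPAC ambiguity codes are mapped to `N` with a warning
#' (downstream filters treat any ambiguity as missing data). Any other
#' character raises an error naming the offending line.
#'
#' @param path FASTA file; the file stem becomes the cluster id.
#' @param cluster_id optional override for the cluster id.
#' @return An [ortho_cluster()].
#' @export
read_fasta <- function(path, cluster_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("empty FASTA file: %s", path))
  if (is.null(cluster_id))
    cluster_id <- sub("\\.(fa|fasta|fna|ffn)(\\.gz)?$", "",
                      basename(path), ignore.case = TRUE)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) stop(sprintf("%s: first line is not a FASTA header", path))
  idx <- cumsum(is_header)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_header]))
  if (any(!nzchar(ids)))
    stop(sprintf("%s: empty sample identifier in header", path))
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate sample identifier '%s'",
                 path, ids[duplicated(ids)][1L]))
  body <- lines
  body[is_header] <- ""
  ## validate per line so errors can point at the original file line;
  ## '-' placed last in the class so it cannot form a range
  allowed <- paste0("ACGTN", paste(IUPAC_AMBIG, collapse = ""), "[:space:]-")
  for (i in which(!is_header)) {
    ln <- gsub("U", "T", toupper(body[i]), fixed = TRUE)
    bad <- regmatches(ln, regexpr(sprintf("[^%s]", allowed), ln))
    if (length(bad) == 1L)
      stop(sprintf("%s: illegal character '%s' on line %d", path, bad, line_no[i]))
  }
  seqs <- vapply(split(body, idx), function(x) paste(x, collapse = ""), "")
  seqs <- gsub("\\s", "", seqs)
  names(seqs) <- ids
  if (any(!nzchar(seqs)))
    stop(sprintf("%s: record '%s' has an empty sequence",
                 path, ids[!nzchar(seqs)][1L]))
  seqs <- normalize_dna(seqs, where = path)
  ortho_cluster(cluster_id, seqs)
}

#' Write sequences to FASTA
#'
#' @param x an [ortho_cluster()] or a named character vector of sequences.
#' @param path output file.
#' @param width line-wrapping width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "ortho_cluster")) x$seq else x
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

validate_tree <- function(tr, what = "tree") {
  if (anyDuplicated(tr$tip.label))
    stop(sprintf("%s: duplicate leaf label '%s'",
                 what, tr$tip.label[duplicated(tr$tip.label)][1L]))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop(sprintf("%s: negative branch length", what))
  tr
}

#' Read a Newick tree
#'
#' Parses a single Newick tree (from a file or a literal string) with optional
#' branch lengths and internal labels, and validates that leaf labels are
#' unique and branch lengths non-negative. A basal bifurcation is kept as
#' parsed; callers decide the rooted/unrooted interpretation.
#'
#' @param x path to a Newick file, or a Newick string (contains `(`/`;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(x) {
  tr <- if (grepl("[(;]", x)) ape::read.tree(text = x) else ape::read.tree(x)
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single Newick tree; use read_gene_trees() for collections")
    tr <- tr[[1L]]
  }
  validate_tree(tr, "newick")
}

#' Read a gene-tree collection (one Newick tree per line)
#'
#' @param path Newick file with one tree per line.
#' @return A list of validated `phylo` objects.
#' @export
read_gene_trees <- function(path) {
  trs <- ape::read.tree(path, keep.multi = TRUE)
  if (is.null(trs) || length(trs) == 0L) stop(sprintf("no trees in %s", path))
  lapply(seq_along(trs), function(i) validate_tree(trs[[i]], sprintf("tree %d", i)))
}

#' Write one or more trees as Newick
#' @param trees a `phylo` or list of them.
#' @param path output file.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(tr) ape::write.tree(tr), "")
  writeLines(txt, path)
  invisible(path)
}

#' Read a locus coordinate table
#'
#' Tab-separated with header `locus_id  chrom  pos`; positions are 1-based
#' point coordinates (the first base of the locus). Rows are returned sorted
#' by `(chrom, pos)`.
#'
#' @param path TSV file.
#' @return data.frame with columns `locus_id`, `chrom`, `pos`.
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop(sprintf("locus table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(df$locus_id))
    stop(sprintf("duplicate locus_id '%s'", df$locus_id[duplicated(df$locus_id)][1L]))
  pos_num <- suppressWarnings(as.numeric(df$pos))
  if (any(is.na(pos_num)) || any(pos_num != floor(pos_num)))
    stop("locus positions must be integers")
  if (any(pos_num < 1)) stop("locus positions must be >= 1 (1-based)")
  df$pos <- as.integer(pos_num)
  df <- df[order(df$chrom, df$pos), need]
  rownames(df) <- NULL
  df
}
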