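## Codon-aware alignment: ORF validation and translation, progressive
## protein alignment, column trimming, and back-translation to codons.

# standard genetic code, built once from Biostrings
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}
.gc_env <- new.env(parent = emptyenv())

translate_codons <- function(codons) {
  if (is.null(.gc_env$code)) .gc_env$code <- genetic_code()
  aa <- .gc_env$code[codons]
  aa[is.na(aa)] <- "X" # any codon containing N (or other ambiguity)
  unname(aa)
}

#' Validate an open reading frame and translate it
#'
#' Checks that a gap-free CDS has length divisible by three and contains no
#' in-frame stop codon before the final codon; a single terminal stop codon
#' is permitted and trimmed before translation. Codons containing `N`
#' translate to `X`. Failures are reported as statuses (not errors) because
#' they feed the filter report.
#'
#' @param sequence gap-free DNA string.
#' @return list with `status` (one of `ok`, `not_multiple_of_three`,
#'   `internal_stop`), `detail` (1-based index of the first offending codon,
#'   or `NA`), and `protein` (amino-acid string, or `NA` unless `ok`).
#' @export
check_and_translate <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("-", sequence, fixed = TRUE))
    stop("check_and_translate expects a gap-free sequence")
  n <- nchar(sequence)
  if (n %% 3L != 0L)
    return(list(status = "not_multiple_of_three", detail = NA_integer_,
                protein = NA_character_))
  codons <- substring(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- translate_codons(codons)
  k <- length(aa)
  if (k > 0L && aa[k] == "*") { # terminal stop trimmed
    codons <- codons[-k]
    aa <- aa[-k]
    k <- k - 1L
  }
  stops <- which(aa == "*")
  if (length(stops) > 0L)
    return(list(status = "internal_stop", detail = stops[1L],
                protein = NA_character_))
  list(status = "ok", detail = NA_integer_,
       protein = paste(aa, collapse = ""))
}

## protein alphabet: indices into the BLOSUM62 matrix; 0 encodes a gap
.aln_env <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.aln_env$S)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    S <- e$BLOSUM62
    ## 'X' here means missing data (masked codons), not a random residue:
    ## it must carry no alignment signal at all
    S["X", ] <- 0
    S[, "X"] <- 0
    .aln_env$S <- S
  }
  .aln_env$S
}

protein_to_int <- function(s) {
  S <- blosum62()
  alpha <- colnames(S)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- match(ch, alpha)
  idx[ch == "-"] <- 0L
  idx[is.na(idx)] <- match("X", alpha)
  idx
}

int_to_protein <- function(idx, template_chars) {
  # reconstruct from the original characters plus inserted gaps (idx == 0)
  out <- character(length(idx))
  out[idx == 0L] <- "-"
  out[idx != 0L] <- template_chars
  paste(out, collapse = "")
}

kmer_distance <- function(proteins, k = 3L) {
  n <- length(proteins)
  kmers <- lapply(proteins, function(s) {
    km <- if (nchar(s) < k) s
          else unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    ## k-mers containing ambiguity are uninformative about relatedness
    km[!grepl("X", km, fixed = TRUE)]
  })
  D <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    denom <- min(length(kmers[[i]]), length(kmers[[j]]))
    D[i, j] <- D[j, i] <- 1 - shared / max(denom, 1L)
  }
  D
}

#' Align protein sequences
#'
#' Deterministic progressive alignment: a UPGMA guide tree from k-mer (k = 3)
#' distances, then profile-profile global alignment under BLOSUM62 scores
#' with affine gap penalties. Input order of the rows is preserved; ungapping
#' any output row returns its input. An external aligner can be substituted
#' via `aligner_cmd`, a command line receiving the input FASTA path and the
#' output FASTA path as its two final arguments.
#'
#' @param proteins named character vector of ungapped amino-acid sequences.
#' @param gap_open,gap_ext affine gap penalties (positive numbers; defaults
#'   10 and 1).
#' @param aligner_cmd optional external command mapping FASTA to aligned
#'   FASTA.
#' @return named character vector of aligned rows (equal lengths).
#' @export
align_proteins <- function(proteins, gap_open = 10, gap_ext = 1,
                           aligner_cmd = NULL) {
  if (length(proteins) == 0L) stop("no sequences to align")
  if (any(!nzchar(proteins))) stop("empty protein sequence")
  if (length(proteins) == 1L) {
    warning("single sequence: returned unaligned", call. = FALSE)
    return(proteins)
  }
  if (!is.null(aligner_cmd)) {
    fin <- tempfile(fileext = ".faa")
    fout <- tempfile(fileext = ".faa")
    on.exit(unlink(c(fin, fout)))
    write_fasta_aa(proteins, fin)
    status <- system(paste(aligner_cmd, shQuote(fin), shQuote(fout)))
    if (status != 0L || !file.exists(fout))
      stop("external aligner command failed")
    out <- read_fasta_aa(fout)
    return(out[names(proteins)])
  }
  S <- blosum62()
  ord <- order(names(proteins)) # lexicographic tie-breaking in the guide tree
  sorted <- proteins[ord]
  n <- length(sorted)
  ints <- lapply(sorted, protein_to_int)
  if (n == 2L) {
    merge_order <- matrix(c(-1L, -2L), 1L, 2L)
  } else {
    D <- kmer_distance(sorted)
    hc <- hclust(as.dist(D), method = "average")
    merge_order <- hc$merge
  }
  profiles <- vector("list", nrow(merge_order))
  get_profile <- function(ref) {
    if (ref < 0) {
      m <- matrix(ints[[-ref]], nrow = 1L)
      rownames(m) <- names(sorted)[-ref]
      m
    } else profiles[[ref]]
  }
  for (r in seq_len(nrow(merge_order))) {
    A <- get_profile(merge_order[r, 1L])
    B <- get_profile(merge_order[r, 2L])
    path <- align_profiles_cpp(A, B, S, gap_open, gap_ext)
    nc <- length(path$a)
    M <- matrix(0L, nrow(A) + nrow(B), nc)
    M[seq_len(nrow(A)), path$a == 1L] <- A
    M[nrow(A) + seq_len(nrow(B)), path$b == 1L] <- B
    rownames(M) <- c(rownames(A), rownames(B))
    profiles[[r]] <- M
  }
  final <- profiles[[nrow(merge_order)]]
  rows <- vapply(names(proteins), function(id) {
    idx <- final[id, ]
    int_to_protein(idx, strsplit(proteins[[id]], "", fixed = TRUE)[[1L]])
  }, "")
  names(rows) <- names(proteins)
  rows
}

write_fasta_aa <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) writeLines(c(paste0(">", id), seqs[[id]]), con)
  invisible(path)
}

read_fasta_aa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_h <- startsWith(lines, ">")
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_h]))
  seqs <- vapply(split(lines[!is_h], cumsum(is_h)[!is_h]),
                 function(x) paste(x, collapse = ""), "")
  setNames(toupper(seqs), ids)
}

#' Trim poorly aligned protein columns
#'
#' A column is retained iff its gap fraction is at most `max_gap_frac` and
#' the modal-residue fraction among non-gap cells is at least
#' `min_conservation`. `X` cells count in the gap-fraction denominator and in
#' the non-gap count, but never toward the modal residue.
#'
#' @param aln named character vector of aligned rows (equal length).
#' @param max_gap_frac maximum tolerated fraction of gaps per column.
#' @param min_conservation minimum modal-residue fraction among non-gap cells.
#' @return list with `alignment` (trimmed rows) and `retained`
#'   (strictly increasing original column indices).
#' @export
trim_columns <- function(aln, max_gap_frac = 0.2, min_conservation = 0.25) {
  stopifnot(length(unique(nchar(aln))) == 1L)
  M <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  nr <- nrow(M)
  keep <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    gap_frac <- sum(col == "-") / nr
    if (gap_frac > max_gap_frac) return(FALSE)
    nongap <- col[col != "-"]
    if (length(nongap) == 0L) return(FALSE)
    res <- nongap[nongap != "X"]
    modal <- if (length(res) == 0L) 0 else max(table(res)) / length(nongap)
    modal >= min_conservation
  }, logical(1L))
  retained <- which(keep)
  trimmed <- vapply(seq_len(nr), function(i)
    paste(M[i, retained], collapse = ""), "")
  names(trimmed) <- names(aln)
  list(alignment = trimmed, retained = retained)
}

#' Back-translate a trimmed protein alignment to a codon alignment
#'
#' The residue at protein column `j` of a row maps to codon `j` of the CDS
#' counting only non-gap cells; gap residues map to `---`. Only the columns
#' listed in `retained` are emitted, so each output row has length
#' `3 * length(retained)`.
#'
#' @param aln full (untrimmed) protein alignment, named character vector.
#' @param retained strictly increasing protein column indices to keep.
#' @param cds named character vector of the original gap-free CDS (terminal
#'   stop codons allowed; they are ignored).
#' @return named character vector of aligned DNA rows.
#' @export
backtranslate <- function(aln, retained, cds) {
  stopifnot(all(names(aln) %in% names(cds)))
  out <- vapply(names(aln), function(id) {
    row <- strsplit(aln[[id]], "", fixed = TRUE)[[1L]]
    s <- cds[[id]]
    chk <- check_and_translate(s)
    if (!identical(chk$status, "ok") ||
        !identical(chk$protein, gsub("-", "", aln[[id]], fixed = TRUE)))
      stop(sprintf("protein row '%s' does not match the translation of its CDS", id))
    n_cod <- nchar(chk$protein)
    codons <- substring(s, seq(1L, 3L * n_cod, 3L), seq(3L, 3L * n_cod, 3L))
    codon_idx <- cumsum(row != "-")
    cells <- ifelse(row == "-", "---", codons[codon_idx])
    paste(cells[retained], collapse = "")
  }, "")
  names(out) <- names(aln)
  out
}

#' Codon-aware alignment of a cluster
#'
#' Convenience wrapper running translate, align, trim, back-translate for the
#' gap-free CDS of a cluster. Records failing the ORF check are dropped with
#' a reason (callers that need the audit trail use [run_pipeline()]).
#'
#' @param sequences named character vector of gap-free CDS.
#' @param max_gap_frac,min_conservation trimming thresholds, see
#'   [trim_columns()].
#' @param aligner_cmd optional external aligner, see [align_proteins()].
#' @return list with `codon` (aligned DNA rows), `protein` (trimmed protein
#'   rows), `retained` (kept protein columns), `dropped` (ids failing the
#'   ORF check).
#' @export
align_cluster <- function(sequences, max_gap_frac = 0.2,
                          min_conservation = 0.25, aligner_cmd = NULL) {
  checks <- lapply(sequences, check_and_translate)
  ok <- vapply(checks, function(x)
    identical(x$status, "ok") && nzchar(x$protein), logical(1L))
  proteins <- vapply(checks[ok], `[[`, "", "protein")
  names(proteins) <- names(sequences)[ok]
  if (length(proteins) == 0L)
    return(list(codon = character(0), protein = character(0),
                retained = integer(0), dropped = names(sequences)))
  if (length(proteins) == 1L) {
    # nothing to align; keep the sequence whole
    prot <- proteins
    n_cod <- nchar(prot)
    ret <- seq_len(n_cod)
    cod <- backtranslate(prot, ret, sequences)
    return(list(codon = cod, protein = prot, retained = ret,
                dropped = names(sequences)[!ok]))
  }
  aligned <- align_proteins(proteins, aligner_cmd = aligner_cmd)
  tr <- trim_columns(aligned, max_gap_frac, min_conservation)
  if (length(tr$retained) == 0L)
    return(list(codon = setNames(rep("", length(proteins)), names(proteins)),
                protein = tr$alignment, retained = integer(0),
                dropped = names(sequences)[!ok]))
  cod <- backtranslate(aligned, tr$retained, sequences)
  list(codon = cod, protein = tr$alignment, retained = tr$retained,
       dropped = names(sequences)[!ok])
}
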