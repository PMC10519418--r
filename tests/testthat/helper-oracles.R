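## Independent oracle implementations used to cross-check the package: all
## of them deliberately avoid the code paths they verify (plain R loops,
## ape/phangorn primitives, union-find).

## per-column uncorrected distance, character by character
oracle_pdist <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  ncmp <- 0L
  nmis <- 0L
  for (k in seq_along(a)) {
    if (a[k] %in% c("A", "C", "G", "T") && b[k] %in% c("A", "C", "G", "T")) {
      ncmp <- ncmp + 1L
      if (a[k] != b[k]) nmis <- nmis + 1L
    }
  }
  list(d = if (ncmp == 0L) NA_real_ else 100 * nmis / ncmp, compared = ncmp)
}

## induced quartet topology of 4 leaves in a tree, by pruning and comparing
## against the three reference shapes (0 = unresolved)
oracle_quartet <- function(tree, a, b, c, d) {
  sub <- ape::keep.tip(tree, c(a, b, c, d))
  refs <- c(sprintf("((%s,%s),(%s,%s));", a, b, c, d),
            sprintf("((%s,%s),(%s,%s));", a, c, b, d),
            sprintf("((%s,%s),(%s,%s));", a, d, b, c))
  for (i in 1:3) {
    ref <- ape::unroot(ape::read.tree(text = refs[i]))
    if (ape::dist.topo(ape::unroot(sub), ref) == 0) return(i)
  }
  0L
}

## quartet agreement score by direct double loop over 4-subsets
oracle_quartet_score <- function(topology, gene_trees) {
  taxa <- topology$tip.label
  total <- 0L
  subsets <- combn(taxa, 4)
  for (j in seq_len(ncol(subsets))) {
    q <- subsets[, j]
    pt <- oracle_quartet(topology, q[1], q[2], q[3], q[4])
    if (pt == 0L) next
    for (gt in gene_trees) {
      if (!all(q %in% gt$tip.label)) next
      if (oracle_quartet(gt, q[1], q[2], q[3], q[4]) == pt)
        total <- total + 1L
    }
  }
  total
}

## single-linkage cluster count via union-find over the threshold graph
oracle_n_clusters <- function(loci, dist_max) {
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (loci$chrom[i] == loci$chrom[j] &&
        abs(loci$pos[i] - loci$pos[j]) <= dist_max) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

## random binary tree with the given labels
random_tree <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = TRUE)
  tr$tip.label <- sample(labels)
  tr
}

## random DNA-with-gaps row
random_row <- function(len, p_gap = 0.1, p_n = 0.05) {
  sample(c("A", "C", "G", "T", "-", "N"), len, replace = TRUE,
         prob = c(rep((1 - p_gap - p_n) / 4, 4), p_gap, p_n)) |>
    paste(collapse = "")
}

## random gap-free CDS with no internal stop (for alignment tests)
random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
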