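## Genomic independence of a marker panel: nearest-neighbour distances on
## point coordinates, single-linkage clustering at a distance threshold, and
## fixed-width bin counts for visualisation export.

#' Nearest-neighbour distances between loci
#'
#' Per locus, the minimum absolute position difference to any other locus on
#' the same chromosome (point coordinates); `NA` when a locus is alone on
#' its chromosome. Loci on different chromosomes are never neighbours.
#'
#' @param loci data.frame with `locus_id`, `chrom`, `pos` (see
#'   [read_locus_table()]).
#' @return named numeric vector (bp), names are locus ids, input order.
#' @export
nearest_neighbor_distances <- function(loci) {
  stopifnot(nrow(loci) >= 1L)
  out <- setNames(rep(NA_real_, nrow(loci)), loci$locus_id)
  for (ch in unique(loci$chrom)) {
    sel <- which(loci$chrom == ch)
    if (length(sel) < 2L) next
    pos <- loci$pos[sel]
    for (k in seq_along(sel))
      out[sel[k]] <- min(abs(pos[-k] - pos[k]))
  }
  out
}

#' Independence summary of a locus panel
#'
#' `n_isolated` counts loci whose nearest-neighbour distance is strictly
#' greater than `independence_dist` (a locus alone on its chromosome counts
#' as isolated). Single-linkage clusters join loci on the same chromosome at
#' distances up to and including `independence_dist`; `n_independent` is the
#' number of clusters, each isolated locus being its own cluster.
#'
#' @param loci data.frame with `locus_id`, `chrom`, `pos`.
#' @param independence_dist distance threshold in bp (default 100000).
#' @return list with `n_isolated`, `n_independent`, and `clusters`
#'   (data.frame `locus_id`, `cluster`).
#' @export
independence_summary <- function(loci, independence_dist = 100000) {
  nn <- nearest_neighbor_distances(loci)
  n_isolated <- sum(is.na(nn) | nn > independence_dist)
  cluster <- integer(nrow(loci))
  next_id <- 0L
  for (ch in unique(loci$chrom)) {
    sel <- which(loci$chrom == ch)
    ord <- sel[order(loci$pos[sel])]
    pos <- loci$pos[ord]
    ## 1-D single linkage: a gap > threshold starts a new cluster
    newgrp <- c(TRUE, diff(pos) > independence_dist)
    cluster[ord] <- next_id + cumsum(newgrp)
    next_id <- next_id + sum(newgrp)
  }
  list(n_isolated = n_isolated, n_independent = next_id,
       clusters = data.frame(locus_id = loci$locus_id, cluster = cluster,
                             stringsAsFactors = FALSE))
}

#' Locus counts in fixed-width genomic bins
#'
#' Bins are half-open `[k * bin_size, (k+1) * bin_size)` in 0-based
#' coordinates, so a locus with 1-based position `p` falls in bin
#' `floor((p - 1) / bin_size)`. Counts conserve the total locus number.
#'
#' @param loci data.frame with `locus_id`, `chrom`, `pos`.
#' @param bin_size bin width in bp (default 500000).
#' @param chrom_lengths optional named vector of chromosome lengths; loci
#'   beyond the declared length raise a warning but are still binned.
#' @return data.frame with `chrom`, `bin_start`, `bin_end`, `count`,
#'   sorted by `(chrom, bin_start)`; empty intermediate bins included per
#'   chromosome.
#' @export
bin_counts <- function(loci, bin_size = 500000, chrom_lengths = NULL) {
  stopifnot(bin_size > 0)
  if (!is.null(chrom_lengths)) {
    over <- loci$pos > chrom_lengths[loci$chrom]
    over[is.na(over)] <- FALSE
    if (any(over))
      warning(sprintf("locus '%s' lies beyond its chromosome length",
                      loci$locus_id[over][1L]), call. = FALSE)
  }
  bin <- (loci$pos - 1) %/% bin_size
  out <- do.call(rbind, lapply(sort(unique(loci$chrom)), function(ch) {
    b <- bin[loci$chrom == ch]
    full <- seq.int(0L, max(b))
    counts <- tabulate(b + 1L, nbins = max(b) + 1L)
    data.frame(chrom = ch, bin_start = full * bin_size,
               bin_end = (full + 1) * bin_size, count = counts,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
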