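## The locus-subsampling experiment: replicate gene-tree subsets of
## increasing size, a species tree per subset, and clade-recovery /
## Robinson-Foulds summaries against a reference tree.

#' Subsampling configuration
#'
#' @param sizes subset sizes to draw (default 10..110 by 10).
#' @param replicates replicate subsets per size (default 500).
#' @param min_coverage every specimen must occur in at least this many
#'   distinct drawn gene trees (default 2).
#' @param with_replacement draw gene trees with replacement (default TRUE).
#' @param seed integer seed.
#' @param max_attempts redraw cap per replicate before an error is raised.
#' @return list of class `subsample_config`.
#' @export
subsample_config <- function(sizes = seq(10L, 110L, by = 10L),
                             replicates = 500L, min_coverage = 2L,
                             with_replacement = TRUE, seed = 1L,
                             max_attempts = 1000L) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 1L), replicates >= 1L,
            min_coverage >= 1L, max_attempts >= 1L)
  structure(list(sizes = as.integer(sizes),
                 replicates = as.integer(replicates),
                 min_coverage = as.integer(min_coverage),
                 with_replacement = isTRUE(with_replacement),
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "subsample_config")
}

#' Draw one gene-tree subset under the coverage rule
#'
#' Draws `size` gene-tree indices (a multiset when `with_replacement`) and
#' accepts the draw only if every specimen in the universe (the union of all
#' gene-tree leaf sets) occurs in at least `min_coverage` DISTINCT drawn
#' trees; otherwise it redraws, up to `max_attempts`. Duplicated copies of a
#' tree never count twice toward coverage.
#'
#' @param gene_trees list of `phylo`.
#' @param size subset size.
#' @param min_coverage required distinct-tree coverage per specimen.
#' @param with_replacement allow repeats.
#' @param max_attempts redraw cap.
#' @return list with `indices` (integer vector of length `size`) and
#'   `attempts`.
#' @export
draw_subset <- function(gene_trees, size, min_coverage = 2L,
                        with_replacement = TRUE, max_attempts = 1000L) {
  leaf_sets <- lapply(gene_trees, `[[`, "tip.label")
  specimens <- sort(unique(unlist(leaf_sets)))
  overall <- vapply(specimens, function(sp)
    sum(vapply(leaf_sets, function(l) sp %in% l, logical(1L))), integer(1L))
  lacking <- specimens[overall < min_coverage]
  if (length(lacking) > 0L)
    stop(sprintf(
      "specimen '%s' occurs in only %d gene tree(s); %d required",
      lacking[1L], overall[[lacking[1L]]], min_coverage))
  if (!with_replacement && size > length(gene_trees))
    stop("size exceeds the number of gene trees without replacement")
  for (attempt in seq_len(max_attempts)) {
    idx <- sample.int(length(gene_trees), size, replace = with_replacement)
    distinct <- unique(idx)
    cov <- vapply(specimens, function(sp)
      sum(vapply(leaf_sets[distinct], function(l) sp %in% l, logical(1L))),
      integer(1L))
    if (all(cov >= min_coverage))
      return(list(indices = idx, attempts = attempt))
  }
  stop(sprintf("no subset satisfying the coverage rule in %d attempts",
               max_attempts))
}

#' Run the subsampling experiment
#'
#' For each (size, replicate): draw a subset with [draw_subset()], estimate a
#' species tree, root it on the outgroup, prune the outgroup, and compare to
#' the (equally rooted and pruned) reference by rooted Robinson-Foulds
#' distance and clade recovery. Fully reproducible from the configuration
#' seed.
#'
#' @param gene_trees list of `phylo`.
#' @param config a [subsample_config()].
#' @param reference_tree `phylo`, rooted or rootable on `outgroup`.
#' @param outgroup leaf label used to root estimated trees (pruned before
#'   comparison).
#' @param reference_clades list of leaf sets checked in each estimated tree;
#'   they must not contain the outgroup.
#' @param estimator function `(gene_trees, seed) -> phylo`; default wraps
#'   [greedy_search()].
#' @return list with `results` (one row per replicate: `size`, `replicate`,
#'   `rf`, `attempts`, plus one logical column per clade) and `summary`
#'   (per size and clade: `recovery_prop`, `rf_median`, `rf_q1`, `rf_q3`).
#' @export
run_experiment <- function(gene_trees, config, reference_tree, outgroup,
                           reference_clades, estimator = NULL) {
  stopifnot(inherits(config, "subsample_config"))
  if (is.null(estimator))
    estimator <- function(gts, seed) greedy_search(gts, seed = seed)$tree
  if (!(outgroup %in% reference_tree$tip.label))
    stop("outgroup absent from the reference tree")
  ref <- ape::root(reference_tree, outgroup = outgroup, resolve.root = TRUE)
  ref <- ape::drop.tip(ref, outgroup)
  for (cl in reference_clades)
    if (outgroup %in% cl) stop("reference clades must not contain the outgroup")
  clade_names <- if (!is.null(names(reference_clades)) &&
                     all(nzchar(names(reference_clades))))
    names(reference_clades) else paste0("clade", seq_along(reference_clades))
  rows <- vector("list", length(config$sizes) * config$replicates)
  ri <- 0L
  for (si in seq_along(config$sizes)) {
    size <- config$sizes[si]
    for (rep_i in seq_len(config$replicates)) {
      rep_seed <- derive_seed(config$seed, si * 100000L + rep_i)
      set.seed(rep_seed)
      dr <- draw_subset(gene_trees, size, config$min_coverage,
                        config$with_replacement, config$max_attempts)
      est <- estimator(gene_trees[dr$indices], rep_seed)
      if (!(outgroup %in% est$tip.label))
        stop("outgroup absent from the estimated tree")
      est <- ape::root(est, outgroup = outgroup, resolve.root = TRUE)
      est <- ape::drop.tip(est, outgroup)
      rf <- rf_distance(est, ref, mode = "rooted", prune_to_common = TRUE)
      rec <- clade_recovery(est, reference_clades)
      ri <- ri + 1L
      row <- data.frame(size = size, replicate = rep_i, rf = rf,
                        attempts = dr$attempts)
      row[clade_names] <- as.list(rec)
      rows[[ri]] <- row
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(results$size), function(sz) {
    sub <- results[results$size == sz, , drop = FALSE]
    do.call(rbind, lapply(clade_names, function(cn)
      data.frame(size = sz, clade_id = cn,
                 recovery_prop = mean(sub[[cn]]),
                 rf_median = median(sub$rf),
                 rf_q1 = unname(quantile(sub$rf, 0.25)),
                 rf_q3 = unname(quantile(sub$rf, 0.75)),
                 stringsAsFactors = FALSE)))
  }))
  list(results = results, summary = summ)
}
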