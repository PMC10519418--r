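## The three-step ortholog-cluster filter: length variation, mean uncorrected
## pairwise distance, and missingness, each followed by a round of codon-aware
## alignment and trimming, plus occupancy filtering across clusters and the
## distance statistics used to choose the distance threshold.

#' Filter parameters
#'
#' @param len_var_pct allowed percent deviation from the cluster mean length
#'   (default 30): sequences longer than `mean * (1 + len_var_pct/100)` or
#'   shorter than `mean * (1 - len_var_pct/100)` are removed.
#' @param max_mean_dist maximum allowed per-sequence mean uncorrected
#'   pairwise distance, percent in `[0, 100]` (default 25).
#' @param max_missing_frac maximum allowed fraction of missing data (`N`)
#'   plus gaps per aligned row (default 0.25).
#' @param min_samples minimum surviving samples for a cluster to be kept
#'   (default 30).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(len_var_pct = 30, max_mean_dist = 25,
                          max_missing_frac = 0.25, min_samples = 30L) {
  stopifnot(len_var_pct >= 0,
            max_mean_dist >= 0, max_mean_dist <= 100,
            max_missing_frac >= 0, max_missing_frac <= 1,
            min_samples >= 2)
  structure(list(len_var_pct = len_var_pct, max_mean_dist = max_mean_dist,
                 max_missing_frac = max_missing_frac,
                 min_samples = as.integer(min_samples)),
            class = "filter_params")
}

report_row <- function(cluster_id, sample_id, step, reason, metric = NA_real_) {
  data.frame(cluster_id = cluster_id, sample_id = sample_id, step = step,
             reason = reason, metric = metric, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(cluster_id = character(0), sample_id = character(0),
             step = character(0), reason = character(0),
             metric = numeric(0), stringsAsFactors = FALSE)
}

#' Prepare raw sequences for filtering
#'
#' Strips alignment gaps and trims leading/trailing runs of `N`.
#'
#' @param seqs named character vector of DNA sequences.
#' @return named character vector.
#' @export
prep_sequences <- function(seqs) {
  s <- gsub("-", "", seqs, fixed = TRUE)
  s <- sub("^N+", "", s)
  s <- sub("N+$", "", s)
  setNames(s, names(seqs))
}

#' Step 1: reading-frame and length-variation filter
#'
#' Per record, in order: strip gaps, trim terminal `N` runs, remove sequences
#' whose length is not a multiple of three or that contain an internal stop
#' codon; then compute the mean length over the remaining records and remove,
#' in a single pass against that mean, any record whose length is strictly
#' above `mean * (1 + len_var_pct/100)` or strictly below
#' `mean * (1 - len_var_pct/100)`.
#'
#' @param cluster an [ortho_cluster()] or named character vector of raw CDS.
#' @param len_var_pct percent length-variation cutoff.
#' @return list with `survivors` (named prepped CDS) and `report`
#'   (removal rows).
#' @export
step1_length_filter <- function(cluster, len_var_pct = 30) {
  seqs <- if (inherits(cluster, "ortho_cluster")) cluster$seq else cluster
  cid <- if (inherits(cluster, "ortho_cluster")) cluster$cluster_id else NA_character_
  prepped <- prep_sequences(seqs)
  report <- empty_report()
  keep <- character(0)
  for (id in names(prepped)) {
    s <- prepped[[id]]
    if (!nzchar(s)) {
      report <- rbind(report, report_row(cid, id, "prep", "empty_after_prep"))
      next
    }
    chk <- check_and_translate(s)
    if (identical(chk$status, "ok")) keep <- c(keep, id)
    else report <- rbind(report, report_row(cid, id, "prep", chk$status,
                                            as.numeric(chk$detail)))
  }
  if (length(keep) == 0L)
    return(list(survivors = prepped[keep], report = report))
  lens <- nchar(prepped[keep])
  mu <- mean(lens)
  lo <- mu * (1 - len_var_pct / 100)
  hi <- mu * (1 + len_var_pct / 100)
  out <- lens > hi | lens < lo
  for (id in keep[out])
    report <- rbind(report, report_row(cid, id, "length_set",
                                       "length_outlier", nchar(prepped[[id]])))
  list(survivors = prepped[keep[!out]], report = report)
}

#' Uncorrected pairwise distance matrix
#'
#' For each pair of aligned rows, compared sites are the columns where both
#' rows carry an unambiguous base (`A`, `C`, `G`, `T`); the distance is
#' `100 * mismatches / compared sites`. Pairs with zero compared sites are
#' undefined (`NA` in `d`) and are treated downstream as exceeding any
#' threshold.
#'
#' @param aln named character vector of aligned DNA rows (equal length).
#' @return list with `ids`, `d` (symmetric percent matrix, zero diagonal,
#'   `NA` where undefined) and `compared` (symmetric integer matrix of
#'   compared-site counts).
#' @export
pdistance_matrix <- function(aln) {
  if (length(aln) < 2L) stop("need at least two aligned rows")
  stopifnot(length(unique(nchar(aln))) == 1L)
  M <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  good <- M == "A" | M == "C" | M == "G" | M == "T"
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  cmp <- matrix(0L, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- good[i, ] & good[j, ]
    nc <- sum(both)
    cmp[i, j] <- cmp[j, i] <- nc
    d[i, j] <- d[j, i] <-
      if (nc == 0L) NA_real_ else 100 * sum(M[i, both] != M[j, both]) / nc
  }
  list(ids = names(aln), d = d, compared = cmp)
}

row_mean_distances <- function(dm) {
  d <- dm$d
  ## undefined pairwise distances enter the mean at the maximum (100)
  d[is.na(d)] <- 100
  n <- nrow(d)
  if (n < 2L) return(setNames(numeric(0), character(0)))
  (rowSums(d)) / (n - 1L)
}

#' Step 2: mean pairwise-distance filter
#'
#' Removes, in one simultaneous pass, every row whose mean off-diagonal
#' uncorrected distance is strictly greater than `max_mean_dist`.
#'
#' @param aln aligned DNA rows (a codon alignment of step-1 survivors).
#' @param max_mean_dist percent threshold in `[0, 100]`.
#' @param cluster_id id used in the report.
#' @return list with `keep` (surviving ids) and `report`.
#' @export
step2_distance_filter <- function(aln, max_mean_dist = 25,
                                  cluster_id = NA_character_) {
  if (length(aln) < 2L)
    return(list(keep = names(aln), report = empty_report()))
  means <- row_mean_distances(pdistance_matrix(aln))
  out <- means > max_mean_dist
  report <- empty_report()
  for (id in names(aln)[out])
    report <- rbind(report, report_row(cluster_id, id, "distance",
                                       "high_mean_distance", means[[id]]))
  list(keep = names(aln)[!out], report = report)
}

#' Step 3: missingness filter
#'
#' Removes every aligned row whose fraction of `N` plus `-` cells is strictly
#' greater than `max_missing_frac`.
#'
#' @param aln aligned DNA rows.
#' @param max_missing_frac fraction in `[0, 1]`.
#' @param cluster_id id used in the report.
#' @return list with `keep` and `report`.
#' @export
step3_missingness_filter <- function(aln, max_missing_frac = 0.25,
                                     cluster_id = NA_character_) {
  n_bad <- nchar(gsub("[^N-]", "", aln))
  frac <- n_bad / nchar(aln)
  out <- frac > max_missing_frac
  report <- empty_report()
  for (id in names(aln)[out])
    report <- rbind(report, report_row(cluster_id, id, "missingness",
                                       "high_missingness", frac[[id]]))
  list(keep = names(aln)[!out], report = report)
}

#' Occupancy filter across clusters
#'
#' Keeps clusters whose surviving sample count is at least `min_samples` and
#' reports the corresponding gene-occupancy label,
#' `round(100 * min_samples / total_samples)` percent.
#'
#' @param counts named integer vector: surviving samples per cluster.
#' @param min_samples minimum sample count.
#' @param total_samples total samples in the study.
#' @return list with `keep` (cluster ids), `occupancy_pct` (integer label)
#'   and `report` (per-cluster rows for dropped clusters).
#' @export
occupancy_filter <- function(counts, min_samples, total_samples) {
  if (min_samples > total_samples)
    stop("min_samples exceeds the total number of samples")
  keep <- names(counts)[counts >= min_samples]
  report <- empty_report()
  for (cid in names(counts)[counts < min_samples])
    report <- rbind(report, report_row(cid, NA_character_, "occupancy",
                                       "below_min_samples", counts[[cid]]))
  list(keep = keep,
       occupancy_pct = as.integer(round(100 * min_samples / total_samples)),
       report = report)
}

#' Distance statistics for threshold selection
#'
#' For each aligned cluster, the maximum off-diagonal uncorrected distance;
#' across clusters, the mean, sample standard deviation and median of those
#' maxima. These are the statistics used to anchor the choice of
#' `max_mean_dist` (the distance filter threshold) on the data.
#'
#' @param alignments named list of aligned clusters (each a named character
#'   vector with at least two rows).
#' @return list with `per_cluster_max` (named vector), `mean`, `sd`,
#'   `median`.
#' @export
distance_threshold_stats <- function(alignments) {
  if (length(alignments) == 0L) stop("no eligible clusters")
  mx <- vapply(alignments, function(aln) {
    d <- pdistance_matrix(aln)$d
    max(d[upper.tri(d)], na.rm = TRUE)
  }, numeric(1L))
  s <- if (length(mx) < 2L) {
    warning("single cluster: SD undefined, reported as 0", call. = FALSE)
    0
  } else sd(mx)
  list(per_cluster_max = mx, mean = mean(mx), sd = s, median = median(mx))
}

#' Mean alignment length summary
#'
#' The bookkeeping formula reported after filtering: mean alignment length is
#' total nucleotide sites divided by the number of retained alignments,
#' rounded to two decimals.
#'
#' @param n_clusters number of retained alignments.
#' @param total_sites summed alignment lengths in nucleotides.
#' @return list with `clusters`, `total_sites`, `mean_length`.
#' @export
alignment_length_summary <- function(n_clusters, total_sites) {
  list(clusters = as.integer(n_clusters),
       total_sites = as.numeric(total_sites),
       mean_length = round(total_sites / n_clusters, 2))
}

#' Run the full three-step filter pipeline
#'
#' Per cluster: step 1 (reading frame + length variation) then codon-aware
#' alignment and trimming; step 2 (mean pairwise distance) on that codon
#' alignment, then re-alignment of the survivors; step 3 (missingness), then
#' a final re-alignment. Clusters are then subjected to the occupancy filter.
#' Every input record appears in the report exactly once, either with the
#' step and reason of its removal or as retained.
#'
#' @param clusters named list of [ortho_cluster()] objects or named sequence
#'   vectors.
#' @param params a [filter_params()] object.
#' @param max_gap_frac,min_conservation trimming thresholds per alignment
#'   round, see [trim_columns()].
#' @param aligner_cmd optional external aligner, see [align_proteins()].
#' @param total_samples total samples in the study (defaults to the number of
#'   distinct sample ids across the input clusters).
#' @return list with `alignments` (final codon alignments of retained
#'   clusters), `report` (per-record audit trail), `dispositions`
#'   (per-cluster outcome), `summary` (cluster count, total sites, mean
#'   alignment length, occupancy percent).
#' @export
run_pipeline <- function(clusters, params = filter_params(),
                         max_gap_frac = 0.2, min_conservation = 0.25,
                         aligner_cmd = NULL, total_samples = NULL) {
  if (length(clusters) == 0L) stop("no input clusters")
  seq_of <- function(cl) if (inherits(cl, "ortho_cluster")) cl$seq else cl
  if (is.null(names(clusters)))
    names(clusters) <- vapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      if (inherits(cl, "ortho_cluster")) cl$cluster_id else sprintf("cluster%d", i)
    }, "")
  if (is.null(total_samples))
    total_samples <- length(unique(unlist(lapply(clusters, function(cl)
      names(seq_of(cl))))))
  report <- empty_report()
  final <- list()
  realign <- function(seqs)
    align_cluster(seqs, max_gap_frac = max_gap_frac,
                  min_conservation = min_conservation,
                  aligner_cmd = aligner_cmd)
  for (cid in names(clusters)) {
    seqs <- seq_of(clusters[[cid]])
    s1 <- step1_length_filter(setNames(seqs, names(seqs)),
                              params$len_var_pct)
    s1$report$cluster_id <- rep(cid, nrow(s1$report))
    report <- rbind(report, s1$report)
    cur <- s1$survivors
    if (length(cur) == 0L) { final[[cid]] <- character(0); next }
    a1 <- realign(cur)
    if (length(a1$retained) == 0L) {
      for (id in names(cur))
        report <- rbind(report, report_row(cid, id, "distance",
                                           "empty_alignment"))
      final[[cid]] <- character(0)
      next
    }
    s2 <- step2_distance_filter(a1$codon, params$max_mean_dist, cid)
    report <- rbind(report, s2$report)
    cur <- cur[s2$keep]
    if (length(cur) == 0L) { final[[cid]] <- character(0); next }
    a2 <- realign(cur)
    if (length(a2$retained) == 0L) {
      for (id in names(cur))
        report <- rbind(report, report_row(cid, id, "missingness",
                                           "empty_alignment"))
      final[[cid]] <- character(0)
      next
    }
    s3 <- step3_missingness_filter(a2$codon, params$max_missing_frac, cid)
    report <- rbind(report, s3$report)
    cur <- cur[s3$keep]
    if (length(cur) == 0L) { final[[cid]] <- character(0); next }
    a3 <- realign(cur)
    final[[cid]] <- a3$codon
  }
  counts <- vapply(final, length, integer(1L))
  occ <- occupancy_filter(counts, params$min_samples, total_samples)
  report <- rbind(report, occ$report)
  retained_alns <- final[occ$keep]
  ## mark retained records
  for (cid in occ$keep)
    for (id in names(retained_alns[[cid]]))
      report <- rbind(report, report_row(cid, id, "final", "retained",
                                         nchar(retained_alns[[cid]][[id]])))
  ## records surviving steps but lost with a dropped cluster
  for (cid in setdiff(names(final), occ$keep))
    for (id in names(final[[cid]]))
      report <- rbind(report, report_row(cid, id, "occupancy",
                                         "cluster_dropped"))
  dispositions <- data.frame(
    cluster_id = names(final),
    disposition = ifelse(names(final) %in% occ$keep, "retained", "dropped"),
    n_final = unname(counts),
    stringsAsFactors = FALSE)
  sites <- vapply(retained_alns, function(a)
    if (length(a)) nchar(a[[1L]]) else 0L, integer(1L))
  summ <- c(alignment_length_summary(length(retained_alns), sum(sites)),
            list(occupancy_pct = occ$occupancy_pct,
                 total_samples = total_samples))
  list(alignments = retained_alns, report = report,
       dispositions = dispositions, summary = summ)
}
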