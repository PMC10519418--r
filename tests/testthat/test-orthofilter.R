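test_that("step 1 enforces the reading frame then the length-variation band", {
  ## lengths {300, 300, 600} at a 30% cutoff: mean 400, bounds [280, 520]
  seqs <- c(a = strrep("ATGAAA", 50), b = strrep("ATGAAA", 50),
            c = strrep("ATGAAA", 100))
  s1 <- step1_length_filter(seqs, 30)
  expect_identical(names(s1$survivors), c("a", "b"))
  expect_identical(s1$report$reason, "length_outlier")
  expect_identical(s1$report$step, "length_set")

  ## frame-valid lengths {90, 99, 111}: mean 100, 5% bounds [95, 105],
  ## both extremes removed in one pass against the original mean
  seqs2 <- c(a = strrep("AAA", 30), b = strrep("AAA", 33),
             c = strrep("AAA", 37))
  s2 <- step1_length_filter(seqs2, 5)
  expect_identical(names(s2$survivors), "b")

  ## prep strips gaps and trims terminal N runs before any length test
  s3 <- step1_length_filter(c(x = "NNATG-AAATT-TNN", y = "ATGAAATTT"), 100)
  expect_identical(unname(s3$survivors["x"]), "ATGAAATTT")

  ## frame and internal stops are recorded at the prep step
  s4 <- step1_length_filter(c(x = "ATGAAAA", y = "ATGTAAAAA",
                              z = "ATGAAAGGG"), 100)
  expect_identical(names(s4$survivors), "z")
  expect_setequal(s4$report$reason, c("not_multiple_of_three", "internal_stop"))
  expect_true(all(s4$report$step == "prep"))
})

test_that("p-distance excludes gaps and N and matches a per-column oracle", {
  dm <- pdistance_matrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(dm$d["a", "b"], 25)
  expect_equal(dm$compared["a", "b"], 4L)
  dm2 <- pdistance_matrix(c(a = "AA-A", b = "AAAA"))
  expect_equal(dm2$d["a", "b"], 0)
  expect_equal(dm2$compared["a", "b"], 3L)
  ## no shared unambiguous sites -> undefined
  dm3 <- pdistance_matrix(c(a = "AA--", b = "--AA"))
  expect_true(is.na(dm3$d["a", "b"]))

  set.seed(71)
  for (i in 1:20) {
    r1 <- random_row(300)
    r2 <- random_row(300)
    got <- pdistance_matrix(c(x = r1, y = r2))
    want <- oracle_pdist(r1, r2)
    expect_equal(got$d["x", "y"], want$d)
    expect_equal(got$compared["x", "y"], want$compared)
  }
})

test_that("step 2 removes high-mean-distance rows in one simultaneous pass", {
  aln <- c(a = strrep("A", 100), b = strrep("A", 100), c = strrep("A", 100),
           d = paste0(strrep("A", 50), strrep("C", 50)))
  s <- step2_distance_filter(aln, 25)
  expect_identical(s$keep, c("a", "b", "c"))
  expect_equal(s$report$metric, 50)

  ## identical rows survive any threshold; threshold 0 is strict
  same <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  expect_length(step2_distance_filter(same, 0)$keep, 3L)
  mixed <- c(a = "ACGT", b = "ACGA")
  expect_length(step2_distance_filter(mixed, 0)$keep, 0L)
})

test_that("step 2 equals brute-force recomputation for small alignments", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    aln <- setNames(vapply(seq_len(n), function(j) random_row(60), ""),
                    paste0("s", seq_len(n)))
    thr <- runif(1, 0, 40)
    got <- step2_distance_filter(aln, thr)$keep
    d <- matrix(0, n, n)
    for (a in 1:n) for (b in 1:n) {
      if (a == b) next
      o <- oracle_pdist(aln[[a]], aln[[b]])
      d[a, b] <- if (is.na(o$d)) 100 else o$d
    }
    means <- rowSums(d) / (n - 1)
    expect_identical(got, names(aln)[means <= thr])
  }
})

test_that("step 3 counts N and gaps with a strict threshold", {
  row100 <- function(nbad) paste0(strrep("N", nbad), strrep("A", 100 - nbad))
  aln <- c(a = row100(26), b = row100(25), c = row100(0))
  s <- step3_missingness_filter(aln, 0.25)
  expect_identical(s$keep, c("b", "c"))  # 0.25 retained, 0.26 removed
  expect_equal(s$report$metric, 0.26)
})

test_that("occupancy labels reproduce the study percentages", {
  expect_equal(occupancy_filter(c(g = 30L), 30L, 41L)$occupancy_pct, 73L)
  expect_equal(occupancy_filter(c(g = 20L), 20L, 30L)$occupancy_pct, 67L)
  o <- occupancy_filter(c(g1 = 19L, g2 = 20L), 20L, 30L)
  expect_identical(o$keep, "g2")
  expect_error(occupancy_filter(c(g = 5L), 10L, 8L), "exceeds")
})

test_that("distance threshold statistics summarize per-cluster maxima", {
  mk <- function(p) c(a = strrep("A", 100),
                      b = paste0(strrep("C", p), strrep("A", 100 - p)))
  st <- distance_threshold_stats(list(A = mk(10), B = mk(20), C = mk(30)))
  expect_equal(st$mean, 20)
  expect_equal(st$median, 20)
  expect_equal(st$sd, 10)
  expect_warning(one <- distance_threshold_stats(list(A = mk(10))), "SD")
  expect_equal(one$sd, 0)
})

test_that("the pipeline report partitions every input record exactly once", {
  sim <- simulate_dataset(n_species = 10, n_genes = 4, n_codons = 80, seed = 3)
  res <- run_pipeline(sim$clusters, filter_params(min_samples = 2))
  n_input <- sum(vapply(sim$clusters, function(cl) length(cl$seq), integer(1)))
  expect_equal(nrow(res$report), n_input)
  expect_false(any(duplicated(res$report[, c("cluster_id", "sample_id")])))
  ## clean run with permissive parameters removes nothing
  clean <- simulate_dataset(n_species = 8, n_genes = 3, n_codons = 60,
                            contamination = NULL, seed = 4)
  res2 <- run_pipeline(clean$clusters,
                       filter_params(len_var_pct = 100, max_mean_dist = 100,
                                     max_missing_frac = 1, min_samples = 2))
  expect_true(all(res2$report$reason == "retained"))
  expect_equal(length(res2$alignments), 3L)
})

test_that("relaxing any single threshold never removes a survivor", {
  sim <- simulate_dataset(n_species = 10, n_genes = 3, n_codons = 80, seed = 8)
  base <- filter_params(len_var_pct = 30, max_mean_dist = 25,
                        max_missing_frac = 0.25, min_samples = 3)
  res0 <- run_pipeline(sim$clusters, base)
  kept0 <- res0$report[res0$report$reason == "retained",
                       c("cluster_id", "sample_id")]
  relaxed <- list(
    filter_params(60, 25, 0.25, 3), filter_params(30, 60, 0.25, 3),
    filter_params(30, 25, 0.60, 3), filter_params(30, 25, 0.25, 2))
  for (p in relaxed) {
    res1 <- run_pipeline(sim$clusters, p)
    kept1 <- res1$report[res1$report$reason == "retained",
                         c("cluster_id", "sample_id")]
    expect_true(all(paste(kept0$cluster_id, kept0$sample_id) %in%
                    paste(kept1$cluster_id, kept1$sample_id)))
  }
})

test_that("the alignment bookkeeping formula matches total sites / clusters", {
  s <- alignment_length_summary(4, 4 * 300)
  expect_equal(s$mean_length, 300)
  sim <- simulate_dataset(n_species = 8, n_genes = 3, n_codons = 50,
                          contamination = NULL, seed = 5)
  res <- run_pipeline(sim$clusters,
                      filter_params(min_samples = 2, max_mean_dist = 100))
  lens <- vapply(res$alignments, function(a) nchar(a[[1]]), integer(1))
  expect_equal(res$summary$total_sites, sum(lens))
  expect_equal(res$summary$mean_length, round(mean(lens), 2))
})
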