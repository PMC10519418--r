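test_that("RF distance satisfies the worked examples and metric properties", {
  t1 <- read_newick("((A,B),(C,D));")
  t2 <- read_newick("((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  ## four-taxon unrooted binary trees only reach 0 or 2
  for (i in 1:10) {
    a <- random_tree(LETTERS[1:4])
    b <- random_tree(LETTERS[1:4])
    expect_true(rf_distance(a, b) %in% c(0, 2))
  }
  ## symmetry and triangle inequality on random triples
  set.seed(31)
  for (i in 1:10) {
    x <- random_tree(letters[1:8])
    y <- random_tree(letters[1:8])
    z <- random_tree(letters[1:8])
    expect_equal(rf_distance(x, y), rf_distance(y, x))
    expect_lte(rf_distance(x, z), rf_distance(x, y) + rf_distance(y, z))
  }
})

test_that("unrooted RF equals the independent phangorn computation", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    a <- random_tree(letters[1:n])
    b <- random_tree(letters[1:n])
    expect_equal(rf_distance(a, b),
                 as.numeric(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
  }
})

test_that("leaf-set mismatches need pruning and enough shared leaves", {
  a <- random_tree(letters[1:8])
  b <- random_tree(letters[3:10])
  expect_error(rf_distance(a, b), "prune_to_common")
  expect_gte(rf_distance(a, b, prune_to_common = TRUE), 0)
  c1 <- random_tree(letters[1:5])
  c2 <- random_tree(letters[4:9])
  expect_error(rf_distance(c1, c2, prune_to_common = TRUE), "shared leaves")
})

test_that("clade recovery checks exact node leaf sets", {
  tr <- read_newick("((A,B),C);")
  expect_identical(clade_recovery(tr, list(c("A", "B"))), TRUE)
  expect_identical(clade_recovery(tr, list(c("A", "C"))), FALSE)
  expect_identical(clade_recovery(tr, list(c("A", "B", "C"))), TRUE) # root
  expect_error(clade_recovery(tr, list(c("A", "Z"))), "unknown leaf")
  ## every clade of a tree is recovered in the tree itself
  big <- random_tree(letters[1:12])
  sets <- orthosweep:::node_leaf_sets(big)
  internal <- sets[(13:(12 + big$Nnode))]
  expect_true(all(clade_recovery(big, internal)))
})

test_that("gene concordance factor counts decisive and concordant trees", {
  sp <- read_newick("((A,B),(C,D));")
  gts <- lapply(c("((A,B),(C,D));", "((A,B),(C,D));", "((A,C),(B,D));"),
                read_newick)
  g <- gene_concordance_factor(sp, gts)
  expect_equal(g$n_decisive, 3L)
  expect_equal(g$gcf_pct, 100 * 2 / 3)

  ## identical gene trees give 100 on every branch, independent of k
  sp8 <- random_tree(letters[1:8])
  for (k in c(1, 5)) {
    gg <- gene_concordance_factor(sp8, rep(list(sp8), k))
    expect_true(all(gg$gcf_pct == 100))
    expect_true(all(gg$n_decisive == k))
  }

  ## a gene tree missing all but one leaf of one side is not decisive
  sp4 <- read_newick("(((A,B),(C,D)),(E,F));")
  gt <- read_newick("((A,C),(D,E));") # only one of {A,B} present
  g2 <- gene_concordance_factor(sp4, list(gt))
  ab_row <- g2[g2$branch == "A,B", ]
  expect_equal(ab_row$n_decisive, 0L)
  expect_true(is.na(ab_row$gcf_pct))
})

test_that("quartet support tallies gene-tree quartet frequencies", {
  sp <- read_newick("((A,B),(C,D));")
  gts <- lapply(c("((A,B),(C,D));", "((A,B),(C,D));", "((A,C),(B,D));"),
                read_newick)
  q <- quartet_support(sp, gts, seed = 1)
  expect_equal(q$q1, 2 / 3)
  expect_equal(q$q2 + q$q3, 1 / 3)

  sp8 <- random_tree(letters[1:8])
  qq <- quartet_support(sp8, rep(list(sp8), 4), seed = 1)
  expect_true(all(qq$q1 == 1))

  ## exhaustive tallies equal a keep.tip-based enumeration oracle
  set.seed(77)
  sp6 <- random_tree(letters[1:6])
  gts6 <- lapply(1:5, function(i) random_tree(letters[1:6]))
  q6 <- quartet_support(sp6, gts6, max_quartets_per_branch = 10000, seed = 1)
  splits <- orthosweep:::branch_clusters(sp6)
  for (r in seq_len(nrow(q6))) {
    cl <- c(splits[[r]]$below, splits[[r]]$above)
    conc <- 0L
    tot <- 0L
    for (a in cl[[1]]) for (b in cl[[2]]) for (cc in cl[[3]]) for (d in cl[[4]])
      for (gt in gts6) {
        topo <- oracle_quartet(gt, a, b, cc, d)
        if (topo == 0L) next # unresolved quartets are skipped
        ## by construction the species tree pairs (a,b) against (c,d)
        expect_equal(oracle_quartet(sp6, a, b, cc, d), 1L)
        tot <- tot + 1L
        if (topo == 1L) conc <- conc + 1L
      }
    if (tot > 0) expect_equal(q6$q1[r], conc / tot)
  }
})

test_that("per-branch quartet sampling respects the cap and the seed", {
  sp <- random_tree(letters[1:12])
  gts <- lapply(1:4, function(i) random_tree(letters[1:12]))
  q_a <- quartet_support(sp, gts, max_quartets_per_branch = 5, seed = 9)
  q_b <- quartet_support(sp, gts, max_quartets_per_branch = 5, seed = 9)
  expect_identical(q_a, q_b)
  expect_true(all(q_a$n_quartets <= 5))
})
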