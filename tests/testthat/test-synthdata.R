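test_that("species-tree simulation is seeded, binary, and rescalable", {
  tr <- simulate_species_tree(30, seed = 4)
  expect_equal(length(tr$tip.label), 30L)
  expect_equal(tr$Nnode, 29L)
  expect_true(all(tr$edge.length > 0))
  tr2 <- simulate_species_tree(30, seed = 4)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  d <- simulate_species_tree(10, seed = 1, depth = 3)
  expect_equal(max(ape::node.depth.edgelength(d)), 3)
  m <- simulate_species_tree(10, seed = 1, min_internal = 1)
  internal <- m$edge[, 2] > 10
  expect_gte(min(m$edge.length[internal]), 1)
})

test_that("three-species shapes are the only rooted class and are seeded", {
  tr <- simulate_species_tree(3, seed = 9)
  expect_equal(tr$Nnode, 2L)
  gts <- simulate_gene_trees(tr, 5, seed = 2)
  gts_again <- simulate_gene_trees(tr, 5, seed = 2)
  expect_identical(vapply(gts, ape::write.tree, ""),
                   vapply(gts_again, ape::write.tree, ""))
})

test_that("gene-tree concordance follows the coalescent expectation at t = 10", {
  sp <- ape::read.tree(text = "((A:10.5,B:10.5):10,C:20.5);")
  gts <- simulate_gene_trees(sp, 300, seed = 5)
  conc <- mean(vapply(gts, function(g) {
    d <- ape::cophenetic.phylo(g)
    d["A", "B"] < d["A", "C"] & d["A", "B"] < d["B", "C"]
  }, logical(1)))
  expect_equal(conc, 1) # at t = 10 discordance is essentially impossible
})

test_that("codon simulation respects rate zero, frame, and sense codons", {
  sp <- simulate_species_tree(6, seed = 2, depth = 2)
  gt <- simulate_gene_trees(sp, 1, seed = 3)[[1]]
  cl0 <- simulate_codon_sequences(gt, 50, subst_rate = 0, seed = 4)
  expect_equal(length(unique(cl0$seq)), 1L)
  cl <- simulate_codon_sequences(gt, 50, subst_rate = 0.05, seed = 4)
  for (s in cl$seq) {
    expect_equal(nchar(s), 150L)
    expect_identical(check_and_translate(s)$status, "ok")
  }
})

test_that("artifact injection matches its manifest and forced outcomes", {
  sim <- simulate_dataset(n_species = 8, n_genes = 4, n_codons = 60,
                          contamination = NULL, seed = 6)
  ## all probabilities zero: output identical, manifest all "none"
  none <- contamination_spec(0, 0, 0, 0)
  inj0 <- inject_artifacts(sim$clusters, none, seed = 1)
  expect_identical(lapply(inj0$clusters, `[[`, "seq"),
                   lapply(sim$clusters, `[[`, "seq"))
  expect_true(all(inj0$manifest$artifact == "none"))

  ## forced frameshift: every record breaks the reading frame
  fs <- contamination_spec(0, 1, 0, 0)
  injf <- inject_artifacts(sim$clusters, fs, seed = 1)
  for (cl in injf$clusters)
    expect_true(all(nchar(cl$seq) %% 3L == 2L))

  ## forced masking: missingness equals mask_frac up to rounding
  mk <- contamination_spec(0, 0, 0, 1, mask_frac = 0.5)
  injm <- inject_artifacts(sim$clusters, mk, seed = 1)
  for (cl in injm$clusters)
    for (s in cl$seq) {
      frac <- nchar(gsub("[^N]", "", s)) / nchar(s)
      expect_equal(frac, 0.5, tolerance = 0.02)
    }
  expect_error(contamination_spec(0.5, 0.3, 0.2, 0.2), "sum")
})

test_that("injection is reproducible and independent of cluster order", {
  sim <- simulate_dataset(n_species = 8, n_genes = 4, n_codons = 60,
                          contamination = NULL, seed = 7)
  spec <- contamination_spec()
  a <- inject_artifacts(sim$clusters, spec, seed = 42)
  b <- inject_artifacts(sim$clusters, spec, seed = 42)
  expect_identical(a$manifest, b$manifest)
  ## per-cluster substreams: corrupting a subset matches the full run
  c_sub <- inject_artifacts(sim$clusters[2], spec, seed = 42)
  expect_identical(c_sub$clusters[[1]]$seq, b$clusters[[2]]$seq)
})
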