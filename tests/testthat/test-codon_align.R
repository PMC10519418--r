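test_that("ORF checking applies the standard code and trims terminal stops", {
  expect_equal(check_and_translate("ATGAAATAA"),
               list(status = "ok", detail = NA_integer_, protein = "MK"))
  r <- check_and_translate("ATGTAAAAA")
  expect_equal(r$status, "internal_stop")
  expect_equal(r$detail, 2L)
  expect_true(is.na(r$protein))
  expect_equal(check_and_translate("ATGAAAA")$status, "not_multiple_of_three")
  ## N-containing codons translate to X
  expect_equal(check_and_translate("ATGANA")$protein, "MX")
})

test_that("progressive alignment is deterministic, lossless, and gap-aware", {
  ident <- align_proteins(c(a = "MKV", b = "MKV"))
  expect_identical(unname(ident), c("MKV", "MKV"))

  a <- align_proteins(c(a = "MKVV", b = "MKV"))
  expect_equal(unique(nchar(a)), 4L)
  expect_equal(nchar(gsub("[^-]", "", a[["b"]])), 1L)
  expect_equal(nchar(gsub("[^-]", "", a[["a"]])), 0L)

  ## ungapping returns the inputs; rerunning is byte-identical
  set.seed(11)
  prots <- setNames(vapply(1:5, function(i) {
    cds <- random_cds(40)
    check_and_translate(cds)$protein
  }, ""), paste0("s", 1:5))
  al1 <- align_proteins(prots)
  al2 <- align_proteins(prots)
  expect_identical(al1, al2)
  expect_identical(gsub("-", "", al1, fixed = TRUE), prots)

  expect_warning(single <- align_proteins(c(x = "MKV")), "single")
  expect_identical(single, c(x = "MKV"))
  expect_error(align_proteins(character(0)))
})

test_that("column trimming equals the per-column rule applied independently", {
  expect_identical(trim_columns(c(a = "M", b = "M", c = "M", d = "M"),
                                0.2, 0.25)$retained, 1L)
  expect_length(trim_columns(c(a = "M", b = "-", c = "-", d = "-"),
                             0.2, 0.25)$retained, 0L)

  set.seed(5)
  rows <- setNames(vapply(1:10, function(i)
    paste(sample(c("A", "R", "N", "D", "X", "-"), 50, replace = TRUE),
          collapse = ""), ""), paste0("r", 1:10))
  tr <- trim_columns(rows, max_gap_frac = 0.3, min_conservation = 0.3)
  M <- do.call(rbind, strsplit(rows, ""))
  expected <- which(vapply(1:50, function(j) {
    col <- M[, j]
    if (mean(col == "-") > 0.3) return(FALSE)
    ng <- col[col != "-"]
    res <- ng[ng != "X"]
    if (length(res) == 0) return(FALSE)
    max(table(res)) / length(ng) >= 0.3
  }, logical(1)))
  expect_identical(tr$retained, expected)
})

test_that("back-translation maps residues to codons and gaps to ---", {
  expect_identical(unname(backtranslate(c(x = "MK"), 1:2, c(x = "ATGAAA"))),
                   "ATGAAA")
  expect_identical(unname(backtranslate(c(x = "M-K"), 1:3, c(x = "ATGAAA"))),
                   "ATG---AAA")
  expect_identical(unname(backtranslate(c(x = "MKV"), c(1L, 3L),
                                        c(x = "ATGAAAGTT"))), "ATGGTT")
  expect_error(backtranslate(c(x = "MM"), 1:2, c(x = "ATGAAA")), "match")
})

test_that("codon alignment composition: ungapped rows are retained codons in order", {
  set.seed(23)
  sim <- simulate_dataset(n_species = 8, n_genes = 3, n_codons = 60,
                          contamination = NULL, seed = 23)
  for (cl in sim$clusters) {
    al <- align_cluster(cl$seq)
    for (id in names(al$codon)) {
      row <- gsub("-", "", al$codon[[id]], fixed = TRUE)
      cds <- cl$seq[[id]]
      codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
      row_codons <- substring(row, seq(1, nchar(row), 3), seq(3, nchar(row), 3))
      ## the row is whole codons of the CDS, in order (a codon subsequence)
      ptr <- 0L
      for (rc in row_codons) {
        nxt <- which(codons[(ptr + 1L):length(codons)] == rc)[1]
        expect_false(is.na(nxt))
        ptr <- ptr + nxt
      }
      ## translating the codon row reproduces the trimmed protein row
      tr_aa <- vapply(seq(1, nchar(al$codon[[id]]), 3), function(s) {
        cod <- substr(al$codon[[id]], s, s + 2)
        if (cod == "---") "-" else check_and_translate(cod)$protein
      }, "")
      expect_identical(paste(tr_aa, collapse = ""), al$protein[[id]])
    }
  }
})
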