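test_that("stress classes follow the printed boundaries", {
  expect_equal(as.character(classifyStress(c(0.2, 1, 1.0001, 35, 35.1, 440))),
               c("freshwater", "freshwater", "brackish", "brackish",
                 "saline", "saline"))
  expect_error(classifyStress(0), "positive")
  expect_error(classifyStress(NA_real_), "finite")
})

test_that("rarefaction subsamples without replacement to even depth", {
  m <- matrix(c(60, 40, 10, 0, 100, 250), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  ae <- AsvExperiment(m)
  rr <- rarefyTable(ae, 100, seed = 1)
  expect_true(all(colSums(asvCounts(rr)) == 100))
  # exhaustive draw leaves a sample unchanged
  expect_equal(asvCounts(rarefyTable(ae, 110, seed = 1))[, "s1"], m[, "s1"])
  # depth 1: a single nonzero cell of value 1 per sample
  r1 <- asvCounts(rarefyTable(ae, 1, seed = 2))
  expect_true(all(colSums(r1) == 1) && all(colSums(r1 > 0) == 1))
  expect_error(rarefyTable(ae, 200), "s1")
})

test_that("rarefaction means match the hypergeometric expectation", {
  m <- matrix(c(60, 40), nrow = 2, dimnames = list(c("a", "b"), "s"))
  draws <- vapply(seq_len(2000), function(i)
    asvCounts(rarefyTable(AsvExperiment(m), 10, seed = i))["a", 1],
    numeric(1))
  expect_lt(abs(mean(draws) - 6), 0.5)  # E = 10 * 60/100
})

test_that("rarefaction is equivariant under taxon permutation", {
  m <- matrix(rpois(30, 30) + 1, nrow = 5,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
  perm <- c(4, 2, 5, 1, 3)
  a <- asvCounts(rarefyTable(AsvExperiment(m), 50, seed = 9))
  b <- asvCounts(rarefyTable(AsvExperiment(m[perm, ]), 50, seed = 9))
  expect_equal(sort(rownames(b)), sort(rownames(a)))
  expect_equal(colSums(b), colSums(a))
})

test_that("Hellinger transform is the root-relative-abundance map", {
  m <- matrix(c(1, 4, 4, 5, 0, 0), nrow = 3,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  h <- hellingerTransform(m)
  expect_equal(unname(h[, "s1"]), c(1 / 3, 2 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(h[, "s2"]), c(1, 0, 0))
  expect_equal(colSums(h^2), c(s1 = 1, s2 = 1), tolerance = 1e-12)
  expect_error(hellingerTransform(matrix(0, 2, 1,
    dimnames = list(NULL, "bad"))), "bad")
})

test_that("CLR rows are centered and match the closed form", {
  m <- matrix(c(1, 10), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  cl <- clrTransform(m, 1)
  # closed form: ln(2/sqrt(22)), ln(11/sqrt(22)) = -/+ 0.5 ln(11/2)
  expect_equal(unname(cl[, 1]), c(-1, 1) * 0.5 * log(11 / 2),
               tolerance = 1e-12)
  big <- matrix(rpois(200, 20), nrow = 20)
  expect_true(all(abs(colSums(clrTransform(big))) < 1e-9))
  expect_equal(unname(clrTransform(matrix(c(7, 7, 7), 3, 1))[, 1]),
               rep(0, 3))
  expect_error(clrTransform(m, 0), "pseudocount")
})

test_that("TSV and BIOM round-trips reproduce counts exactly", {
  m <- matrix(rpois(24, 8), nrow = 4,
              dimnames = list(paste0("ASV", 1:4), paste0("S", 1:6)))
  ae <- AsvExperiment(m, domain = "archaea")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeAsvTable(ae, tf)
  expect_equal(asvCounts(readAsvTable(tf, "archaea")), m)
  bf <- withr::local_tempfile(fileext = ".biom")
  writeBiomTable(ae, bf)
  expect_equal(unname(asvCounts(readBiomTable(bf))[rownames(m), colnames(m)]),
               unname(m))
})

test_that("QIIME2-style taxonomy strings are parsed into ranks", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ttaxon_string",
               paste0("ASV1\td__Bacteria; p__Proteobacteria; c__Gamma; ",
                      "o__; f__; g__; s__"),
               "ASV2\td__Archaea; p__Halobacterota"), tf)
  tx <- readTaxonomy(tf)
  expect_equal(tx$phylum, c("Proteobacteria", "Halobacterota"))
  expect_true(is.na(tx$class[2]))
  expect_true(is.na(tx$order[1]))  # empty rank prefix
})

test_that("AsvExperiment validity catches malformed input", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(AsvExperiment(m, domain = "fungi"), "domain")
  expect_error(AsvExperiment(m - 3), "non-negative")
})
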