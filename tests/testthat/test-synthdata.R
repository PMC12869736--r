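test_that("metadata matches the survey design and is deterministic", {
  cfg <- scenarioConfig(seed = 3)
  md <- generateMetadata(cfg)
  expect_equal(nrow(md), 20 * 10)
  expect_true(all(md$salinity >= 0.2 & md$salinity <= 440))
  expect_setequal(as.character(unique(md$stress)),
                  c("freshwater", "brackish", "saline"))
  expect_equal(length(unique(md$salinity)), length(unique(md$wetland)))
  expect_identical(md, generateMetadata(cfg))
  # within-wetland distances are far smaller than between-wetland ones
  d <- as.matrix(dist(cbind(md$lon, md$lat)))
  same <- outer(md$wetland, md$wetland, "==")
  expect_lt(max(d[same]), min(d[!same][d[!same] > 0.2]))
})

test_that("configuration errors are caught", {
  expect_error(scenarioConfig(depth = 0), "depth")
  expect_error(scenarioConfig(n_wetlands = 0), "positive")
  expect_error(scenarioConfig(
    planted_edges = data.frame(taxon_i = "B001", taxon_j = "Z999",
                               sign = 1, strength = 0.5)), "absent")
  expect_error(scenarioConfig(
    planted_edges = data.frame(taxon_i = "B001", taxon_j = "B002",
                               sign = 1, strength = 1.2)), "strength")
  expect_error(scenarioConfig(
    niche = data.frame(taxon = "B001", opt = 1, width = 0, amp = 1)),
    "width")
})

test_that("counts are compositionally closed and deterministic", {
  cfg <- scenarioConfig(n_taxa_bacteria = 40, n_taxa_archaea = 20,
                        depth = 5000, seed = 4)
  md <- generateMetadata(cfg)
  sim <- generateCounts(cfg, md)
  expect_true(all(colSums(asvCounts(sim$bacteria)) == 5000))
  expect_true(all(colSums(asvCounts(sim$archaea)) == 5000))
  sim2 <- generateCounts(cfg, md)
  expect_identical(asvCounts(sim$bacteria), asvCounts(sim2$bacteria))
})

test_that("a structureless scenario yields uncorrelated taxa", {
  cfg <- scenarioConfig(n_taxa_bacteria = 100, n_taxa_archaea = 0, seed = 5)
  sim <- generateCounts(cfg, generateMetadata(cfg))
  cc <- cor(t(asvCounts(sim$bacteria)), method = "spearman")
  expect_lt(median(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("a planted +0.8 coupling shows up in CLR correlation", {
  cfg <- scenarioConfig(
    n_taxa_bacteria = 100, n_taxa_archaea = 0,
    planted_edges = data.frame(taxon_i = "B001", taxon_j = "B002",
                               sign = 1, strength = 0.8), seed = 6)
  sim <- generateCounts(cfg, generateMetadata(cfg))
  X <- clrTransform(asvCounts(sim$bacteria))
  expect_gt(cor(X["B001", ], X["B002", ]), 0.4)
  # oracle: the latent (pre-multinomial) correlation carries the coupling
  expect_gt(cor(sim$latent[, "B001"], sim$latent[, "B002"]), 0.6)
})

test_that("ground-truth labels are exhaustive and exclusive", {
  cfg <- presetScenarios(90, 50)$paper_like
  sim <- generateCounts(cfg, generateMetadata(cfg))
  lab <- sim$truth$labels
  expect_setequal(names(lab),
                  c(rownames(asvCounts(sim$bacteria)),
                    rownames(asvCounts(sim$archaea))))
  expect_true(all(lab %in% c("env-driven", "space-driven", "coupled",
                             "neutral")))
})

test_that("presets cover the three study scenarios", {
  ps <- presetScenarios(90, 50)
  expect_setequal(names(ps), c("paper_like", "null", "sgh"))
  expect_null(ps$null$planted_edges)
  # archaeal niche optima bimodal on the log-salinity axis
  ni <- ps$paper_like$niche
  aopt <- ni$opt[startsWith(ni$taxon, "A")]
  expect_gt(sum(aopt < 0.5), 3)
  expect_gt(sum(aopt > 1.2), 3)
  expect_equal(sum(aopt >= 0.5 & aopt <= 1.2), 0)
  expect_true(ps$sgh$sgh)
})

test_that("paper_like richness shapes are recovered across replicates", {
  ok_b <- 0; ok_a <- 0; reps <- 10
  for (r in seq_len(reps)) {
    cfg <- presetScenarios(90, 50)$paper_like
    cfg$seed <- 500L + r
    md <- generateMetadata(cfg)
    sim <- generateCounts(cfg, md)
    ls <- log10(md$salinity)
    gb <- fitGradient(ls, richnessIndices(sim$bacteria)$richness)
    ga <- fitGradient(ls, richnessIndices(sim$archaea)$richness)
    sb <- summary(gb$models$ols)$coefficients
    ok_b <- ok_b + (sb[2, 1] < 0 && sb[2, 4] < 0.05)
    ok_a <- ok_a + (ga$best %in% c("spline", "piecewise"))
  }
  expect_gte(ok_b / reps, 0.9)
  expect_gte(ok_a / reps, 0.9)
})

test_that("scenario outputs round-trip through plain-text files", {
  dir <- withr::local_tempdir()
  cfg <- scenarioConfig(n_taxa_bacteria = 15, n_taxa_archaea = 8,
                        depth = 500, seed = 7)
  sim <- generateCounts(cfg, generateMetadata(cfg))
  paths <- writeScenario(sim, cfg, dir)
  expect_true(all(file.exists(paths)))
  back <- readAsvTable(paths["bacteria"], "bacteria")
  expect_equal(asvCounts(back), asvCounts(sim$bacteria))
})
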