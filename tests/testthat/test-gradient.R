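test_that("model selection prefers OLS on linear data", {
  set.seed(51)
  x <- runif(200, 0, 4)
  y <- 2 - x + rnorm(200, 0, 0.1)
  g <- fitGradient(x, y, x_is_log10_psu = FALSE)
  expect_equal(g$best, "ols")
  expect_lt(abs(coef(g$models$ols)[2] + 1), 0.05)
  # constant response: flat OLS, piecewise never selected
  gc <- fitGradient(x, rep(3, 200), x_is_log10_psu = FALSE)
  expect_equal(gc$best, "ols")
})

test_that("segmented search recovers a planted breakpoint", {
  set.seed(52)
  x <- runif(200, 0, 4)
  y <- ifelse(x < 2, -0.5 * x, -1 - 2 * (x - 2)) + rnorm(200, 0, 0.1)
  g <- fitGradient(x, y, x_is_log10_psu = FALSE)
  expect_true(g$best %in% c("piecewise", "spline"))
  expect_lt(abs(g$models$breakpoint - 2), 0.2)
  pw <- g$fits[g$fits$model == "piecewise", ]
  expect_true(pw$supported)
  expect_lt(pw$AIC, g$fits$AIC[g$fits$model == "ols"])
  # breakpoints reported on both scales when x is log10(psu)
  g2 <- fitGradient(x, y, x_is_log10_psu = TRUE)
  pw2 <- g2$fits[g2$fits$model == "piecewise", ]
  expect_equal(pw2$breakpoint_psu, 10^pw2$breakpoint, tolerance = 1e-9)
})

test_that("taxon responders rank deterministic monotone taxa first", {
  set.seed(53)
  sal <- 10^runif(60, -0.7, 2.6)
  m <- matrix(rep(50, 20 * 60), nrow = 20,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:60)))
  up <- 10 + 100 * (log10(sal) + 1)
  m["t1", ] <- up            # relative abundance strictly increasing
  m["t2", ] <- 600 - up      # complementary: strictly decreasing
  tr <- taxonResponders(m, sal, top_k = 5)
  expect_equal(tr$top_positive$taxon[1], "t1")
  expect_equal(tr$top_positive$rho[1], 1, tolerance = 1e-9)
  expect_equal(tr$top_negative$taxon[1], "t2")
  expect_true(all(tr$table$q >= tr$table$p - 1e-15, na.rm = TRUE))
})

test_that("taxon responders control FDR on null communities", {
  cfg <- scenarioConfig(n_taxa_bacteria = 200, n_taxa_archaea = 0,
                        seed = 54)
  sim <- generateCounts(cfg, generateMetadata(cfg))
  tr <- taxonResponders(sim$bacteria, sampleData(sim$bacteria)$salinity)
  expect_lte(mean(tr$table$q < 0.05, na.rm = TRUE), 0.05)
})

test_that("random-forest screening keeps the real driver, drops noise", {
  set.seed(55)
  ok <- 0
  for (r in 1:3) {
    pr <- data.frame(A = rnorm(150), B = rnorm(150), C = rnorm(150),
                     D = rnorm(150), E = rnorm(150))
    y <- pr$A + rnorm(150, 0, 0.3)
    rf <- rfScreen(pr, y, n_trees = 200, n_perm = 49, seed = r)
    ok <- ok + (("A" %in% rf$retained) &&
                rf$importance$variable[rf$importance$rank == 1] == "A")
  }
  expect_equal(ok, 3)
  # a constant predictor has zero importance
  pr2 <- data.frame(A = rnorm(100), K = rep(1, 100))
  rf2 <- rfScreen(pr2, rnorm(100), n_trees = 100, n_perm = 19, seed = 3)
  expect_equal(rf2$importance$importance[rf2$importance$variable == "K"], 0)
})

test_that("mixed-model R2 separates fixed and random contributions", {
  set.seed(56)
  g <- rep(1:20, each = 10)
  # no group structure: conditional ~= marginal
  x <- rnorm(200)
  y <- x + rnorm(200, 0, 0.5)
  r1 <- lmmAssoc(y, data.frame(x = x), g)
  expect_lt(abs(r1$R2["conditional"] - r1$R2["marginal"]), 0.02)
  # strong group intercepts, no fixed signal: conditional >> marginal
  y2 <- rnorm(20, 0, 2)[g] + rnorm(200, 0, 0.5)
  r2 <- lmmAssoc(y2, data.frame(x = rnorm(200)), g)
  expect_gt(r2$R2["conditional"] - r2$R2["marginal"], 0.3)
  # planted slope is detected decisively
  y3 <- x + rnorm(200, 0, 0.1) + rnorm(20, 0, 0.3)[g]
  r3 <- lmmAssoc(y3, data.frame(x = x, junk = rnorm(200)), g)
  expect_lt(r3$coefficients$p[r3$coefficients$predictor == "x"], 1e-3)
})

test_that("Fisher's C and the basis set follow the d-separation rules", {
  expect_error(fisherC(numeric(0)))
  fc <- fisherC(c(0.5, 0.5))
  expect_equal(fc$C, -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$df, 4)
  set.seed(57)
  n <- 300
  d <- data.frame(x = rnorm(n))
  d$m <- 0.8 * d$x + rnorm(n, 0, 0.5)
  d$y <- 0.8 * d$m + rnorm(n, 0, 0.5)
  sem <- piecewiseSem(list(m ~ x, y ~ m), d)
  expect_equal(nrow(sem$claims), 1)          # x -- y | m
  expect_equal(sem$df, 2)
  expect_true(sem$goodness_ok)
  # standardized coefficient ~ true partial correlation structure
  cf <- sem$coefficients
  expect_lt(abs(cf$std_estimate[cf$response == "m"] -
                cor(d$x, d$m)), 0.05)
  # effects decompose: total effect of x on y is the path product
  ef <- sem$effects
  xy <- ef[ef$of == "x" & ef$on == "y", ]
  expect_equal(xy$direct, 0)
  expect_equal(xy$total,
               cf$std_estimate[cf$response == "m"] *
               cf$std_estimate[cf$response == "y"], tolerance = 1e-9)
})

test_that("SEM rejects cycles and flags saturated models", {
  d <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_error(piecewiseSem(list(a ~ b, b ~ a), d), "cyclic")
  sat <- piecewiseSem(list(b ~ a, c ~ a + b), d)
  expect_true(sat$saturated)
  expect_equal(sat$df, 0)
})

test_that("standardized paths are invariant to affine rescaling", {
  set.seed(58)
  n <- 200
  d <- data.frame(x = rnorm(n))
  d$m <- d$x + rnorm(n)
  d$y <- d$m + rnorm(n)
  s1 <- piecewiseSem(list(m ~ x, y ~ m + x), d)
  d2 <- transform(d, x = 100 * x - 3, y = 0.01 * y + 7)
  s2 <- piecewiseSem(list(m ~ x, y ~ m + x), d2)
  expect_equal(s1$coefficients$std_estimate, s2$coefficients$std_estimate,
               tolerance = 1e-9)
})

test_that("SEM composites are first principal components of indicators", {
  set.seed(59)
  n <- 150
  base <- rnorm(n)
  d <- data.frame(i1 = base + rnorm(n, 0, 0.2),
                  i2 = base + rnorm(n, 0, 0.2),
                  y = base + rnorm(n, 0, 0.5))
  sem <- piecewiseSem(list(y ~ comp), d,
                      composites = list(comp = c("i1", "i2")))
  expect_gt(abs(cor(sem$data$comp, base)), 0.9)
  expect_gt(cor(sem$data$comp, d$i1), 0)  # sign-aligned
})
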