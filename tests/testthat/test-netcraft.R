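test_that("taxon filtering applies strict printed thresholds", {
  # 5 taxa x 10 samples with prevalences 10/20/30/90/100 %
  m <- rbind(t1 = c(200, rep(0, 9)),
             t2 = c(150, 80, rep(0, 8)),
             t3 = c(90, 80, 70, rep(0, 7)),
             t4 = c(rep(30, 9), 0),
             t5 = rep(25, 10))
  colnames(m) <- paste0("s", 1:10)
  kept <- rownames(asvCounts(filterTaxa(AsvExperiment(m), 0.2, 100)))
  expect_equal(kept, c("t3", "t4", "t5"))  # 20% prevalence excluded (strict)
  # near-zero thresholds keep everything observed
  expect_equal(nrow(filterTaxa(AsvExperiment(m), 1e-9, 0)), 5)
  expect_error(filterTaxa(AsvExperiment(m), 0.999, 1e9), "no taxa")
})

test_that("MB+StARS recovers a small planted graph with correct signs", {
  inst <- plantedPrecisionInstance(p = 25, n = 150, density = 0.08,
                                   seed = 21)
  net <- inferNetwork(inst$counts, stars_B = 30, seed = 1)
  ed <- edgeTable(net)
  expect_gt(nrow(ed), 3)
  ij <- which(inst$adjacency & upper.tri(inst$adjacency), arr.ind = TRUE)
  tkey <- paste(pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2]))
  ei <- match(ed$from, rownames(inst$counts))
  ej <- match(ed$to, rownames(inst$counts))
  ekey <- paste(pmin(ei, ej), pmax(ei, ej))
  tp <- sum(ekey %in% tkey)
  prec <- tp / nrow(ed); rec <- tp / nrow(ij)
  expect_gt(2 * prec * rec / (prec + rec), 0.6)
  hit <- ekey %in% tkey
  trueSign <- inst$signs[cbind(ei, ej)][hit]
  expect_gt(mean(sign(ed$weight[hit]) == trueSign), 0.85)
  # provenance is complete
  pv <- provenance(net)
  expect_true(all(c("method", "lambda_path", "lambda_selected", "stars_B",
                    "stars_beta", "subsample_size", "seed") %in% names(pv)))
})

test_that("inference is deterministic and sample-order invariant", {
  inst <- plantedPrecisionInstance(p = 15, n = 80, density = 0.1, seed = 22)
  n1 <- inferNetwork(inst$counts, stars_B = 15, seed = 5)
  n2 <- inferNetwork(inst$counts, stars_B = 15, seed = 5)
  expect_identical(edgeTable(n1), edgeTable(n2))
  perm <- sample(ncol(inst$counts))
  n3 <- inferNetwork(inst$counts[, perm], stars_B = 15, seed = 5)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_identical(key(edgeTable(n3)), key(edgeTable(n1)))
})

test_that("raising the StARS instability target never prunes edges", {
  inst <- plantedPrecisionInstance(p = 15, n = 100, density = 0.1, seed = 23)
  key <- function(net) {
    e <- edgeTable(net)
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  loose <- inferNetwork(inst$counts, stars_B = 15, stars_beta = 0.1, seed = 6)
  tight <- inferNetwork(inst$counts, stars_B = 15, stars_beta = 0.02, seed = 6)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("the graphical-lasso variant enriches for planted edges", {
  inst <- plantedPrecisionInstance(p = 12, n = 200, density = 0.12,
                                   value = 0.5, seed = 24)
  net <- inferNetwork(inst$counts, method = "glasso", nlambda = 15,
                      stars_B = 15, seed = 7)
  ed <- edgeTable(net)
  expect_gt(nrow(ed), 0)
  ij <- which(inst$adjacency & upper.tri(inst$adjacency), arr.ind = TRUE)
  tkey <- paste(pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2]))
  ei <- match(ed$from, rownames(inst$counts))
  ej <- match(ed$to, rownames(inst$counts))
  ekey <- paste(pmin(ei, ej), pmax(ei, ej))
  prec <- mean(ekey %in% tkey)
  rec <- sum(ekey %in% tkey) / length(tkey)
  expect_gte(rec, 0.5)
  expect_gte(prec, 2 * length(tkey) / choose(12, 2))  # beats chance 2x
})

test_that("habitat sub-networks are induced subgraphs under strict rules", {
  set.seed(25)
  m <- matrix(rpois(20 * 30, 120), nrow = 20,
              dimnames = list(sprintf("B%03d", 1:20), paste0("s", 1:30)))
  # taxon B001 present in exactly 30% of habitat samples: excluded
  m["B001", ] <- 0
  m["B001", 1:3] <- 500
  md <- data.frame(stress = rep(c("freshwater", "saline"), c(10, 20)),
                   row.names = paste0("s", 1:30))
  ae <- AsvExperiment(m, md)
  full <- EcoNetwork(data.frame(from = c("B001", "B002"),
                                to = c("B002", "B003"), weight = 0.5),
                     nodes = rownames(m))
  sub <- extractSubnetwork(full, ae, "freshwater")
  expect_false("B001" %in% igraph::V(netGraph(sub))$name)
  expect_true(all(igraph::V(netGraph(sub))$name %in%
                  igraph::V(netGraph(full))$name))
  ed <- edgeTable(sub)
  expect_true(all(paste(ed$from, ed$to) %in%
                  paste(edgeTable(full)$from, edgeTable(full)$to)))
  expect_error(extractSubnetwork(full, ae, "brackish"), "no samples")
})

test_that("EcoNetwork validity enforces sign-weight coherence", {
  g <- igraph::make_graph(~ a - b)
  g <- igraph::set_edge_attr(g, "weight", value = -0.5)
  g <- igraph::set_edge_attr(g, "sign", value = "+")
  expect_error(new("EcoNetwork", graph = g, provenance = list()), "sign")
})
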