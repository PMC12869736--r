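#' Scenario configuration for the synthetic community generator
#'
#' Builds and validates the configuration driving [generateMetadata()] and
#' [generateCounts()]. The generator emulates a lakeshore wetland survey
#' design: `n_wetlands` sites spanning a salinity gradient, each with
#' `n_replicates` composite soil samples, two amplicon domains (bacteria,
#' archaea), multinomial count draws at a fixed sequencing depth, Gaussian
#' salinity niches on the log10(psu) axis, spatially autocorrelated taxa,
#' and planted taxon-taxon couplings realised as shared latent Gaussian
#' factors (pairwise latent correlation equal to the coupling strength).
#'
#' @param n_wetlands,n_replicates survey design (default 20 x 10 = 200
#'   samples).
#' @param n_taxa_bacteria,n_taxa_archaea taxa per domain.
#' @param depth reads per sample (multinomial total).
#' @param salinity_range numeric length-2, psu; wetland salinities are
#'   spread log-uniformly across it.
#' @param planted_edges data.frame with columns `taxon_i`, `taxon_j`,
#'   `sign` (+1/-1) and `strength` in (0, 1); each taxon may appear in at
#'   most one planted edge.
#' @param niche data.frame with columns `taxon`, `opt` (optimum on log10
#'   psu), `width` (> 0, log10 units), `amp` (latent log-abundance gain at
#'   the optimum) and optionally `base` (flat latent offset, default 0;
#'   strongly negative values make a taxon a habitat specialist that is
#'   effectively absent away from its optimum). Taxa not listed respond
#'   flatly to salinity.
#' @param spatial_taxa character vector of taxa receiving a spatially
#'   autocorrelated latent field (exponential covariance, range
#'   `spatial_range` km, sd `spatial_sd`).
#' @param spatial_range,spatial_sd spatial field parameters.
#' @param noise_sd latent log-scale iid dispersion.
#' @param sgh logical; if `TRUE`, planted coupling strengths scale with the
#'   wetland's standardized stress level (0 at the freshest site, the
#'   configured strength at the most saline) — the stress-gradient-
#'   hypothesis scenario.
#' @param facilitation `NULL`, or `list(strength, boost_strength, boost,
#'   suppress, noise_sd, sample_sd, threshold)`: a facilitation/stress
#'   factor F = standardized log10(salinity) + N(0, noise_sd) per wetland
#'   plus N(0, sample_sd) microsite variation per sample; it adds
#'   `boost_strength * F` (default `strength`) to the latent abundance of
#'   `boost` taxa and subtracts `strength * max(F - threshold, 0)`
#'   (one-sided: stress suppresses above the threshold, default -0.6, but
#'   does not reward below it) from `suppress` taxa, planting a
#'   network-mediated (rather than directly salinity-driven) richness
#'   response with a stress threshold.
#' @param within_wetland_sd relative within-wetland heterogeneity of the
#'   soil variables (replicate-level noise; salinity itself is per-wetland).
#' @param seed default RNG seed for this scenario.
#' @return A validated `ScenarioConfig` (named list, class
#'   `"ScenarioConfig"`).
#' @export
scenarioConfig <- function(n_wetlands = 20, n_replicates = 10,
                           n_taxa_bacteria = 120, n_taxa_archaea = 60,
                           depth = 10000, salinity_range = c(0.2, 440),
                           planted_edges = NULL, niche = NULL,
                           spatial_taxa = character(),
                           spatial_range = 200, spatial_sd = 1,
                           noise_sd = 1, sgh = FALSE, facilitation = NULL,
                           within_wetland_sd = 0.1, seed = 1L) {
  cfg <- list(n_wetlands = as.integer(n_wetlands),
              n_replicates = as.integer(n_replicates),
              n_taxa_bacteria = as.integer(n_taxa_bacteria),
              n_taxa_archaea = as.integer(n_taxa_archaea),
              depth = as.integer(depth), salinity_range = salinity_range,
              planted_edges = planted_edges, niche = niche,
              spatial_taxa = spatial_taxa, spatial_range = spatial_range,
              spatial_sd = spatial_sd, noise_sd = noise_sd, sgh = sgh,
              facilitation = facilitation,
              within_wetland_sd = within_wetland_sd, seed = as.integer(seed))
  class(cfg) <- "ScenarioConfig"
  validateScenario(cfg)
  cfg
}

validateScenario <- function(cfg) {
  stopifnotMsg(cfg$n_wetlands > 0 && cfg$n_replicates > 0 &&
               cfg$n_taxa_bacteria > 0 && cfg$n_taxa_archaea >= 0,
               "counts in the scenario configuration must be positive")
  stopifnotMsg(cfg$depth > 0, "sequencing depth must be positive")
  stopifnotMsg(length(cfg$salinity_range) == 2 &&
               all(cfg$salinity_range > 0) && diff(cfg$salinity_range) > 0,
               "salinity_range must be an increasing positive pair (psu)")
  pe <- cfg$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    stopifnotMsg(all(c("taxon_i", "taxon_j", "sign", "strength") %in% names(pe)),
                 "planted_edges needs taxon_i/taxon_j/sign/strength")
    stopifnotMsg(all(pe$strength > 0 & pe$strength < 1),
                 "coupling strengths must lie in (0, 1)")
    stopifnotMsg(all(pe$sign %in% c(-1, 1)), "edge sign must be +1 or -1")
    ids <- c(pe$taxon_i, pe$taxon_j)
    stopifnotMsg(!anyDuplicated(ids),
                 "each taxon may appear in at most one planted edge")
    stopifnotMsg(all(ids %in% scenarioTaxa(cfg)),
                 "planted edge references a taxon absent from the scenario")
  }
  if (!is.null(cfg$niche) && nrow(cfg$niche))
    stopifnotMsg(all(cfg$niche$width > 0), "niche widths must be positive")
  invisible(TRUE)
}

scenarioTaxa <- function(cfg) {
  c(sprintf("B%03d", seq_len(cfg$n_taxa_bacteria)),
    if (cfg$n_taxa_archaea > 0) sprintf("A%03d", seq_len(cfg$n_taxa_archaea)))
}

#' Generate per-sample metadata for a scenario
#'
#' One salinity value per wetland (replicates share it), spread
#' log-uniformly over the configured range so that all three stress classes
#' are represented when the range spans them; wetland coordinates scattered
#' over a Tibetan-Plateau-like extent with replicates clustered within
#' ~1 km; nine soil variables plus climate generated with stated loadings
#' on log10(salinity) plus independent noise.
#'
#' @param config a [scenarioConfig()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return data.frame with one row per sample: `sample_id`, `wetland`,
#'   `replicate`, `lon`, `lat`, `elevation`, `salinity`, `stress`, the soil
#'   variables (`pH`, `DOC`, `DON`, `NO3`, `NH4`, `TC`, `TN`, `TK`, `TP`)
#'   and climate (`MAT`, `MAP`).
#' @export
generateMetadata <- function(config, seed = config$seed) {
  validateScenario(config)
  set.seed(seed)
  nw <- config$n_wetlands; nr <- config$n_replicates
  lr <- log10(config$salinity_range)
  # even log-spacing with jitter keeps all stress classes covered
  sal_log <- seq(lr[1], lr[2], length.out = nw)
  if (nw > 2) {
    step <- diff(sal_log[1:2])
    sal_log[2:(nw - 1)] <- sal_log[2:(nw - 1)] +
      runif(nw - 2, -0.3, 0.3) * step
  }
  sal <- pmin(pmax(10^sal_log, config$salinity_range[1]),
              config$salinity_range[2])
  wet_lon <- runif(nw, 79.8, 91.1)
  wet_lat <- runif(nw, 28.6, 33.5)
  wet_elev <- runif(nw, 4224, 5100)
  z <- as.numeric(scale(log10(sal)))
  wsd <- config$within_wetland_sd
  wet <- rep(seq_len(nw), each = nr)
  n <- nw * nr
  jitter2 <- function(mu, sd_between, sd_within) {
    rep(mu + rnorm(nw, 0, sd_between), each = nr) + rnorm(n, 0, sd_within)
  }
  md <- data.frame(
    sample_id = sprintf("W%02dR%02d", wet, rep(seq_len(nr), nw)),
    wetland = sprintf("W%02d", wet),
    replicate = rep(seq_len(nr), nw),
    lon = rep(wet_lon, each = nr) + rnorm(n, 0, 0.004),
    lat = rep(wet_lat, each = nr) + rnorm(n, 0, 0.004),
    elevation = rep(wet_elev, each = nr),
    salinity = rep(sal, each = nr),
    pH  = jitter2(8.2 + 0.30 * z, 0.40, 0.25 * wsd * 3),
    DOC = exp(jitter2(4.0 - 0.20 * z, 0.30, 0.3 * wsd * 3)),
    DON = exp(jitter2(2.0 - 0.15 * z, 0.30, 0.3 * wsd * 3)),
    NO3 = exp(jitter2(1.0 + 0.00 * z, 0.40, 0.4 * wsd * 3)),
    NH4 = exp(jitter2(1.5 + 0.25 * z, 0.35, 0.35 * wsd * 3)),
    TC  = exp(jitter2(3.0 - 0.10 * z, 0.25, 0.25 * wsd * 3)),
    TN  = exp(jitter2(0.8 - 0.10 * z, 0.25, 0.25 * wsd * 3)),
    TK  = exp(jitter2(2.8 + 0.05 * z, 0.20, 0.2 * wsd * 3)),
    TP  = exp(jitter2(0.5 + 0.00 * z, 0.25, 0.25 * wsd * 3)),
    MAT = jitter2(-1.5, 0.8, 0),
    MAP = jitter2(420, 60, 0),
    stringsAsFactors = FALSE
  )
  md$MAT <- md$MAT - 1.2 * (md$lat - mean(md$lat))
  md$MAP <- md$MAP - 20 * (md$lon - mean(md$lon))
  md$stress <- classifyStress(md$salinity)
  rownames(md) <- md$sample_id
  cls <- unique(md$stress)
  if (length(cls) < 3)
    warning("salinity range does not cover all three stress classes: ",
            paste(cls, collapse = ", "))
  md
}

#' Generate synthetic ASV count tables with planted ground truth
#'
#' Latent log-abundances are the sum of (i) a Gaussian niche response to
#' log10(salinity), (ii) an optional spatially correlated field with
#' exponential covariance over great-circle distances, (iii) shared-factor
#' couplings for the planted edges, (iv) an optional facilitation-factor
#' term, and (v) iid Gaussian noise. Counts are multinomial draws at the
#' configured depth, so every sample's row sum equals `config$depth`.
#'
#' @param config a [scenarioConfig()].
#' @param metadata output of [generateMetadata()].
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return `list(bacteria = AsvExperiment, archaea = AsvExperiment or NULL,
#'   truth = list(edges, niche, labels, facilitation, expected_pattern),
#'   latent = matrix)` — `latent` is the pre-multinomial log-abundance
#'   matrix (samples x taxa), kept for oracle checks.
#' @export
generateCounts <- function(config, metadata, seed = config$seed + 1L) {
  validateScenario(config)
  set.seed(seed)
  taxa <- scenarioTaxa(config)
  n <- nrow(metadata); p <- length(taxa)
  lsal <- log10(metadata$salinity)
  latent <- matrix(0, n, p, dimnames = list(metadata$sample_id, taxa))

  if (!is.null(config$niche) && nrow(config$niche)) {
    ni <- config$niche
    if (is.null(ni$base)) ni$base <- 0
    for (k in seq_len(nrow(ni))) {
      j <- match(ni$taxon[k], taxa)
      if (is.na(j)) stop("niche entry for unknown taxon ", ni$taxon[k])
      latent[, j] <- latent[, j] + ni$base[k] +
        ni$amp[k] * exp(-(lsal - ni$opt[k])^2 / (2 * ni$width[k]^2))
    }
  }

  fac <- config$facilitation
  Fw <- NULL
  if (!is.null(fac)) {
    zf <- as.numeric(scale(log10(metadata$salinity[!duplicated(metadata$wetland)])))
    Fw <- zf + rnorm(length(zf), 0, fac$noise_sd %||% 0.5)
    Fs <- Fw[match(metadata$wetland, unique(metadata$wetland))] +
      rnorm(n, 0, fac$sample_sd %||% 0.4)
    bs <- fac$boost_strength %||% fac$strength
    thr <- rep_len(fac$threshold %||% -0.6, length(fac$suppress))
    for (tx in fac$boost)
      latent[, tx] <- latent[, tx] + bs * Fs
    for (k in seq_along(fac$suppress))
      latent[, fac$suppress[k]] <- latent[, fac$suppress[k]] -
        fac$strength * pmax(Fs - thr[k], 0)
  }

  if (length(config$spatial_taxa)) {
    D <- haversineKm(metadata$lon, metadata$lat)
    K <- config$spatial_sd^2 * exp(-D / config$spatial_range)
    L <- t(chol(K + diag(1e-8, n)))
    Z <- matrix(rnorm(n * length(config$spatial_taxa)), n)
    fld <- L %*% Z
    latent[, config$spatial_taxa] <- latent[, config$spatial_taxa] + fld
  }

  # iid noise, overwritten by shared-factor construction for coupled taxa
  eps <- matrix(rnorm(n * p), n, p)
  pe <- config$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    stress01 <- (lsal - min(lsal)) / max(diff(range(lsal)), 1e-9)
    for (k in seq_len(nrow(pe))) {
      i <- match(pe$taxon_i[k], taxa); j <- match(pe$taxon_j[k], taxa)
      cs <- pe$strength[k] * if (config$sgh) stress01 else 1
      u <- rnorm(n)
      eps[, i] <- sqrt(cs) * u + sqrt(1 - cs) * eps[, i]
      eps[, j] <- pe$sign[k] * sqrt(cs) * u + sqrt(1 - cs) * eps[, j]
    }
  }
  latent <- latent + config$noise_sd * eps

  # each domain is sequenced separately (own primers), so counts are
  # drawn per domain at the full depth
  isB <- startsWith(taxa, "B")
  counts <- matrix(0L, p, n, dimnames = list(taxa, metadata$sample_id))
  for (dom in unique(isB)) {
    sub <- latent[, isB == dom, drop = FALSE]
    prob <- exp(sub - apply(sub, 1, max))
    prob <- prob / rowSums(prob)
    counts[isB == dom, ] <-
      apply(prob, 1, function(pr) rmultinom(1, config$depth, pr))
  }
  labels <- rep("neutral", p); names(labels) <- taxa
  if (length(config$spatial_taxa)) labels[config$spatial_taxa] <- "space-driven"
  if (!is.null(config$niche) && nrow(config$niche))
    labels[config$niche$taxon] <- "env-driven"
  if (!is.null(pe) && nrow(pe)) labels[c(pe$taxon_i, pe$taxon_j)] <- "coupled"

  truth <- list(
    edges = pe,
    niche = config$niche,
    labels = labels,
    facilitation = if (is.null(fac)) NULL else
      list(factor_by_wetland = Fw, factor_by_sample = Fs,
           strength = fac$strength),
    expected_pattern = attr(config, "expected_pattern")
  )

  bact <- AsvExperiment(counts[isB, , drop = FALSE], metadata, "bacteria")
  arch <- if (any(!isB))
    AsvExperiment(counts[!isB, , drop = FALSE], metadata, "archaea") else NULL
  list(bacteria = bact, archaea = arch, truth = truth, latent = latent)
}

#' Preset synthetic scenarios
#'
#' Three named scenarios with planted, recoverable structure:
#' \describe{
#'   \item{`paper_like`}{bacterial richness declining with salinity
#'     (stress-sensitive low-salinity niches suppressed by a facilitation
#'     factor that tracks salinity), a positively coupled halotolerant
#'     bacterial block whose cohesion rises with stress, and archaeal
#'     richness U-shaped on the log-salinity axis with a halophile block
#'     dominating above 35 psu.}
#'   \item{`null`}{no niches, no couplings, no spatial structure — every
#'     taxon iid log-normal; the negative control for false-positive
#'     checks.}
#'   \item{`sgh`}{positive couplings whose strength grows with the
#'     standardized stress level (stress-gradient-hypothesis pattern),
#'     carried by mildly halotolerant taxa.}
#' }
#'
#' @param n_taxa_bacteria,n_taxa_archaea,depth optional overrides applied
#'   to every preset (taxon-indexed structure is laid out within the first
#'   taxa, so sizes must be at least the preset defaults' structural
#'   blocks: 120/60 are the reference sizes).
#' @return named list of `ScenarioConfig` objects.
#' @export
presetScenarios <- function(n_taxa_bacteria = 120, n_taxa_archaea = 60,
                            depth = 10000) {
  B <- function(i) sprintf("B%03d", i)
  A <- function(i) sprintf("A%03d", i)
  nb <- n_taxa_bacteria; na_ <- n_taxa_archaea
  stopifnotMsg(nb >= 70 && na_ >= 50,
               "presets need at least 70 bacterial and 50 archaeal taxa")

  # paper_like: blocks scale with table size
  nSens <- round(nb / 3)                       # stress-sensitive bacteria
  nCoup <- max(10, round(nb / 4)) %/% 2 * 2    # coupled facilitated block
  sens <- B(seq_len(nSens))
  coup <- B(nSens + seq_len(nCoup))
  nMeso <- round(na_ * 0.2)                    # low-salinity archaea
  nHalo <- round(na_ * 0.5)                    # halophile block
  meso <- A(seq_len(nMeso))
  halo <- A(nMeso + seq_len(nHalo))
  set.seed(7041)  # fixed layout draws: niche placement is part of the preset
  niche_pl <- rbind(
    data.frame(taxon = sens, opt = runif(nSens, -0.7, 0.3),
               width = 0.7, amp = 0.5, base = 0),
    data.frame(taxon = meso, opt = runif(nMeso, -0.7, -0.3),
               width = 0.45, amp = 11.5, base = -9),
    data.frame(taxon = halo, opt = runif(nHalo, 1.8, 2.64),
               width = 0.5, amp = 11.5, base = -9)
  )
  edges_pl <- rbind(
    data.frame(taxon_i = coup[seq(1, nCoup, 2)],
               taxon_j = coup[seq(2, nCoup, 2)],
               sign = 1, strength = 0.9),
    data.frame(taxon_i = meso[seq_len(4) * 2 - 1],
               taxon_j = meso[seq_len(4) * 2],
               sign = 1, strength = 0.45)
  )
  paper_like <- scenarioConfig(
    n_taxa_bacteria = nb, n_taxa_archaea = na_, depth = depth,
    planted_edges = edges_pl, niche = niche_pl,
    facilitation = list(strength = 4.0, boost_strength = 1.2, boost = coup,
                        suppress = sens, noise_sd = 1.0, sample_sd = 0.4,
                        threshold = seq(-1.5, 1.2, length.out = nSens)),
    seed = 101L)
  attr(paper_like, "expected_pattern") <-
    list(bacteria = "linear-decline", archaea = "u-shaped")

  null_cfg <- scenarioConfig(
    n_taxa_bacteria = nb, n_taxa_archaea = na_, depth = depth, seed = 202L)
  attr(null_cfg, "expected_pattern") <- list(bacteria = "flat", archaea = "flat")

  nSgh <- max(10, round(nb / 6)) %/% 2 * 2
  sghTaxa <- B(seq_len(nSgh))
  sgh_cfg <- scenarioConfig(
    n_taxa_bacteria = nb, n_taxa_archaea = na_, depth = depth,
    planted_edges = data.frame(taxon_i = sghTaxa[seq(1, nSgh, 2)],
                               taxon_j = sghTaxa[seq(2, nSgh, 2)],
                               sign = 1, strength = 0.8),
    niche = data.frame(taxon = sghTaxa, opt = 2.0, width = 1.4, amp = 1.2),
    sgh = TRUE, seed = 303L)
  attr(sgh_cfg, "expected_pattern") <-
    list(bacteria = "cohesion-increasing", archaea = "flat")

  list(paper_like = paper_like, null = null_cfg, sgh = sgh_cfg)
}

#' Write scenario outputs to plain-text files
#'
#' Counts as TSV (samples as rows, taxa as columns), metadata as TSV,
#' ground truth as JSON, config as YAML.
#'
#' @param sim output of [generateCounts()].
#' @param config the scenario configuration used.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeScenario <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bacteria = file.path(dir, "counts_bacteria.tsv"),
    archaea = file.path(dir, "counts_archaea.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config.yaml"))
  writeAsvTable(sim$bacteria, paths["bacteria"])
  if (!is.null(sim$archaea)) writeAsvTable(sim$archaea, paths["archaea"])
  write.table(sampleData(sim$bacteria), paths["metadata"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- sim$truth; tr$labels <- as.list(tr$labels)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  cfg <- unclass(config)
  cfg$planted_edges <- if (is.null(cfg$planted_edges)) NULL else
    as.list(as.data.frame(cfg$planted_edges))
  cfg$niche <- if (is.null(cfg$niche)) NULL else as.list(as.data.frame(cfg$niche))
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}

#' Planted sparse-precision-matrix instance
#'
#' Ground-truth generator for network-recovery benchmarking: an
#' Erdos-Renyi support of the requested density with +/-`value`
#' off-diagonal precision entries, diagonal loaded to |lambda_min| + `pad`
#' (so the matrix is just positive definite and the partial correlations
#' stay as strong as the support permits), multivariate-normal latent
#' abundances, and multinomial counts at fixed depth.
#'
#' @param p taxa; @param n samples; @param density edge density in (0,1).
#' @param value magnitude of off-diagonal precision entries.
#' @param pad diagonal padding above |lambda_min|.
#' @param depth multinomial depth.
#' @param seed RNG seed.
#' @return list: `counts` (taxa x samples), `adjacency` (logical p x p),
#'   `signs` (sign of the true partial correlation on each true edge),
#'   `precision`, `latent`.
#' @export
plantedPrecisionInstance <- function(p = 50, n = 200, density = 0.1,
                                     value = 0.3, pad = 0.05,
                                     depth = 10000, seed = 1L) {
  set.seed(seed)
  A <- matrix(0, p, p)
  on <- sample(which(upper.tri(A)), round(density * p * (p - 1) / 2))
  A[on] <- sample(c(-value, value), length(on), TRUE)
  A <- A + t(A)
  diag(A) <- abs(min(eigen(A, TRUE, TRUE)$values)) + pad
  Sig <- solve(A)
  X <- matrix(rnorm(n * p), n, p) %*% chol(Sig)
  pr <- exp(X - apply(X, 1, max)); pr <- pr / rowSums(pr)
  cts <- apply(pr, 1, function(q) rmultinom(1, depth, q))
  rownames(cts) <- sprintf("B%03d", seq_len(p))
  colnames(cts) <- sprintf("S%03d", seq_len(n))
  list(counts = cts, adjacency = A != 0 & !diag(TRUE, p),
       signs = -sign(A), precision = A, latent = X)
}
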