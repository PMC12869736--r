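soilVars <- c("pH", "DOC", "DON", "NO3", "NH4", "TC", "TN", "TK", "TP")
climVars <- c("MAT", "MAP")

#' Run the full salinity-gradient analysis pipeline
#'
#' Orchestrates simulate (or load) -> rarefy -> alpha diversity -> beta
#' statistics -> taxon filtering -> network inference -> link-process
#' classification -> cohesion & fragility -> gradient fits -> driver
#' cascade (random-forest screen, mixed models). Every stochastic stage
#' receives a child seed derived from `seed`; a manifest records each
#' stage's parameters, dimensions and elapsed time.
#'
#' @param scenario preset name (`"paper_like"`, `"null"`, `"sgh"`) or a
#'   [scenarioConfig()]; alternatively pass `tables` directly.
#' @param tables optional `list(bacteria = AsvExperiment, archaea =
#'   AsvExperiment)` to analyse instead of simulating.
#' @param seed global seed.
#' @param n_taxa_bacteria,n_taxa_archaea,depth preset overrides (ignored
#'   when `scenario` is already a config or `tables` given).
#' @param filter_prevalence,filter_abundance global taxon filter (strict
#'   `>`; abundance is total reads).
#' @param network_args list of extra arguments for [inferNetwork()].
#' @param linkproc_args list: `env` columns, `alpha`, `n_perm` for
#'   [classifyLinks()].
#' @param use_biotic restrict cohesion to the biotic-classified subgraph.
#'   Default FALSE (cohesion from all inferred links, as in the original
#'   cohesion metric): under a spatially blocked survey design with strong
#'   environmental structuring the assembly filter legitimately assigns
#'   almost every link to space or environment, leaving a biotic subgraph
#'   too sparse to carry a community-level cohesion signal. When TRUE and
#'   the biotic subgraph is edgeless, the stage falls back to all links
#'   and flags it in the manifest.
#' @param beta_n_perm permutations for the beta-diversity tests.
#' @param run_linkproc,run_beta,run_fragility,run_cross_domain stage
#'   switches (all on by default; switch off for reduced runs).
#' @param outdir optional directory: stage outputs and the manifest are
#'   written as TSV/JSON.
#' @return a result bundle (list) with elements `tables`, `truth`,
#'   `alpha`, `beta`, `networks`, `links`, `cohesion`, `fragility`,
#'   `gradient`, `drivers`, `manifest`.
#' @export
runPipeline <- function(scenario = "paper_like", tables = NULL, seed = 1L,
                        n_taxa_bacteria = 120, n_taxa_archaea = 60,
                        depth = 10000,
                        filter_prevalence = 0.2, filter_abundance = 100,
                        network_args = list(), linkproc_args = list(),
                        use_biotic = FALSE, beta_n_perm = 999,
                        run_linkproc = TRUE, run_beta = TRUE,
                        run_fragility = TRUE, run_cross_domain = TRUE,
                        outdir = NULL) {
  manifest <- list(seed = seed, stages = list())
  tick <- function(name, params, expr) {
    t0 <- proc.time()[3]
    val <- force(expr)
    manifest$stages[[name]] <<- c(
      manifest$stages[[name]],
      list(params = params, elapsed_s = round(proc.time()[3] - t0, 2)))
    val
  }

  truth <- NULL
  if (is.null(tables)) {
    cfg <- if (inherits(scenario, "ScenarioConfig")) scenario else
      presetScenarios(n_taxa_bacteria, n_taxa_archaea, depth)[[scenario]]
    stopifnotMsg(!is.null(cfg), paste("unknown scenario:", scenario))
    sim <- tick("simulate",
                list(scenario = if (is.character(scenario)) scenario else
                     "custom", seed = childSeed(seed, "sim")),
      {
        md <- generateMetadata(cfg, seed = childSeed(seed, "simmeta"))
        generateCounts(cfg, md, seed = childSeed(seed, "simcounts"))
      })
    tables <- list(bacteria = sim$bacteria, archaea = sim$archaea)
    truth <- sim$truth
  }
  tables <- Filter(Negate(is.null), tables)
  md <- sampleData(tables[[1]])

  tables <- tick("rarefy", list(policy = "min-sample"), {
    lapply(tables, function(tb) {
      d <- min(colSums(asvCounts(tb)))
      rarefyTable(tb, d, seed = childSeed(seed, paste0("rarefy", domainTag(tb))))
    })
  })

  alpha <- tick("alpha", list(), lapply(tables, function(tb) {
    idx <- richnessIndices(tb)
    lsd <- lsdTest(idx$richness, md$stress)
    prs <- combn(levels(droplevels(md$stress)), 2, simplify = FALSE)
    dE <- lapply(prs, function(pr) {
      cd <- cohensD(idx$richness[md$stress == pr[1]],
                    idx$richness[md$stress == pr[2]])
      data.frame(group1 = pr[1], group2 = pr[2], d = cd$d,
                 magnitude = cd$magnitude, stars = cd$stars)
    })
    list(indices = idx, lsd = lsd, effect_sizes = do.call(rbind, dE),
         shared = sharedAsvFractions(tb, md$stress))
  }))

  beta <- if (run_beta) tick("beta", list(n_perm = beta_n_perm),
    lapply(tables, function(tb) {
      d <- brayCurtis(tb)
      list(permanova = permanovaTest(d, md$stress, beta_n_perm,
                                     childSeed(seed, "adonis")),
           anosim = anosimTest(d, md$stress, beta_n_perm,
                               childSeed(seed, "anosim")),
           mrpp = mrppTest(d, md$stress, beta_n_perm,
                           childSeed(seed, "mrpp")))
    })) else NULL

  filtered <- tick("filter",
    list(prevalence = filter_prevalence, abundance = filter_abundance),
    lapply(tables, function(tb)
      filterTaxa(tb, filter_prevalence, filter_abundance)))

  networks <- tick("network", network_args, lapply(names(filtered),
    function(dm) do.call(inferNetwork, c(
      list(filtered[[dm]], seed = childSeed(seed, paste0("net", dm))),
      network_args))))
  names(networks) <- names(filtered)

  joint <- NULL
  if (run_cross_domain && length(filtered) == 2) {
    jointCounts <- rbind(asvCounts(filtered$bacteria),
                         asvCounts(filtered$archaea))
    jointTab <- AsvExperiment(jointCounts, md, "multi")
    joint <- tick("network_joint", network_args,
      do.call(inferNetwork, c(list(jointTab,
        seed = childSeed(seed, "netjoint")), network_args)))
  }

  lpArgs <- modifyList(list(env = c(soilVars, climVars, "salinity"),
                            alpha = 0.05, n_perm = 199), linkproc_args)
  links <- NULL
  cohNets <- networks
  if (run_linkproc) {
    links <- tick("linkproc", lpArgs, lapply(names(networks), function(dm)
      classifyLinks(networks[[dm]], filtered[[dm]], env = lpArgs$env,
                    alpha = lpArgs$alpha, n_perm = lpArgs$n_perm,
                    seed = childSeed(seed, paste0("lp", dm)))))
    names(links) <- names(networks)
    if (use_biotic)
      cohNets <- lapply(names(networks), function(dm)
        bioticSubgraph(networks[[dm]], links[[dm]]))
    names(cohNets) <- names(networks)
  }

  cohesion <- tick("cohesion", list(use_biotic = use_biotic && run_linkproc), {
    out <- lapply(names(cohNets), function(dm) {
      pr <- cohesionProfile(cohNets[[dm]], tables[[dm]])
      ch <- cohesionTable(pr)
      # degenerate biotic subgraph (no links survive the assembly filter):
      # fall back to all-links cohesion, flagged in the manifest
      if (sd(ch$pos) == 0 && sd(ch$neg) == 0 &&
          !identical(cohNets[[dm]], networks[[dm]])) {
        manifest$stages$cohesion$fallback_all_links <<-
          c(manifest$stages$cohesion$fallback_all_links, dm)
        pr <- cohesionProfile(networks[[dm]], tables[[dm]])
      }
      pr
    })
    names(out) <- names(cohNets)
    if (!is.null(joint)) {
      jointTab <- AsvExperiment(rbind(asvCounts(tables$bacteria),
                                      asvCounts(tables$archaea)),
                                md, "multi")
      out$cross_domain <- crossDomainCohesion(joint, jointTab)
    }
    out
  })

  frag <- if (run_fragility) tick("fragility", list(strategy = "degree"),
    lapply(networks, function(nw)
      fragility(nw, "degree", seed = childSeed(seed, "frag")))) else NULL

  gradient <- tick("gradient", list(x = "log10(salinity)"), {
    lapply(names(tables), function(dm) {
      rich <- richnessIndices(tables[[dm]])$richness
      coh <- cohesionTable(cohesion[[dm]])
      list(richness = fitGradient(log10(md$salinity), rich),
           pos_cohesion = fitGradient(log10(md$salinity), coh$pos),
           neg_cohesion = fitGradient(log10(md$salinity), coh$neg),
           responders = taxonResponders(tables[[dm]], md$salinity))
    }) |> setNames(names(tables))
  })

  drivers <- tick("drivers", list(), {
    lapply(names(tables), function(dm) {
      rich <- richnessIndices(tables[[dm]])$richness
      coh <- cohesionTable(cohesion[[dm]])
      preds <- data.frame(
        salinity = log10(md$salinity),
        pos_cohesion = coh$pos, neg_cohesion = coh$neg,
        pH = md$pH, NH4 = log(md$NH4), DOC = log(md$DOC),
        MAT = md$MAT, MAP = md$MAP, elevation = md$elevation)
      preds <- preds[, vapply(preds, sd, 1) > 0, drop = FALSE]
      rf <- rfScreen(preds, rich, n_perm = 49,
                     seed = childSeed(seed, paste0("rf", dm)))
      kept <- rf$retained
      if (length(kept) < 2) kept <- rf$importance$variable[1:2]
      lmm <- lmmAssoc(rich, preds[, kept, drop = FALSE], md$wetland)
      semDat <- cbind(preds, richness = rich,
                      lon = md$lon, lat = md$lat, wetland = md$wetland)
      withCoh <- "pos_cohesion" %in% names(preds)
      semPaths <- c(
        list(MAT ~ lat + elevation, salinity ~ MAT, pH ~ salinity),
        if (withCoh) list(pos_cohesion ~ salinity,
                          richness ~ pos_cohesion + salinity + pH)
        else list(richness ~ salinity + pH))
      sem <- piecewiseSem(paths = semPaths, data = semDat,
                          random = "wetland")
      list(rf = rf, lmm = lmm, sem = sem)
    }) |> setNames(names(tables))
  })

  bundle <- list(tables = tables, truth = truth, metadata = md,
                 alpha = alpha, beta = beta, filtered = filtered,
                 networks = networks, joint_network = joint, links = links,
                 cohesion = cohesion, fragility = frag, gradient = gradient,
                 drivers = drivers, manifest = manifest)
  if (!is.null(outdir)) writeBundle(bundle, outdir)
  bundle
}

#' Identify each domain's strongest standardized diversity driver
#'
#' Returns, per domain, the predictor of the richness structural equation
#' with the largest |standardized path coefficient| (`from = "sem"`,
#' default), or the mixed-model predictor with the largest |standardized
#' estimate| (`from = "lmm"`).
#'
#' @param bundle output of [runPipeline()].
#' @param from `"sem"` or `"lmm"`.
#' @return named character vector, one top predictor per domain.
#' @export
driverHeadline <- function(bundle, from = c("sem", "lmm")) {
  from <- match.arg(from)
  vapply(bundle$drivers, function(dr) {
    if (from == "sem") {
      cf <- dr$sem$coefficients
      cf <- cf[cf$response == "richness", ]
      cf$predictor[which.max(abs(cf$std_estimate))]
    } else {
      cf <- dr$lmm$coefficients
      cf$predictor[which.max(abs(cf$estimate))]
    }
  }, character(1))
}

#' Summary tables from a pipeline result bundle
#'
#' Mirrors the study's reporting surfaces: per-class diversity comparisons
#' with LSD letters and Cohen's d stars, cohesion by class with effect
#' sizes, gradient fits with thresholds, and driver tables.
#'
#' @param bundle output of [runPipeline()].
#' @return list of tidy data.frames: `diversity`, `cohesion_by_class`,
#'   `gradient_fits`, `drivers`.
#' @export
reportBundle <- function(bundle) {
  md <- bundle$metadata
  div <- do.call(rbind, lapply(names(bundle$alpha), function(dm) {
    a <- bundle$alpha[[dm]]
    mns <- a$lsd$means
    data.frame(domain = dm, class = names(mns), mean_richness = unname(mns),
               letter = unname(a$lsd$letters[names(mns)]))
  }))
  cohcl <- do.call(rbind, lapply(names(bundle$cohesion), function(dm) {
    ch <- cohesionTable(bundle$cohesion[[dm]])
    do.call(rbind, lapply(split(seq_len(nrow(ch)), md$stress), function(ix)
      data.frame(domain = dm, class = as.character(md$stress[ix[1]]),
                 mean_pos = mean(ch$pos[ix]), mean_neg = mean(ch$neg[ix]))))
  }))
  grad <- do.call(rbind, lapply(names(bundle$gradient), function(dm) {
    do.call(rbind, lapply(names(bundle$gradient[[dm]])[1:3], function(rv) {
      g <- bundle$gradient[[dm]][[rv]]
      cbind(domain = dm, response = rv, best = g$best, g$fits)
    }))
  }))
  drv <- do.call(rbind, lapply(names(bundle$drivers), function(dm)
    cbind(domain = dm, bundle$drivers[[dm]]$lmm$coefficients)))
  list(diversity = div, cohesion_by_class = cohcl, gradient_fits = grad,
       drivers = drv)
}

writeBundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rep <- reportBundle(bundle)
  for (nm in names(rep))
    write.table(rep[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (dm in names(bundle$networks))
    write.table(edgeTable(bundle$networks[[dm]]),
                file.path(outdir, paste0("network_", dm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(outdir)
}
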