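#' Linear, segmented and spline fits along the stress gradient
#'
#' Fits (i) ordinary least squares, (ii) a single-breakpoint segmented
#' regression (profile grid search over interior quantiles of the
#' predictor, minimizing SSE; the searched breakpoint counts as one extra
#' parameter in its AIC), and (iii) a penalized cubic spline
#' (GCV-selected smoothness via mgcv) as the non-linear reference. The
#' best model is the lowest-AIC fit, with a 2-unit indifference band
#' favouring the simpler model (ols < piecewise < spline).
#'
#' @param x predictor (use log10(salinity) for salinity gradients spanning
#'   orders of magnitude).
#' @param y response.
#' @param x_is_log10_psu if `TRUE`, breakpoints are also reported
#'   back-transformed to psu.
#' @param grid_n breakpoint grid resolution.
#' @return list: `best` (model name), `fits` (data.frame: model, AIC, R2,
#'   p, breakpoint, breakpoint_psu, supported), `models` (the fitted
#'   objects).
#' @export
fitGradient <- function(x, y, x_is_log10_psu = TRUE, grid_n = 201) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stopifnotMsg(length(x) >= 10, "need at least 10 observations")
  tss <- sum((y - mean(y))^2)
  if (tss == 0)
    return(list(best = "ols",
                fits = data.frame(model = "ols", AIC = NA_real_, R2 = 0,
                                  p = 1, breakpoint = NA_real_,
                                  breakpoint_psu = NA_real_,
                                  supported = TRUE),
                models = list(ols = lm(y ~ x), piecewise = NULL,
                              spline = NULL, breakpoint = NA)))
  r2 <- function(fit) 1 - sum(resid(fit)^2) / tss

  ols <- lm(y ~ x)
  olsP <- if (tss == 0) 1 else summary(ols)$coefficients[2, 4]

  qs <- quantile(x, c(0.05, 0.95))
  grid <- seq(qs[1], qs[2], length.out = grid_n)
  grid <- grid[grid > min(x) & grid < max(x)]
  sse <- vapply(grid, function(cpt)
    sum(resid(lm(y ~ x + pmax(x - cpt, 0)))^2), numeric(1))
  bp <- grid[which.min(sse)]
  pw <- lm(y ~ x + pmax(x - bp, 0))
  pwSupported <- length(grid) > 0 && min(sse) < sum(resid(ols)^2) - 1e-12
  pwAIC <- AIC(pw) + 2  # + the searched breakpoint

  sp <- mgcv::gam(y ~ s(x), method = "GCV.Cp")
  spP <- tryCatch(summary(sp)$s.table[1, 4], error = function(e) NA_real_)

  fits <- data.frame(
    model = c("ols", "piecewise", "spline"),
    AIC = c(AIC(ols), if (pwSupported) pwAIC else Inf, AIC(sp)),
    R2 = c(r2(ols), if (pwSupported) r2(pw) else NA_real_, r2(sp)),
    p = c(olsP,
          if (pwSupported) summary(pw)$coefficients[3, 4] else NA_real_,
          spP),
    breakpoint = c(NA, if (pwSupported) bp else NA, NA),
    breakpoint_psu = c(NA,
      if (pwSupported && x_is_log10_psu) 10^bp else NA, NA),
    supported = c(TRUE, pwSupported, TRUE))
  minA <- min(fits$AIC)
  best <- fits$model[fits$AIC <= minA + 2 & fits$supported][1]
  list(best = best, fits = fits,
       models = list(ols = ols, piecewise = if (pwSupported) pw else NULL,
                     spline = sp, breakpoint = if (pwSupported) bp else NA))
}

#' Taxa most correlated with the stress gradient
#'
#' Per-taxon (optionally aggregated to a taxonomic rank) Spearman
#' correlation of relative abundance with salinity, BH-adjusted across
#' taxa, with the top-k positive and negative responders.
#'
#' @param x an [AsvExperiment-class] or counts matrix (taxa x samples).
#' @param salinity per-sample salinity (psu).
#' @param taxonomy optional data.frame from [readTaxonomy()]; with `rank`,
#'   counts are summed within that rank before correlating.
#' @param rank taxonomic rank column name in `taxonomy`.
#' @param top_k size of the top responder lists.
#' @return list: `table` (taxon, rho, p, q, sorted by rho), `top_positive`,
#'   `top_negative`.
#' @export
taxonResponders <- function(x, salinity, taxonomy = NULL, rank = "phylum",
                            top_k = 10) {
  cts <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  if (!is.null(taxonomy)) {
    grp <- taxonomy[[rank]][match(rownames(cts), taxonomy$taxon)]
    grp[is.na(grp)] <- "unclassified"
    cts <- rowsum(cts, grp)
  }
  rel <- sweep(cts, 2, pmax(colSums(cts), 1), "/")
  res <- t(apply(rel, 1, function(v) {
    if (sd(v) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(v, salinity, method = "spearman"))
    c(ct$estimate, ct$p.value)
  }))
  tab <- data.frame(taxon = rownames(cts), rho = res[, 1], p = res[, 2],
                    q = p.adjust(res[, 2], "BH"), row.names = NULL)
  tab <- tab[order(-tab$rho), ]
  neg <- tab[!is.na(tab$rho) & tab$rho < 0, ]
  list(table = tab,
       top_positive = head(tab[!is.na(tab$rho) & tab$rho > 0, ], top_k),
       top_negative = head(neg[order(neg$rho), ], top_k))
}

#' Random-forest screening of candidate drivers
#'
#' Regression forest of the response on all predictors; per-variable
#' permutation importance (%IncMSE), with significance from a
#' response-permutation null: the forest is refitted `n_perm` times on a
#' permuted response and p = (1 + #(null importance >= observed)) /
#' (n_perm + 1). Variables with p <= 0.05 form the retained set.
#'
#' @param predictors data.frame of candidate drivers.
#' @param response numeric response.
#' @param n_trees trees per forest.
#' @param n_perm response permutations.
#' @param seed RNG seed.
#' @return list: `importance` (variable, importance, p, retained, rank),
#'   `retained` (character vector).
#' @export
rfScreen <- function(predictors, response, n_trees = 300, n_perm = 99,
                     seed = 1L) {
  predictors <- as.data.frame(predictors)
  set.seed(seed)
  obs <- randomForest::randomForest(predictors, response, ntree = n_trees,
                                    importance = TRUE)
  impObs <- obs$importance[, "%IncMSE"]
  nullGe <- rep(0, length(impObs))
  for (b in seq_len(n_perm)) {
    fit <- randomForest::randomForest(predictors, sample(response),
                                      ntree = n_trees, importance = TRUE)
    nullGe <- nullGe + (fit$importance[, "%IncMSE"] >= impObs)
  }
  p <- (1 + nullGe) / (n_perm + 1)
  imp <- data.frame(variable = names(impObs), importance = unname(impObs),
                    p = unname(p), retained = unname(p <= 0.05),
                    row.names = NULL)
  imp$rank <- rank(-imp$importance, ties.method = "first")
  imp <- imp[order(imp$rank), ]
  list(importance = imp, retained = imp$variable[imp$retained])
}

#' Fisher's C statistic
#'
#' C = -2 sum ln p over a set of independence-claim p-values, with df =
#' 2k and the chi-square upper-tail p-value; the conventional goodness
#' rule is 0 < C/df < 2 with p > 0.05.
#'
#' @param pvals numeric vector of claim p-values in (0, 1].
#' @return list: `C`, `df`, `p`.
#' @export
fisherC <- function(pvals) {
  stopifnotMsg(length(pvals) > 0 && all(pvals > 0 & pvals <= 1),
               "claim p-values must lie in (0, 1]")
  C <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `p.adjust(..., "BH")`, the multiple-testing
#' correction used throughout the pipeline.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
adjustFDR <- function(p) p.adjust(p, "BH")

# Nakagawa marginal/conditional R2 for a random-intercept lmer fit
r2Nakagawa <- function(fit) {
  vf <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- sum(vc$vcov[vc$grp != "Residual"])
  ve <- vc$vcov[vc$grp == "Residual"]
  c(marginal = vf / (vf + vr + ve), conditional = (vf + vr) / (vf + vr + ve))
}

#' Mixed-model associations with a grouping random factor
#'
#' Random-intercept linear mixed model of the (standardized) response on
#' standardized predictors, with per-predictor type-II Wald chi-square
#' tests, BH adjustment across predictors, and Nakagawa marginal /
#' conditional R2. Singular fits fall back to a fixed-effects-only OLS and
#' are flagged.
#'
#' @param response numeric response.
#' @param predictors data.frame of predictors.
#' @param grouping factor of group (sampling-plot) ids.
#' @return list: `coefficients` (predictor, estimate (standardized),
#'   chisq, df, p, q), `R2` (marginal, conditional), `singular`.
#' @export
lmmAssoc <- function(response, predictors, grouping) {
  dat <- as.data.frame(standardizeCols(predictors))
  dat$.y <- as.numeric(scale(response))
  dat$.g <- factor(grouping)
  preds <- setdiff(names(dat), c(".y", ".g"))
  fml <- as.formula(paste(".y ~", paste(preds, collapse = " + "),
                          "+ (1 | .g)"))
  fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    fit2 <- lm(as.formula(paste(".y ~", paste(preds, collapse = " + "))),
               data = dat)
    aov2 <- car::Anova(fit2, type = 2)
    cf <- coef(fit2)[preds]
    tab <- data.frame(predictor = preds, estimate = unname(cf),
                      chisq = aov2[preds, "F value"] * aov2[preds, "Df"],
                      df = aov2[preds, "Df"], p = aov2[preds, "Pr(>F)"])
    r2 <- summary(fit2)$r.squared
    R2 <- c(marginal = r2, conditional = r2)
  } else {
    aov2 <- car::Anova(fit, type = 2)
    cf <- lme4::fixef(fit)[preds]
    tab <- data.frame(predictor = preds, estimate = unname(cf),
                      chisq = aov2[preds, "Chisq"], df = aov2[preds, "Df"],
                      p = aov2[preds, "Pr(>Chisq)"])
    R2 <- r2Nakagawa(fit)
  }
  tab$q <- p.adjust(tab$p, "BH")
  rownames(tab) <- NULL
  list(coefficients = tab, R2 = R2, singular = singular, fit = fit)
}

#' Piecewise structural equation model with Fisher's C
#'
#' Each structural equation is fitted as a linear (mixed) model; the
#' d-separation basis set is derived from the DAG (every non-adjacent
#' pair, the topologically later variable regressed on both variables'
#' parents plus the earlier variable); Fisher's C = -2 sum ln p over the k
#' independence claims, df = 2k, with the chi-square upper-tail p. Path
#' coefficients are standardized (beta * sd(x) / sd(y)); direct, indirect
#' and total effects come from path tracing. The conventional goodness
#' rule (0 < C/df < 2 and p > 0.05) is evaluated and reported.
#'
#' @param paths list of formulas (or formula strings), one structural
#'   equation per endogenous variable.
#' @param data data.frame holding every variable.
#' @param random optional name of a grouping column; adds a random
#'   intercept to every equation.
#' @param composites optional named list: composite name -> character
#'   vector of indicator columns; each composite becomes the first
#'   principal component of its standardized indicators (sign-aligned with
#'   the first indicator) and is added to `data` before fitting.
#' @param exclude_claims optional list of length-2 character vectors:
#'   pairs whose independence claim is dropped (correlated errors).
#' @return list: `coefficients` (response, predictor, estimate, std_estimate,
#'   p), `claims` (u, v, p), `C`, `df`, `p`, `goodness_ok`, `R2` (per
#'   endogenous variable), `effects` (standardized direct/indirect/total
#'   on each endogenous variable), `saturated`.
#' @export
piecewiseSem <- function(paths, data, random = NULL, composites = NULL,
                         exclude_claims = NULL) {
  data <- as.data.frame(data)
  for (nm in names(composites)) {
    ind <- composites[[nm]]
    pc <- prcomp(standardizeCols(data[, ind, drop = FALSE]), center = FALSE)
    sc <- pc$x[, 1]
    if (cor(sc, data[[ind[1]]]) < 0) sc <- -sc
    data[[nm]] <- as.numeric(sc)
  }
  paths <- lapply(paths, as.formula)
  resp <- vapply(paths, function(f) all.vars(f)[1], character(1))
  stopifnotMsg(!anyDuplicated(resp), "one equation per endogenous variable")
  parents <- lapply(paths, function(f) all.vars(f)[-1])
  names(parents) <- resp
  nodes <- unique(c(resp, unlist(parents)))
  missing <- setdiff(nodes, names(data))
  if (length(missing))
    stop("variables absent from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  # fit on standardized variables: path coefficients then come out on the
  # standardized scale and every equation is well conditioned
  sds <- vapply(nodes, function(v) sd(data[[v]]), numeric(1))
  if (any(sds == 0))
    stop("constant variable(s): ", paste(nodes[sds == 0], collapse = ", "),
         call. = FALSE)
  for (v in nodes) data[[v]] <- as.numeric(scale(data[[v]]))
  dag <- igraph::graph_from_data_frame(
    data.frame(from = unlist(parents),
               to = rep(resp, lengths(parents))),
    directed = TRUE, vertices = data.frame(name = nodes))
  if (!igraph::is_dag(dag)) stop("path specification is cyclic", call. = FALSE)
  topo <- igraph::as_ids(igraph::topo_sort(dag))

  fitEq <- function(y, xs) {
    rhs <- if (length(xs)) paste(xs, collapse = " + ") else "1"
    if (!is.null(random)) {
      wv <- tapply(data[[y]], data[[random]], var)
      if (all(wv < 1e-12, na.rm = TRUE)) {
        # group-constant response: the informative unit is the group, so
        # fit on group means rather than pseudo-replicating
        agg <- stats::aggregate(data[, unique(c(y, xs)), drop = FALSE],
                                list(.grp = data[[random]]), mean)
        return(lm(as.formula(paste(y, "~", rhs)), data = agg))
      }
      f <- as.formula(paste(y, "~", rhs, "+ (1 |", random, ")"))
      fit <- tryCatch(suppressWarnings(suppressMessages(
        lme4::lmer(f, data = data, REML = FALSE))), error = function(e) NULL)
      if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5))
        fit <- lm(as.formula(paste(y, "~", rhs)), data = data)
      fit
    } else lm(as.formula(paste(y, "~", rhs)), data = data)
  }
  coefP <- function(fit, term) {
    if (inherits(fit, "merMod")) {
      s <- coef(summary(fit))
      z <- s[term, "Estimate"] / s[term, "Std. Error"]
      c(est = unname(s[term, "Estimate"]), p = unname(2 * pnorm(-abs(z))))
    } else {
      s <- summary(fit)$coefficients
      c(est = s[term, 1], p = s[term, 4])
    }
  }

  fits <- lapply(resp, function(y) fitEq(y, parents[[y]]))
  names(fits) <- resp
  coefs <- do.call(rbind, lapply(resp, function(y) {
    do.call(rbind, lapply(parents[[y]], function(xv) {
      cp <- coefP(fits[[y]], xv)
      data.frame(response = y, predictor = xv, estimate = cp["est"],
                 std_estimate = cp["est"] * sd(data[[xv]]) / sd(data[[y]]),
                 p = cp["p"], row.names = NULL)
    }))
  }))

  prs <- if (length(nodes) >= 2) combn(nodes, 2, simplify = FALSE) else list()
  excluded <- vapply(prs, function(pr) {
    any(vapply(exclude_claims, function(e) setequal(e, pr), logical(1)))
  }, logical(1))
  if (!length(excluded)) excluded <- logical(0)
  claims <- list()
  for (k in seq_along(prs)) {
    pr <- prs[[k]]
    if (excluded[k]) next
    a <- pr[1]; b <- pr[2]
    if (b %in% (parents[[a]] %||% character()) ||
        a %in% (parents[[b]] %||% character())) next
    later <- pr[which.max(match(pr, topo))]
    earlier <- setdiff(pr, later)
    cond <- union(parents[[later]] %||% character(),
                  parents[[earlier]] %||% character())
    cond <- setdiff(cond, pr)
    fit <- fitEq(later, c(cond, earlier))
    claims[[length(claims) + 1]] <-
      data.frame(u = earlier, v = later, p = coefP(fit, earlier)["p"],
                 row.names = NULL)
  }
  saturated <- length(claims) == 0
  if (saturated) {
    C <- NA_real_; dfC <- 0L; pC <- NA_real_
    claimTab <- data.frame(u = character(), v = character(), p = numeric())
  } else {
    claimTab <- do.call(rbind, claims)
    fc <- fisherC(pmax(pmin(claimTab$p, 1), 1e-300))
    C <- fc$C; dfC <- fc$df; pC <- fc$p
  }
  goodness <- !saturated && C > 0 && C / dfC < 2 && pC > 0.05

  R2 <- lapply(fits, function(f) {
    if (inherits(f, "merMod")) r2Nakagawa(f)
    else c(marginal = summary(f)$r.squared,
           conditional = summary(f)$r.squared)
  })

  # standardized direct/indirect/total effects on each endogenous variable
  stdLookup <- function(from, to) {
    i <- coefs$response == to & coefs$predictor == from
    if (any(i)) coefs$std_estimate[i] else 0
  }
  effects <- do.call(rbind, lapply(resp, function(y) {
    others <- setdiff(nodes, y)
    do.call(rbind, lapply(others, function(v) {
      pathsAll <- igraph::all_simple_paths(dag, from = v, to = y,
                                           mode = "out")
      if (!length(pathsAll)) return(NULL)
      contrib <- vapply(pathsAll, function(pp) {
        nm <- igraph::as_ids(pp)
        prod(vapply(seq_len(length(nm) - 1), function(i)
          stdLookup(nm[i], nm[i + 1]), numeric(1)))
      }, numeric(1))
      direct <- stdLookup(v, y)
      data.frame(on = y, of = v, direct = direct,
                 indirect = sum(contrib) - direct, total = sum(contrib),
                 row.names = NULL)
    }))
  }))

  list(coefficients = coefs, claims = claimTab, C = C, df = dfC, p = pC,
       goodness_ok = goodness, R2 = R2, effects = effects,
       saturated = saturated, fits = fits, data = data)
}
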