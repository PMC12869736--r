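#' Bray-Curtis dissimilarity
#'
#' d(x, y) = sum|x - y| / sum(x + y), computed on Hellinger-transformed or
#' relative abundances (samples compared column-wise on an AsvExperiment,
#' row-wise on a plain samples x variables matrix).
#'
#' @param x an [AsvExperiment-class] (Hellinger-transformed internally when
#'   `hellinger = TRUE`) or a samples x variables numeric matrix.
#' @param hellinger apply [hellingerTransform()] first (AsvExperiment input
#'   only).
#' @return a `dist` object with sample labels.
#' @export
brayCurtis <- function(x, hellinger = TRUE) {
  m <- if (is(x, "AsvExperiment")) {
    t(if (hellinger) hellingerTransform(x) else asvCounts(x))
  } else as.matrix(x)
  vegan::vegdist(m, method = "bray")
}

permResult <- function(statistic, p, n_perm, stat_name) {
  data.frame(stat = stat_name, statistic = statistic, p = p, n_perm = n_perm)
}

#' Permutation tests on distance matrices
#'
#' `permanovaTest()` (ADONIS pseudo-F and R2 from the Gower-centered
#' partition), `anosimTest()` (rank-based R), `mrppTest()` (chance-
#' corrected A), all by free permutation of sample labels; `mantelTest()`
#' and `partialMantelTest()` correlate two distance matrices over the
#' lower triangle (Spearman by default), permuting one matrix's rows and
#' columns jointly; the partial variant correlates residuals after
#' removing a third matrix.
#'
#' @param d,d1,d2,d3 `dist` objects over the same samples.
#' @param groups factor of group labels (each group n >= 2).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param method correlation method for the Mantel statistics.
#' @return data.frame: `stat`, `statistic`, `p`, `n_perm` (plus `R2` and
#'   `F` columns for PERMANOVA).
#' @export
permanovaTest <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- droplevels(factor(groups))
  stopifnotMsg(all(table(groups) >= 2), "every group needs n >= 2")
  set.seed(seed)
  df <- data.frame(groups = groups)
  fit <- vegan::adonis2(d ~ groups, data = df, permutations = n_perm)
  out <- permResult(fit$R2[1], fit$`Pr(>F)`[1], n_perm, "ADONIS.R2")
  out$R2 <- fit$R2[1]; out$F <- fit$F[1]
  out
}

#' @rdname permanovaTest
#' @export
anosimTest <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- droplevels(factor(groups))
  stopifnotMsg(all(table(groups) >= 2), "every group needs n >= 2")
  set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_perm)
  permResult(fit$statistic, fit$signif, n_perm, "ANOSIM.R")
}

#' @rdname permanovaTest
#' @export
mrppTest <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- droplevels(factor(groups))
  stopifnotMsg(all(table(groups) >= 2), "every group needs n >= 2")
  set.seed(seed)
  fit <- vegan::mrpp(d, groups, permutations = n_perm)
  permResult(fit$A, fit$Pvalue, n_perm, "MRPP.A")
}

#' @rdname permanovaTest
#' @export
mantelTest <- function(d1, d2, method = c("spearman", "pearson"),
                       n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = method, permutations = n_perm)
  permResult(fit$statistic, fit$signif, n_perm, paste0("Mantel.r.", method))
}

#' @rdname permanovaTest
#' @export
partialMantelTest <- function(d1, d2, d3, method = c("spearman", "pearson"),
                              n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  fit <- vegan::mantel.partial(d1, d2, d3, method = method,
                               permutations = n_perm)
  permResult(fit$statistic, fit$signif, n_perm,
             paste0("partialMantel.r.", method))
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix with Lingoes
#' correction for negative eigenvalues.
#'
#' @param d a `dist` object.
#' @param k number of axes to return.
#' @return list: `points` (samples x k), `eig`, `correction`.
#' @export
pcoaOrdination <- function(d, k = 2) {
  fit <- vegan::wcmdscale(d, k = k, eig = TRUE, add = "lingoes")
  list(points = fit$points, eig = fit$eig,
       correction = fit$ac %||% 0)
}

#' Distance-based RDA with forward selection
#'
#' dbRDA of a dissimilarity matrix on standardized environmental columns
#' (Lingoes correction for negative eigenvalues), with Blanchet-style
#' double-stopping forward selection: a candidate enters only while its
#' permutation p <= `alpha` and the adjusted R2 of the selected model does
#' not exceed that of the full model. Marginal (single-variable) R2 and p
#' are reported for every candidate alongside the selection path.
#'
#' @param d a `dist` object.
#' @param env data.frame of environmental columns (standardized
#'   internally).
#' @param alpha entry threshold on the permutation p-value.
#' @param n_perm permutations per entry test.
#' @param seed RNG seed.
#' @return list: `selected` (data.frame: variable, order, R2adj_cum, p),
#'   `marginal` (per-variable R2 and p from single-variable models),
#'   `full_R2adj`.
#' @export
dbrdaForward <- function(d, env, alpha = 0.05, n_perm = 999, seed = 1L) {
  env <- as.data.frame(standardizeCols(env))
  keep <- vapply(env, function(v) sd(v) > 0, logical(1))
  env <- env[, keep, drop = FALSE]
  set.seed(seed)
  marg <- do.call(rbind, lapply(names(env), function(v) {
    m <- vegan::dbrda(d ~ ., data = env[, v, drop = FALSE], add = "lingoes")
    a <- vegan::anova.cca(m, permutations = n_perm)
    data.frame(variable = v,
               R2 = vegan::RsquareAdj(m)$r.squared,
               R2adj = vegan::RsquareAdj(m)$adj.r.squared,
               p = a$`Pr(>F)`[1])
  }))
  m1 <- vegan::dbrda(d ~ ., data = env, add = "lingoes")
  fullAdj <- vegan::RsquareAdj(m1)$adj.r.squared
  globalP <- vegan::anova.cca(m1, permutations = n_perm)$`Pr(>F)`[1]
  selected <- data.frame(variable = character(), order = integer(),
                         R2adj_cum = numeric(), p = numeric())
  if (is.finite(globalP) && globalP <= alpha) {
    chosen <- character()
    remaining <- names(env)
    repeat {
      adds <- vapply(remaining, function(cand) {
        f <- as.formula(paste("d ~", paste(c(chosen, cand), collapse = "+")))
        vegan::RsquareAdj(vegan::dbrda(f, data = env,
                                       add = "lingoes"))$adj.r.squared
      }, numeric(1))
      cand <- remaining[which.max(adds)]
      # permutation test of the candidate, conditioned on the selection
      f <- if (length(chosen))
        as.formula(paste("d ~", cand, "+ Condition(",
                         paste(chosen, collapse = "+"), ")"))
      else as.formula(paste("d ~", cand))
      p <- vegan::anova.cca(vegan::dbrda(f, data = env, add = "lingoes"),
                            permutations = n_perm)$`Pr(>F)`[1]
      if (!is.finite(p) || p > alpha) break
      chosen <- c(chosen, cand)
      remaining <- setdiff(remaining, cand)
      selected <- rbind(selected,
                        data.frame(variable = cand, order = length(chosen),
                                   R2adj_cum = max(adds), p = p))
      # Blanchet R2 scope: stop once the cumulative adjusted R2 reaches
      # the full model's (the crossing variable is kept)
      if (max(adds) >= fullAdj || !length(remaining)) break
    }
  }
  list(selected = selected, marginal = marg, full_R2adj = fullAdj,
       global_p = globalP)
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R2_k), R2_k from the OLS regression of column k on all
#' other columns. Perfectly collinear columns are reported as `Inf`.
#'
#' @param env data.frame or matrix of predictor columns.
#' @return named numeric vector of VIFs.
#' @export
vifScreen <- function(env) {
  env <- as.data.frame(env)
  stopifnotMsg(ncol(env) >= 2, "need at least two columns")
  vapply(seq_along(env), function(k) {
    r2 <- suppressWarnings(
      summary(lm(env[[k]] ~ ., data = env[, -k, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(names(env))
}
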