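#' Per-sample diversity indices
#'
#' Species richness (number of taxa observed with count > 0) plus Shannon
#' and inverse-Simpson indices as supplementary measures.
#'
#' @param x an [AsvExperiment-class] or counts matrix (taxa x samples).
#' @return data.frame: `sample`, `richness`, `shannon`, `invsimpson`.
#' @export
richnessIndices <- function(x) {
  cts <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  if (is.null(colnames(cts))) colnames(cts) <- paste0("S", seq_len(ncol(cts)))
  rel <- sweep(cts, 2, pmax(colSums(cts), 1), "/")
  sh <- apply(rel, 2, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  is <- apply(rel, 2, function(p) {
    s2 <- sum(p^2); if (s2 == 0) 0 else 1 / s2
  })
  data.frame(sample = colnames(cts), richness = colSums(cts > 0),
             shannon = sh, invsimpson = is, row.names = NULL)
}

#' Least Significant Difference test
#'
#' One-way ANOVA followed by all pairwise t comparisons using the pooled
#' mean-square error and its degrees of freedom; unprotected by default
#' (pairwise p-values reported regardless of the omnibus F), optionally
#' gated on omnibus significance. A compact letter display is attached.
#'
#' @param values numeric response, one per sample.
#' @param groups factor of group labels (>= 2 groups, each n >= 2).
#' @param protect if `TRUE`, pairwise p-values are reported as 1 when the
#'   omnibus F is not significant at `alpha`.
#' @param alpha significance level for the letters (and the gate when
#'   `protect = TRUE`).
#' @return list: `anova` (F, df, p), `pairwise` (data.frame with group
#'   pair, mean difference, t, df, p), `letters` (named character vector;
#'   groups sharing a letter are not significantly different), `means`.
#' @export
lsdTest <- function(values, groups, protect = FALSE, alpha = 0.05) {
  groups <- droplevels(factor(groups))
  ng <- nlevels(groups)
  stopifnotMsg(ng >= 2, "need at least two groups")
  nk <- table(groups)
  stopifnotMsg(all(nk >= 2), "every group needs n >= 2")
  fit <- aov(values ~ groups)
  an <- anova(fit)
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  if (mse <= 0) stop("zero pooled variance: LSD undefined", call. = FALSE)
  mns <- tapply(values, groups, mean)
  cmb <- combn(levels(groups), 2)
  pw <- apply(cmb, 2, function(pr) {
    diffm <- mns[pr[1]] - mns[pr[2]]
    se <- sqrt(mse * (1 / nk[pr[1]] + 1 / nk[pr[2]]))
    tval <- diffm / se
    c(diff = diffm, t = tval, p = 2 * pt(-abs(tval), dfe))
  })
  pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                         diff = pw[1, ], t = pw[2, ], df = dfe, p = pw[3, ],
                         row.names = NULL)
  omnibus_p <- an[["Pr(>F)"]][1]
  if (protect && omnibus_p > alpha) pairwise$p <- 1
  list(anova = data.frame(F = an[["F value"]][1], df1 = an[["Df"]][1],
                          df2 = dfe, p = omnibus_p),
       pairwise = pairwise,
       letters = letterDisplay(levels(groups)[order(-mns)], pairwise, alpha),
       means = mns)
}

# compact letter display: insert-and-absorb over groups ordered by mean
letterDisplay <- function(ordered_groups, pairwise, alpha) {
  sig <- function(a, b) {
    i <- (pairwise$group1 == a & pairwise$group2 == b) |
         (pairwise$group1 == b & pairwise$group2 == a)
    any(pairwise$p[i] <= alpha)
  }
  cols <- list()  # each column = set of groups sharing a letter
  for (g in ordered_groups) {
    placed <- FALSE
    for (k in seq_along(cols)) {
      if (!any(vapply(cols[[k]], sig, logical(1), b = g))) {
        cols[[k]] <- c(cols[[k]], g); placed <- TRUE
      }
    }
    if (!placed) cols[[length(cols) + 1]] <- g
  }
  out <- setNames(rep("", length(ordered_groups)), ordered_groups)
  for (k in seq_along(cols))
    for (g in cols[[k]]) out[g] <- paste0(out[g], letters[k])
  out
}

#' Cohen's d standardized effect size
#'
#' d = (mean(a) - mean(b)) / pooled SD, the pooled SD weighting each
#' group's variance by its degrees of freedom. Magnitude bands: negligible
#' (|d| <= 0.2), small (0.2 < |d| <= 0.5, `*`), medium (0.5 < |d| <= 0.8,
#' `**`), large (|d| > 0.8, `***`).
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return list: `d`, `magnitude`, `stars`, `undefined` (TRUE when the
#'   pooled SD is zero).
#' @export
cohensD <- function(a, b) {
  na_ <- length(a); nb <- length(b)
  stopifnotMsg(na_ >= 2 && nb >= 2, "both groups need n >= 2")
  sp2 <- ((na_ - 1) * var(a) + (nb - 1) * var(b)) / (na_ + nb - 2)
  if (sp2 <= 0)
    return(list(d = NA_real_, magnitude = NA_character_, stars = "",
                undefined = TRUE))
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  ad <- abs(d)
  mag <- if (ad <= 0.2) "negligible" else if (ad <= 0.5) "small"
         else if (ad <= 0.8) "medium" else "large"
  stars <- c(negligible = "", small = "*", medium = "**", large = "***")[mag]
  list(d = d, magnitude = mag, stars = unname(stars), undefined = FALSE)
}

#' Shared-ASV Venn fractions across stress classes
#'
#' Taxa are scored present in a class when they have count > 0 in at least
#' one of its samples; the 7 regions of the three-set Venn partition are
#' reported as fractions of the union (summing to 1).
#'
#' @param x an [AsvExperiment-class] whose `sampleData` has the grouping
#'   column, or a counts matrix plus explicit `groups`.
#' @param groups factor with exactly three levels (defaults to the
#'   `stress` column of `sampleData(x)`).
#' @return data.frame: `region` (e.g. `"freshwater&brackish&saline"`),
#'   `n_taxa`, `fraction`.
#' @export
sharedAsvFractions <- function(x, groups = NULL) {
  cts <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  if (is.null(groups)) groups <- sampleData(x)$stress
  groups <- droplevels(factor(groups))
  stopifnotMsg(nlevels(groups) == 3, "need exactly three classes")
  lv <- levels(groups)
  pres <- vapply(lv, function(g)
    rowSums(cts[, groups == g, drop = FALSE] > 0) > 0, logical(nrow(cts)))
  if (any(colSums(pres) == 0))
    stop("class with no observed taxa: ",
         paste(lv[colSums(pres) == 0], collapse = ", "), call. = FALSE)
  inUnion <- rowSums(pres) > 0
  pres <- pres[inUnion, , drop = FALSE]
  code <- pres[, 1] + 2 * pres[, 2] + 4 * pres[, 3]
  regionName <- vapply(1:7, function(k)
    paste(lv[c(bitwAnd(k, 1L), bitwAnd(k, 2L), bitwAnd(k, 4L)) > 0],
          collapse = "&"), character(1))
  n <- vapply(1:7, function(k) sum(code == k), numeric(1))
  data.frame(region = regionName, n_taxa = n, fraction = n / sum(n))
}
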