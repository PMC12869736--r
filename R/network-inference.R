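#' Prevalence/abundance filtering of taxa
#'
#' Retains taxa observed in strictly more than `prevalence` of the samples
#' and with sequence abundance strictly greater than `abundance`
#' (`abundance_type = "total"` reads across samples for the global filter;
#' `"mean"` reads per sample for the per-habitat sub-network rule). Taxon
#' order is preserved.
#'
#' @param x an [AsvExperiment-class].
#' @param prevalence fraction of samples in (0, 1]; strict `>`.
#' @param abundance reads threshold; strict `>`.
#' @param abundance_type `"total"` or `"mean"`.
#' @return the filtered [AsvExperiment-class]; the kept taxon ids are in
#'   `metadata(x)$kept_taxa`.
#' @export
filterTaxa <- function(x, prevalence = 0.2, abundance = 100,
                       abundance_type = c("total", "mean")) {
  abundance_type <- match.arg(abundance_type)
  stopifnotMsg(prevalence > 0 && prevalence <= 1, "prevalence must be in (0,1]")
  stopifnotMsg(abundance >= 0, "abundance threshold must be >= 0")
  cts <- asvCounts(x)
  prev <- rowMeans(cts > 0)
  ab <- if (abundance_type == "total") rowSums(cts) else rowMeans(cts)
  keep <- prev > prevalence & ab > abundance
  if (!any(keep)) stop("no taxa survive the filter", call. = FALSE)
  out <- x[keep, ]
  S4Vectors::metadata(out)$kept_taxa <- rownames(cts)[keep]
  out
}

# shared log-spaced lambda path from the CLR data (samples x taxa)
lambdaPath <- function(X, nlambda, lambda_min_ratio) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  lmax <- 0
  for (j in seq_len(ncol(Xc)))
    lmax <- max(lmax, max(abs(crossprod(Xc[, -j], Xc[, j]))) / n)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# MB neighborhood selection on one data matrix for a fixed lambda path;
# returns edge-presence matrix (n_pairs x nlambda) and, optionally, the
# signed max-|coefficient| weights at a single lambda index.
mbSelect <- function(X, lambda, pairIdx, weightsAt = NULL) {
  p <- ncol(X)
  pres <- matrix(FALSE, max(pairIdx), length(lambda))
  wts <- if (!is.null(weightsAt)) matrix(0, p, p) else NULL
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j], family = "gaussian",
                          lambda = lambda, standardize = TRUE)
    cf <- as.matrix(fit$beta)  # (p-1) x nlambda (may be shorter path)
    if (ncol(cf) < length(lambda))
      cf <- cbind(cf, matrix(cf[, ncol(cf)], nrow(cf),
                             length(lambda) - ncol(cf)))
    others <- seq_len(p)[-j]
    nz <- cf != 0
    for (l in which(colSums(nz) > 0)) {
      nb <- others[nz[, l]]
      a <- pmin(j, nb); b <- pmax(j, nb)
      pres[pairIdx[cbind(a, b)], l] <- TRUE
    }
    if (!is.null(weightsAt)) {
      co <- cf[, weightsAt]
      sel <- which(co != 0)
      for (s in sel) {
        k <- others[s]
        if (abs(co[s]) > abs(wts[j, k])) {
          wts[j, k] <- co[s]; wts[k, j] <- co[s]
        }
      }
    }
  }
  list(presence = pres, weights = wts)
}

# graphical lasso via Friedman block coordinate descent (lasso subproblems
# solved by cyclic coordinate descent); pattern-oriented, small p only
glassoFit <- function(S, rho, maxit = 50, tol = 1e-4) {
  p <- ncol(S)
  W <- S + diag(rho, p)
  B <- matrix(0, p, p)  # column j holds beta for block j
  for (it in seq_len(maxit)) {
    Wold <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx]; s12 <- S[idx, j]
      beta <- B[idx, j]
      for (sweep_ in 1:20) {
        bold <- beta
        for (k in seq_along(idx)) {
          r <- s12[k] - sum(W11[k, -k] * beta[-k])
          beta[k] <- sign(r) * max(abs(r) - rho, 0) / W11[k, k]
        }
        if (max(abs(beta - bold)) < tol * (1 + max(abs(beta)))) break
      }
      B[idx, j] <- beta
      W[idx, j] <- W[j, idx] <- W11 %*% beta
    }
    if (mean(abs(W - Wold)) < tol * mean(abs(S))) break
  }
  # precision pattern/sign: theta12 = -beta * theta22, theta22 > 0, so
  # sign(theta_ij) = -sign(beta); partial correlation sign = sign(beta)
  B
}

glassoSelect <- function(X, lambda, pairIdx, weightsAt = NULL) {
  S <- cor(X)
  p <- ncol(S)
  pres <- matrix(FALSE, max(pairIdx), length(lambda))
  wts <- if (!is.null(weightsAt)) matrix(0, p, p) else NULL
  for (l in seq_along(lambda)) {
    B <- glassoFit(S, lambda[l])
    A <- (abs(B) + t(abs(B))) / 2
    nz <- which(A > 1e-8 & upper.tri(A), arr.ind = TRUE)
    if (nrow(nz)) pres[pairIdx[nz], l] <- TRUE
    if (!is.null(weightsAt) && l == weightsAt) {
      sgn <- B + t(B)  # partial-correlation-signed magnitude
      wts[] <- ifelse(A > 1e-8, sgn / 2, 0)
    }
  }
  list(presence = pres, weights = wts)
}

#' Infer a signed co-occurrence network with StARS stability selection
#'
#' CLR-transforms the counts, then runs sparse-regression network
#' inference along a log-spaced lambda path: Meinshausen-Buhlmann
#' neighborhood selection (default; lasso of each taxon's CLR profile on
#' all others, OR-symmetrized) or graphical lasso. The regularization
#' level is chosen by StARS: `stars_B` subsamples of size
#' min(floor(10 sqrt(n)), 0.8 n) are drawn, edge-selection frequencies
#' give a per-lambda instability D = mean 2 xi (1 - xi), the instability
#' is monotonized from the sparse end, and the densest lambda with
#' instability <= `stars_beta` is selected. Edge weights are the
#' symmetrized max-|coefficient| values at the selected lambda; the edge
#' sign is the weight's sign.
#'
#' @param x an [AsvExperiment-class] (already filtered) or a counts matrix
#'   (taxa x samples).
#' @param method `"mb"` (default) or `"glasso"`.
#' @param nlambda,lambda_min_ratio lambda path (30 points down to 1% of
#'   lambda-max by default).
#' @param stars_B number of subsamples (default 50).
#' @param stars_beta instability target (default 0.05).
#' @param pseudocount CLR pseudocount.
#' @param seed RNG seed (drives the subsample plan).
#' @return an [EcoNetwork-class]; provenance records method, lambda path,
#'   selected lambda, instability path, StARS settings and seed.
#' @export
inferNetwork <- function(x, method = c("mb", "glasso"), nlambda = 30,
                         lambda_min_ratio = 0.01, stars_B = 50,
                         stars_beta = 0.05, pseudocount = 1, seed = 1L) {
  method <- match.arg(method)
  cts <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  stopifnotMsg(ncol(cts) >= 20, "need at least 20 samples")
  X <- t(clrTransform(cts, pseudocount))  # samples x taxa
  n <- nrow(X); p <- ncol(X)
  m <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  stopifnotMsg(m >= 2, "too few samples for StARS subsampling")
  lambda <- if (method == "mb") {
    lambdaPath(X, nlambda, lambda_min_ratio)
  } else {
    # glasso penalises the correlation matrix directly
    S <- cor(X)
    lmax <- max(abs(S[upper.tri(S)]))
    exp(seq(log(lmax), log(lmax * lambda_min_ratio),
            length.out = nlambda))
  }
  pairIdx <- matrix(0L, p, p)
  pairIdx[upper.tri(pairIdx)] <- seq_len(p * (p - 1) / 2)
  pairIdx <- pairIdx + t(pairIdx)
  selector <- if (method == "mb") mbSelect else glassoSelect

  set.seed(seed)
  subplans <- replicate(stars_B, sample(n, m), simplify = FALSE)
  freq <- matrix(0, p * (p - 1) / 2, length(lambda))
  for (b in seq_len(stars_B))
    freq <- freq + selector(X[subplans[[b]], , drop = FALSE], lambda,
                            pairIdx)$presence
  xi <- freq / stars_B
  instab <- colMeans(2 * xi * (1 - xi))
  instabMono <- cummax(instab)           # lambda sorted dense... path is
  # decreasing lambda: index 1 = sparsest; monotonize from the sparse end
  ok <- which(instabMono <= stars_beta)
  sel <- if (length(ok)) max(ok) else 1L

  fin <- selector(X, lambda, pairIdx, weightsAt = sel)
  W <- fin$weights
  nz <- which(abs(W) > 0 & upper.tri(W), arr.ind = TRUE)
  taxa <- colnames(X)
  edges <- if (nrow(nz))
    data.frame(from = taxa[nz[, 1]], to = taxa[nz[, 2]],
               weight = W[nz]) else NULL
  rel <- sweep(cts, 2, pmax(colSums(cts), 1), "/")
  nodes <- data.frame(name = taxa,
                      domain = ifelse(startsWith(taxa, "A"), "archaea",
                                      "bacteria"),
                      meanAbund = rowMeans(rel))
  EcoNetwork(edges, nodes, provenance = list(
    method = method, lambda_path = lambda, lambda_selected = lambda[sel],
    lambda_index = sel, instability = instab, stars_B = stars_B,
    stars_beta = stars_beta, subsample_size = m, seed = seed,
    n_samples = n, n_taxa = p))
}

#' Extract a per-habitat sub-network
#'
#' Induced subgraph of the global network on the taxa that stably occur in
#' the habitat: present in strictly more than `prevalence` of the
#' habitat's samples and with within-habitat mean abundance strictly
#' greater than `abundance` reads. Edges are inherited from the global
#' network.
#'
#' @param network an [EcoNetwork-class].
#' @param x the [AsvExperiment-class] the network was inferred from.
#' @param habitat a stress-class label present in `sampleData(x)$stress`,
#'   or a logical/character selector of samples.
#' @param prevalence within-habitat occurrence threshold (default 0.3).
#' @param abundance within-habitat mean-reads threshold (default 100).
#' @return an [EcoNetwork-class] (provenance inherited, plus the habitat
#'   rule).
#' @export
extractSubnetwork <- function(network, x, habitat, prevalence = 0.3,
                              abundance = 100) {
  md <- sampleData(x)
  sel <- if (is.logical(habitat)) habitat else md$stress == habitat
  if (!any(sel)) stop("habitat has no samples", call. = FALSE)
  cts <- asvCounts(x)[, sel, drop = FALSE]
  keep <- rownames(cts)[rowMeans(cts > 0) > prevalence &
                        rowMeans(cts) > abundance]
  g <- netGraph(network)
  keep <- intersect(keep, igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, keep)
  prov <- provenance(network)
  prov$subnetwork <- list(habitat = as.character(habitat)[1],
                          prevalence = prevalence, abundance = abundance)
  new("EcoNetwork", graph = sub, provenance = prov)
}
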