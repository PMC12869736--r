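#' Per-edge co-variation signal across sample pairs
#'
#' For an edge (i, j), the between-sample dissimilarity of the pair's
#' joint abundance profile: the Euclidean distance between samples in the
#' 2-dimensional space of the two taxa's CLR values, vectorized over all
#' n(n-1)/2 sample pairs.
#'
#' @param x an [AsvExperiment-class] or counts matrix (taxa x samples).
#' @param edge character length-2: the two taxon ids.
#' @param clr optional precomputed CLR matrix (taxa x samples).
#' @return a `dist` over samples.
#' @export
pairwiseSignal <- function(x, edge, clr = NULL) {
  if (is.null(clr))
    clr <- clrTransform(if (is(x, "AsvExperiment")) asvCounts(x) else x)
  miss <- setdiff(edge, rownames(clr))
  if (length(miss)) stop("taxon absent from table: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dist(t(clr[edge, , drop = FALSE]))
}

# one-sided (positive) Mantel permutation test on a precomputed rank
# matrix; perms is a list of sample permutations shared across edges
mantelEdge <- function(rankMat, refRanks, perms) {
  lt <- lower.tri(rankMat)
  v <- rankMat[lt]
  if (sd(v) == 0) return(c(r = NA_real_, p = NA_real_))
  r_obs <- cor(v, refRanks)
  r_perm <- vapply(perms, function(pm) {
    cor(rankMat[pm, pm][lt], refRanks)
  }, numeric(1))
  c(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (length(perms) + 1))
}

#' Assign assembly processes to network links
#'
#' For every edge, the [pairwiseSignal()] series is tested by one-sided
#' Mantel-type permutation correlation (Spearman) against (a) geographic
#' distance (haversine km) and (b) environmental dissimilarity (Euclidean
#' on standardized metadata columns), in that order. P-values are
#' BH-adjusted across edges within each test family; the sequential rule
#' is: significant vs geography -> `spatial`; else significant vs
#' environment -> `environmental`; else -> `biotic`. Edges with
#' zero-variance signal are flagged degenerate and excluded from the
#' biotic set.
#'
#' @param network an [EcoNetwork-class].
#' @param x the [AsvExperiment-class] the network refers to (its
#'   `sampleData` must carry `lon`, `lat` and the `env` columns).
#' @param env character vector of metadata column names to use as the
#'   environment (standardized internally).
#' @param alpha significance level applied to the BH-adjusted p-values.
#' @param n_perm Mantel permutations per edge and family.
#' @param seed RNG seed (one shared permutation plan across edges).
#' @return a [LinkProcessTable-class].
#' @export
classifyLinks <- function(network, x, env, alpha = 0.05, n_perm = 999,
                          seed = 1L) {
  ed <- edgeTable(network)
  md <- sampleData(x)
  n <- ncol(x)
  clr <- clrTransform(asvCounts(x))
  geo <- haversineKm(md$lon, md$lat)
  envm <- as.matrix(dist(standardizeCols(md[, env, drop = FALSE])))
  lt <- lower.tri(geo)
  geoRanks <- rank(geo[lt])
  envRanks <- rank(envm[lt])
  set.seed(seed)
  perms <- replicate(n_perm, sample(n), simplify = FALSE)

  res <- lapply(seq_len(nrow(ed)), function(k) {
    S <- as.matrix(pairwiseSignal(x, c(ed$from[k], ed$to[k]), clr = clr))
    R <- matrix(0, n, n)
    R[lt] <- rank(S[lt]); R <- R + t(R)
    g <- mantelEdge(R, geoRanks, perms)
    e <- mantelEdge(R, envRanks, perms)
    c(g, e)
  })
  res <- do.call(rbind, res)
  tab <- data.frame(from = ed$from, to = ed$to,
                    r_geo = res[, 1], p_geo = res[, 2],
                    r_env = res[, 3], p_env = res[, 4])
  tab$degenerate <- is.na(tab$p_geo) | is.na(tab$p_env)
  tab$q_geo <- p.adjust(tab$p_geo, "BH")
  tab$q_env <- p.adjust(tab$p_env, "BH")
  tab$process <- ifelse(tab$degenerate, NA_character_,
                 ifelse(tab$q_geo <= alpha, "spatial",
                 ifelse(tab$q_env <= alpha, "environmental", "biotic")))
  new("LinkProcessTable",
      table = tab[, c("from", "to", "process", "r_geo", "p_geo", "q_geo",
                      "r_env", "p_env", "q_env", "degenerate")],
      alpha = alpha)
}

#' Restrict a network to its putative biotic links
#'
#' Keeps only the edges classified `biotic`; nodes left isolated are
#' dropped from the graph and recorded in the provenance
#' (`$biotic_isolates`).
#'
#' @param network an [EcoNetwork-class].
#' @param lpt the matching [LinkProcessTable-class].
#' @return an [EcoNetwork-class].
#' @export
bioticSubgraph <- function(network, lpt) {
  tab <- linkTable(lpt)
  keep <- !is.na(tab$process) & tab$process == "biotic"
  g <- netGraph(network)
  ids <- igraph::as_edgelist(g)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  drop <- which(!key(ids[, 1], ids[, 2]) %in% key(tab$from[keep], tab$to[keep]))
  g2 <- igraph::delete_edges(g, drop)
  iso <- igraph::V(g2)$name[igraph::degree(g2) == 0]
  g2 <- igraph::delete_vertices(g2, iso)
  prov <- provenance(network)
  prov$biotic_isolates <- iso
  prov$link_filter <- "biotic"
  new("EcoNetwork", graph = g2, provenance = prov)
}
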