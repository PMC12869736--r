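#' Network topology summary
#'
#' Node and edge counts, percentage of negative links, mean degree,
#' density, global clustering coefficient, and modularity from greedy
#' community detection on absolute edge weights (NA and flagged for
#' edgeless graphs).
#'
#' @param network an [EcoNetwork-class].
#' @return one-row data.frame: `nodes`, `edges`, `pct_negative`,
#'   `mean_degree`, `density`, `clustering`, `modularity`.
#' @export
networkTopology <- function(network) {
  g <- netGraph(network)
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (ne == 0)
    return(data.frame(nodes = nv, edges = 0, pct_negative = NA_real_,
                      mean_degree = 0, density = 0, clustering = NA_real_,
                      modularity = NA_real_))
  ga <- igraph::set_edge_attr(g, "weight", value = abs(igraph::E(g)$weight))
  comm <- igraph::cluster_fast_greedy(ga)
  data.frame(
    nodes = nv, edges = ne,
    pct_negative = 100 * mean(igraph::E(g)$sign == "-"),
    mean_degree = 2 * ne / nv,
    density = igraph::edge_density(g),
    clustering = igraph::transitivity(ga, type = "global"),
    modularity = igraph::modularity(comm))
}

#' Per-taxon positive and negative connectedness
#'
#' pos_i = mean weight over taxon i's positive edges (0 when none);
#' neg_i = mean weight over its negative edges (0 when none).
#'
#' @param network an [EcoNetwork-class].
#' @return data.frame: `taxon`, `pos` (>= 0), `neg` (<= 0).
#' @export
connectedness <- function(network) {
  g <- netGraph(network)
  taxa <- igraph::V(g)$name
  out <- data.frame(taxon = taxa, pos = numeric(length(taxa)),
                    neg = numeric(length(taxa)))
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    w <- igraph::E(g)$weight
    long <- data.frame(taxon = c(el[, 1], el[, 2]), w = c(w, w))
    posm <- tapply(long$w[long$w > 0], long$taxon[long$w > 0], mean)
    negm <- tapply(long$w[long$w < 0], long$taxon[long$w < 0], mean)
    out$pos <- unname(ifelse(is.na(posm[taxa]), 0, posm[taxa]))
    out$neg <- unname(ifelse(is.na(negm[taxa]), 0, negm[taxa]))
  }
  out
}

#' Sample-level positive and negative cohesion
#'
#' cohesion_s = sum over taxa of relative abundance x connectedness,
#' computed separately for the positive and negative components. Taxa
#' absent from the network contribute zero; cohesion is linear in the
#' abundances.
#'
#' @param network an [EcoNetwork-class] (or a precomputed connectedness
#'   data.frame).
#' @param x an [AsvExperiment-class]; relative abundances are taken from
#'   its counts.
#' @return a [CohesionProfile-class].
#' @export
cohesionProfile <- function(network, x) {
  cn <- if (is.data.frame(network)) network else connectedness(network)
  cts <- asvCounts(x)
  rel <- sweep(cts, 2, pmax(colSums(cts), 1), "/")
  common <- intersect(cn$taxon, rownames(rel))
  relN <- rel[common, , drop = FALSE]
  pos <- as.numeric(crossprod(relN, cn$pos[match(common, cn$taxon)]))
  neg <- as.numeric(crossprod(relN, cn$neg[match(common, cn$taxon)]))
  new("CohesionProfile",
      connectedness = cn,
      cohesion = data.frame(sample = colnames(rel), pos = pos, neg = neg))
}

#' Cross-domain cohesion
#'
#' Connectedness computed on the inter-domain edges only (bacteria to
#' archaea), then relative-abundance-weighted over both domains' taxa in
#' the concatenated table.
#'
#' @param network an [EcoNetwork-class] over both domains (vertex
#'   attribute `domain` required).
#' @param x the concatenated bacteria+archaea [AsvExperiment-class]
#'   (domain `"multi"`).
#' @return a [CohesionProfile-class].
#' @export
crossDomainCohesion <- function(network, x) {
  g <- netGraph(network)
  if (igraph::ecount(g) > 0) {
    dom <- igraph::V(g)$domain
    if (is.null(dom)) stop("network lacks a 'domain' vertex attribute",
                           call. = FALSE)
    el <- igraph::as_edgelist(g)
    di <- dom[match(el[, 1], igraph::V(g)$name)]
    dj <- dom[match(el[, 2], igraph::V(g)$name)]
    g <- igraph::delete_edges(g, which(di == dj))
  }
  cohesionProfile(new("EcoNetwork", graph = g,
                      provenance = provenance(network)), x)
}

#' Natural connectivity
#'
#' ln((1/N) sum_k exp(lambda_k)) over the eigenvalues of the unweighted
#' adjacency matrix of the network's current node set (a weighted variant
#' uses |weight| entries). Computed with a max-shift so large graphs do
#' not overflow.
#'
#' @param network an [EcoNetwork-class] or an igraph.
#' @param weighted use |weight| instead of 0/1 adjacency.
#' @return numeric scalar; 0 for an edgeless (or empty) graph.
#' @export
naturalConnectivity <- function(network, weighted = FALSE) {
  g <- if (is(network, "EcoNetwork")) netGraph(network) else network
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE,
    attr = if (weighted) "weight" else NULL)
  if (weighted) A <- abs(A)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  mx + log(mean(exp(ev - mx)))
}

#' Network fragility under key-taxon removal
#'
#' Iteratively removes nodes by the chosen strategy (ranks recomputed
#' after every removal step for the targeted strategies) and records the
#' natural connectivity of the remaining graph along a removal-fraction
#' grid. Fragility summaries: the endpoint drop nc(0) - nc(f_max) and the
#' normalized area under the decline curve.
#'
#' @param network an [EcoNetwork-class].
#' @param strategy `"degree"`, `"betweenness"` or `"random"`.
#' @param removal_grid increasing fractions in [0, 1); nodes removed
#'   cumulatively to reach each fraction.
#' @param n_rep replicate removals for `strategy = "random"` (curves are
#'   averaged).
#' @param seed RNG seed (random strategy).
#' @return list: `curve` (data.frame `fraction`, `nc`), `fragility`
#'   (endpoint drop), `auc` (1 - area under nc/nc0 over the grid).
#' @export
fragility <- function(network, strategy = c("degree", "betweenness", "random"),
                      removal_grid = seq(0, 0.8, by = 0.05), n_rep = 10,
                      seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnotMsg(all(removal_grid >= 0 & removal_grid < 1),
               "removal fractions must lie in [0, 1)")
  removal_grid <- sort(unique(removal_grid))
  g0 <- netGraph(network)
  n0 <- igraph::vcount(g0)
  stopifnotMsg(n0 > 0, "empty network")
  nRemove <- pmin(round(removal_grid * n0), n0 - 1)

  oneRun <- function(order_seed) {
    g <- g0
    removed <- 0
    ncs <- numeric(length(nRemove))
    if (strategy == "random") {
      set.seed(order_seed)
      plan <- sample(igraph::V(g0)$name)
    }
    for (i in seq_along(nRemove)) {
      while (removed < nRemove[i]) {
        victim <- switch(strategy,
          degree = igraph::V(g)$name[which.max(igraph::degree(g))],
          betweenness = igraph::V(g)$name[which.max(igraph::betweenness(
            g, weights = abs(igraph::E(g)$weight)))],
          random = plan[removed + 1])
        g <- igraph::delete_vertices(g, victim)
        removed <- removed + 1
      }
      ncs[i] <- naturalConnectivity(g)
    }
    ncs
  }
  ncs <- if (strategy == "random") {
    rowMeans(vapply(seq_len(n_rep), function(r) oneRun(seed + r),
                    numeric(length(nRemove))))
  } else oneRun(seed)
  nc0 <- naturalConnectivity(g0)
  rel <- if (nc0 > 0) ncs / nc0 else rep(0, length(ncs))
  span <- diff(range(removal_grid))
  auc <- if (span > 0)
    1 - sum(diff(removal_grid) * (head(rel, -1) + rel[-1]) / 2) / span
  else 0
  list(curve = data.frame(fraction = removal_grid, nc = ncs),
       fragility = nc0 - ncs[length(ncs)], auc = auc)
}
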