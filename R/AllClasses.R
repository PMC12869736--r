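#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom stats aov coef cor dist lm median na.omit p.adjust pchisq
#'   pf pnorm prcomp predict pt quantile resid rmultinom rnorm runif sd
#'   setNames var AIC anova as.dist as.formula cor.test logLik rbinom
#'   terms update vcov
#' @importFrom utils head read.table write.table combn modifyList
NULL

setOldClass("igraph")

#' AsvExperiment: an ASV count table with sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"counts"` assay (taxa as rows, samples as columns), per-sample
#' metadata in `colData` (salinity in psu, stress class, soil chemistry,
#' climate, coordinates, wetland id) and a domain tag identifying the
#' amplicon target (`"bacteria"` or `"archaea"`; `"multi"` for concatenated
#' cross-domain tables).
#'
#' @slot domain character scalar, `"bacteria"`, `"archaea"` or `"multi"`.
#'
#' @seealso [AsvExperiment()] constructor, [asvCounts()], [domainTag()].
#' @export
setClass("AsvExperiment",
  contains = "SummarizedExperiment",
  slots = c(domain = "character")
)

setValidity("AsvExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(!is.finite(cts))) msg <- c(msg, "counts must be finite")
  }
  if (length(object@domain) != 1L ||
      !object@domain %in% c("bacteria", "archaea", "multi"))
    msg <- c(msg, "domain must be one of 'bacteria', 'archaea', 'multi'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate taxon ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AsvExperiment
#'
#' @param counts numeric matrix of non-negative counts, taxa x samples. A
#'   samples x taxa matrix is accepted when `samplesAsRows = TRUE`.
#' @param sampleData data.frame (or DataFrame) of per-sample metadata, rows
#'   matching the samples of `counts`.
#' @param domain `"bacteria"`, `"archaea"` or `"multi"`.
#' @param samplesAsRows logical; set `TRUE` if `counts` has samples as rows.
#' @return An [AsvExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("ASV", 1:3), paste0("S", 1:4)))
#' ae <- AsvExperiment(m, data.frame(salinity = c(0.5, 3, 40, 100),
#'                                   row.names = colnames(m)), "bacteria")
#' domainTag(ae)
#' @export
AsvExperiment <- function(counts, sampleData = NULL, domain = "bacteria",
                          samplesAsRows = FALSE) {
  counts <- as.matrix(counts)
  if (samplesAsRows) counts <- t(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("ASV", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(counts))
  sampleData <- S4Vectors::DataFrame(sampleData)
  if (is.null(rownames(sampleData))) rownames(sampleData) <- colnames(counts)
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = sampleData)
  new("AsvExperiment", se, domain = domain)
}

#' EcoNetwork: a signed, weighted co-occurrence network over ASVs
#'
#' Undirected graph whose vertices are ASVs (with domain and mean relative
#' abundance attributes) and whose edges carry a sign (+/-) and a weight
#' (selected regression-coefficient magnitude, signed). The `provenance`
#' list records how the network was inferred (method, lambda path, selected
#' lambda, StARS settings, seed, subsample count) so any network can be
#' reproduced from its table and provenance.
#'
#' @slot graph an `igraph` object; edge attributes `weight` (signed) and
#'   `sign` (`"+"`/`"-"`); vertex attributes `name`, `domain`, `meanAbund`.
#' @slot provenance named list of inference settings.
#' @export
setClass("EcoNetwork", slots = c(graph = "igraph", provenance = "list"))

setValidity("EcoNetwork", function(object) {
  g <- object@graph
  msg <- NULL
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    s <- igraph::E(g)$sign
    if (is.null(w) || is.null(s))
      msg <- c(msg, "edges need 'weight' and 'sign' attributes")
    else if (any(ifelse(s == "+", w <= 0, w >= 0)))
      msg <- c(msg, "edge sign must match the sign of its weight")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an EcoNetwork from an edge table
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (signed
#'   numeric); a `sign` column is derived from `weight` if absent. Zero-row
#'   data.frames give an edgeless network.
#' @param nodes character vector of node ids (superset of edge endpoints),
#'   or a data.frame with columns `name` and optionally `domain`,
#'   `meanAbund`.
#' @param provenance named list recording inference settings.
#' @return An [EcoNetwork-class].
#' @examples
#' net <- EcoNetwork(data.frame(from = "A", to = "B", weight = 0.6),
#'                   nodes = c("A", "B", "C"))
#' edgeTable(net)
#' @export
EcoNetwork <- function(edges = NULL, nodes = character(), provenance = list()) {
  if (is.character(nodes)) nodes <- data.frame(name = nodes)
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (nrow(nodes)) g <- igraph::add_vertices(g, nrow(nodes), name = nodes$name)
  } else {
    edges$sign <- ifelse(edges$weight >= 0, "+", "-")
    allv <- union(nodes$name, union(edges$from, edges$to))
    nodes <- merge(data.frame(name = allv), nodes, all.x = TRUE, sort = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  }
  for (at in c("domain", "meanAbund"))
    if (!is.null(nodes[[at]]) && igraph::vcount(g) > 0)
      g <- igraph::set_vertex_attr(g, at,
        value = nodes[[at]][match(igraph::V(g)$name, nodes$name)])
  new("EcoNetwork", graph = g, provenance = provenance)
}

#' LinkProcessTable: assembly-process labels for network links
#'
#' Per-edge classification into spatial, environmental or biotic assembly
#' processes, with the Mantel-type statistics and BH-adjusted p-values of
#' the two sequential tests. Degenerate edges (zero-variance signal) are
#' flagged and excluded from the biotic set.
#'
#' @slot table data.frame with columns `from`, `to`, `process`, `r_geo`,
#'   `p_geo`, `q_geo`, `r_env`, `p_env`, `q_env`, `degenerate`.
#' @slot alpha numeric significance level used for classification.
#' @export
setClass("LinkProcessTable", slots = c(table = "data.frame", alpha = "numeric"))

setValidity("LinkProcessTable", function(object) {
  need <- c("from", "to", "process", "r_geo", "p_geo", "q_geo",
            "r_env", "p_env", "q_env", "degenerate")
  msg <- NULL
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, names(object@table)), collapse = ", ")))
  else {
    ok <- object@table$process %in% c("spatial", "environmental", "biotic") |
      object@table$degenerate
    if (!all(ok)) msg <- c(msg, "every non-degenerate edge needs a process label")
  }
  if (is.null(msg)) TRUE else msg
})

#' CohesionProfile: connectedness and cohesion
#'
#' Per-taxon positive/negative connectedness (mean positive / mean negative
#' link weight, zero when a taxon has no links of that sign) and per-sample
#' positive/negative cohesion (relative-abundance-weighted sums of
#' connectedness).
#'
#' @slot connectedness data.frame: `taxon`, `pos` (>= 0), `neg` (<= 0).
#' @slot cohesion data.frame: `sample`, `pos` (>= 0), `neg` (<= 0).
#' @export
setClass("CohesionProfile",
  slots = c(connectedness = "data.frame", cohesion = "data.frame"))

setValidity("CohesionProfile", function(object) {
  msg <- NULL
  cn <- object@connectedness
  ch <- object@cohesion
  if (!all(c("taxon", "pos", "neg") %in% names(cn)))
    msg <- c(msg, "connectedness needs taxon/pos/neg")
  else if (any(cn$pos < 0) || any(cn$neg > 0))
    msg <- c(msg, "connectedness signs violated")
  if (nrow(ch) && (any(ch$pos < -1e-12) || any(ch$neg > 1e-12)))
    msg <- c(msg, "cohesion signs violated")
  if (is.null(msg)) TRUE else msg
})
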