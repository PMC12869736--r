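#' Accessors for saltgrad classes
#'
#' `asvCounts()` returns the counts assay (taxa x samples); `domainTag()`
#' the domain label; `sampleData()` the per-sample metadata as a data.frame;
#' `edgeTable()` the signed edge list of a network; `netGraph()` the
#' underlying igraph; `provenance()` the inference provenance list;
#' `linkTable()` the per-edge process table; `connectednessTable()` and
#' `cohesionTable()` the two faces of a [CohesionProfile-class].
#'
#' @param x a saltgrad object.
#' @return See the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("asvCounts", function(x) standardGeneric("asvCounts"))
#' @rdname accessors
#' @export
setMethod("asvCounts", "AsvExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("domainTag", function(x) standardGeneric("domainTag"))
#' @rdname accessors
#' @export
setMethod("domainTag", "AsvExperiment", function(x) x@domain)

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @rdname accessors
#' @export
setMethod("sampleData", "AsvExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setMethod("edgeTable", "EcoNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), sign = character()))
  el <- igraph::as_edgelist(g)
  data.frame(from = el[, 1], to = el[, 2],
             weight = igraph::E(g)$weight, sign = igraph::E(g)$sign)
})

#' @rdname accessors
#' @export
setGeneric("netGraph", function(x) standardGeneric("netGraph"))
#' @rdname accessors
#' @export
setMethod("netGraph", "EcoNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "EcoNetwork", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))
#' @rdname accessors
#' @export
setMethod("linkTable", "LinkProcessTable", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("connectednessTable", function(x) standardGeneric("connectednessTable"))
#' @rdname accessors
#' @export
setMethod("connectednessTable", "CohesionProfile", function(x) x@connectedness)

#' @rdname accessors
#' @export
setGeneric("cohesionTable", function(x) standardGeneric("cohesionTable"))
#' @rdname accessors
#' @export
setMethod("cohesionTable", "CohesionProfile", function(x) x@cohesion)

setMethod("show", "AsvExperiment", function(object) {
  cat("AsvExperiment (", object@domain, "): ",
      nrow(object), " taxa x ", ncol(object), " samples\n", sep = "")
  cat("  total reads:", sum(asvCounts(object)),
      "| colData:", paste(head(colnames(SummarizedExperiment::colData(object)), 6),
                          collapse = ", "), "\n")
})

setMethod("show", "EcoNetwork", function(object) {
  g <- object@graph
  ne <- igraph::ecount(g)
  pn <- if (ne) mean(igraph::E(g)$sign == "-") * 100 else NA_real_
  cat("EcoNetwork:", igraph::vcount(g), "nodes,", ne, "edges",
      if (ne) sprintf("(%.1f%% negative)", pn) else "", "\n")
  if (length(object@provenance))
    cat("  inferred by:", object@provenance$method %||% "?",
        "| lambda:", signif(object@provenance$lambda_selected %||% NA, 3), "\n")
})

setMethod("show", "LinkProcessTable", function(object) {
  tab <- object@table
  cat("LinkProcessTable:", nrow(tab), "edges | ",
      sum(tab$process == "spatial", na.rm = TRUE), "spatial,",
      sum(tab$process == "environmental", na.rm = TRUE), "environmental,",
      sum(tab$process == "biotic", na.rm = TRUE), "biotic,",
      sum(tab$degenerate), "degenerate\n")
})

setMethod("show", "CohesionProfile", function(object) {
  cat("CohesionProfile:", nrow(object@connectedness), "taxa,",
      nrow(object@cohesion), "samples\n")
  if (nrow(object@cohesion))
    cat(sprintf("  mean cohesion: pos %.4f / neg %.4f\n",
                mean(object@cohesion$pos), mean(object@cohesion$neg)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
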