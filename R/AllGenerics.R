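# Generics, accessors and show methods for the core classes.

#' @rdname GeneSignature-class
#' @param object,x a SigScan object.
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))
#' @rdname GeneSignature-class
#' @export
setGeneric("signatureDirection",
           function(object) standardGeneric("signatureDirection"))
#' @rdname ExpressionSeries-class
#' @export
setGeneric("seriesId", function(object) standardGeneric("seriesId"))
#' @rdname ExpressionSeries-class
#' @export
setGeneric("exprsMatrix", function(object) standardGeneric("exprsMatrix"))
#' @rdname ExpressionSeries-class
#' @export
setGeneric("seriesTitle", function(object) standardGeneric("seriesTitle"))
#' @rdname ExpressionSeries-class
#' @export
setGeneric("seriesSummary", function(object) standardGeneric("seriesSummary"))
#' @rdname ScanResult-class
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))
#' @rdname ScanResult-class
#' @export
setGeneric("selectedSeries", function(object) standardGeneric("selectedSeries"))
#' @rdname DEResult-class
#' @export
setGeneric("deTable", function(object) standardGeneric("deTable"))
#' @rdname DEResult-class
#' @export
setGeneric("fdrEstimate", function(object) standardGeneric("fdrEstimate"))
#' @rdname SummaryGraph-class
#' @export
setGeneric("graphClusters", function(object) standardGeneric("graphClusters"))
#' @rdname SummaryGraph-class
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname GeneSignature-class
#' @export
setMethod("signatureGenes", "GeneSignature", function(object) object@genes)
#' @rdname GeneSignature-class
#' @export
setMethod("signatureDirection", "GeneSignature", function(object) {
  stats::setNames(object@direction, object@genes)
})
#' @rdname DEResult-class
#' @export
setMethod("signatureGenes", "DEResult",
          function(object) object@signature@genes)
#' @rdname DEResult-class
#' @export
setMethod("signatureDirection", "DEResult",
          function(object) signatureDirection(object@signature))

#' @rdname ExpressionSeries-class
#' @export
setMethod("seriesId", "ExpressionSeries", function(object) object@seriesId)
#' @rdname ExpressionSeries-class
#' @export
setMethod("exprsMatrix", "ExpressionSeries", function(object) object@exprs)
#' @rdname ExpressionSeries-class
#' @export
setMethod("seriesTitle", "ExpressionSeries", function(object) object@title)
#' @rdname ExpressionSeries-class
#' @export
setMethod("seriesSummary", "ExpressionSeries", function(object) object@summary)

#' @rdname SeriesCollection-class
#' @export
setMethod("length", "SeriesCollection", function(x) length(x@series))
#' @rdname SeriesCollection-class
#' @param i index or series identifier.
#' @export
setMethod("[[", "SeriesCollection", function(x, i) x@series[[i]])
#' @rdname SeriesCollection-class
#' @export
setMethod("names", "SeriesCollection", function(x) names(x@series))

#' @rdname ScanResult-class
#' @export
setMethod("scanTable", "ScanResult", function(object) object@table)
#' @rdname ScanResult-class
#' @export
setMethod("selectedSeries", "ScanResult",
          function(object) object@table$seriesId[object@table$selected])

#' @rdname DEResult-class
#' @export
setMethod("deTable", "DEResult", function(object) object@table)
#' @rdname DEResult-class
#' @export
setMethod("fdrEstimate", "DEResult", function(object) object@fdrEstimate)

#' @rdname SummaryGraph-class
#' @export
setMethod("graphClusters", "SummaryGraph", function(object) object@clusters)
#' @rdname SummaryGraph-class
#' @export
setMethod("graphEdges", "SummaryGraph", function(object) object@edges)

setMethod("show", "GeneSignature", function(object) {
  n <- length(object@genes)
  cat("GeneSignature of", n, "genes (",
      sum(object@direction == 1L), "up,", sum(object@direction == -1L),
      "down )\n")
  if (n) cat("  ", paste(utils::head(object@genes, 8), collapse = ", "),
             if (n > 8) "..." else "", "\n")
})

setMethod("show", "ExpressionSeries", function(object) {
  cat("ExpressionSeries", object@seriesId, ":",
      nrow(object@exprs), "genes x", ncol(object@exprs), "samples\n")
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
})

setMethod("show", "SeriesCollection", function(object) {
  cat("SeriesCollection of", length(object@series), "series\n")
})

setMethod("show", "DEResult", function(object) {
  cat("DEResult:", object@testedCount, "genes tested at alpha =",
      object@alpha, "\n  selected:", sum(object@table$selected),
      " FDR estimate:", signif(object@fdrEstimate, 3), "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult:", nrow(object@table), "series scanned,",
      sum(object@table$selected), "selected\n")
  if (nrow(object@table))
    cat("  best p-value:", format(object@table$pValue[1], digits = 4), "\n")
})

setMethod("show", "NeighborMatrix", function(object) {
  cat("NeighborMatrix:", length(object@lGenes), "query genes x",
      length(object@neighbors), "neighbors (",
      sum(object@m), "relations )\n")
})

setMethod("show", "SummaryGraph", function(object) {
  cat("SummaryGraph:", length(object@clusters), "clusters,",
      nrow(object@edges), "edges (connectivity >=", object@threshold, ")\n")
})
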