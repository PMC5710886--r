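#' @import methods
NULL

#' GeneSignature: an ordered, directed gene list
#'
#' A gene signature is an ordered list of gene identifiers together with the
#' expected sign of each gene in driver-high samples (+1 over-expressed,
#' -1 under-expressed). Identifiers are opaque, case-sensitive strings.
#'
#' @slot genes character vector of unique gene identifiers.
#' @slot direction integer vector of +1/-1, one per gene.
#'
#' @examples
#' sig <- GeneSignature(c("LMO2", "TNFRSF9"), direction = c(-1L, -1L))
#' signatureGenes(sig)
#' @export
setClass("GeneSignature",
  representation(genes = "character", direction = "integer"),
  prototype(genes = character(0), direction = integer(0))
)

setValidity("GeneSignature", function(object) {
  msg <- NULL
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate gene identifiers in signature")
  if (length(object@direction) != length(object@genes))
    msg <- c(msg, "direction length must equal gene count")
  if (length(object@direction) && !all(object@direction %in% c(-1L, 1L)))
    msg <- c(msg, "direction entries must be +1 or -1")
  if (is.null(msg)) TRUE else msg
})

#' @param genes character vector of gene identifiers.
#' @param direction integer vector of +1/-1 expected signs (default all +1).
#' @rdname GeneSignature-class
#' @export
GeneSignature <- function(genes, direction = rep(1L, length(genes))) {
  if (length(genes) == 0L)
    stop("a gene signature must contain at least one gene")
  new("GeneSignature", genes = as.character(genes),
      direction = as.integer(direction))
}

#' ExpressionSeries: one study's expression matrix plus annotation
#'
#' Wraps a genes x samples numeric matrix (post-normalization expression
#' units) together with the free-text annotation (title, summary) of the
#' study it came from. Row names are gene identifiers, column names sample
#' identifiers; both must be unique and all values finite.
#'
#' @slot seriesId single series accession/identifier.
#' @slot exprs numeric matrix, genes in rows, samples in columns.
#' @slot title study title (may be empty).
#' @slot summary study summary text (may be empty).
#' @export
setClass("ExpressionSeries",
  representation(seriesId = "character", exprs = "matrix",
                 title = "character", summary = "character"),
  prototype(seriesId = NA_character_, title = "", summary = "")
)

setValidity("ExpressionSeries", function(object) {
  msg <- NULL
  m <- object@exprs
  if (length(object@seriesId) != 1L)
    msg <- c(msg, "seriesId must be a single string")
  if (!is.numeric(m))
    msg <- c(msg, "expression values must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "expression matrix needs gene row names and sample column names")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sample identifiers")
  }
  if (is.numeric(m) && length(m) && !all(is.finite(m)))
    msg <- c(msg, "expression values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @param seriesId single series identifier.
#' @param exprs numeric genes x samples matrix with dimnames.
#' @param title,summary annotation text.
#' @rdname ExpressionSeries-class
#' @export
ExpressionSeries <- function(seriesId, exprs, title = "", summary = "") {
  new("ExpressionSeries", seriesId = as.character(seriesId),
      exprs = exprs, title = as.character(title), summary = as.character(summary))
}

#' SeriesCollection: the scan corpus
#'
#' An ordered collection of \linkS4class{ExpressionSeries} with unique series
#' identifiers; the unit over which the conservation scan and annotation
#' mining operate.
#'
#' @slot series list of ExpressionSeries objects.
#' @export
setClass("SeriesCollection", representation(series = "list"))

setValidity("SeriesCollection", function(object) {
  if (!all(vapply(object@series, is, logical(1), "ExpressionSeries")))
    return("all elements must be ExpressionSeries")
  ids <- vapply(object@series, function(s) s@seriesId, character(1))
  if (anyDuplicated(ids)) return("duplicate series identifiers")
  TRUE
})

#' @param series list of ExpressionSeries.
#' @rdname SeriesCollection-class
#' @export
SeriesCollection <- function(series) {
  series <- unname(series)
  obj <- new("SeriesCollection", series = series)
  names(obj@series) <- vapply(series, function(s) s@seriesId, character(1))
  obj
}

#' DEResult: differential-signature test result
#'
#' Per-gene two-sample t statistics and p-values from the driver-stratified
#' comparison, the selected signature, and the analytic FDR estimate
#' m * alpha / k.
#'
#' @slot table data.frame with columns gene, t, p, direction, selected.
#' @slot testedCount number of genes tested (m).
#' @slot alpha per-gene risk level used for selection.
#' @slot fdrEstimate m * alpha / selected count, capped at 1 (NA when no
#'   gene was selected).
#' @slot signature the selected \linkS4class{GeneSignature} (zero genes when
#'   nothing passed alpha).
#' @export
setClass("DEResult",
  representation(table = "data.frame", testedCount = "integer",
                 alpha = "numeric", fdrEstimate = "numeric",
                 signature = "GeneSignature"))

setValidity("DEResult", function(object) {
  need <- c("gene", "t", "p", "direction", "selected")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (any(!is.finite(object@table$p)))
    return("p-values must be finite")
  if (!all(object@signature@genes %in% object@table$gene))
    return("selected genes must be among tested genes")
  TRUE
})

#' ScanResult: ranked, Holm-adjusted collection scan
#'
#' One best sample pair per scanned series, ranked by ascending p-value, with
#' Holm-adjusted p-values and selection flags at the configured thresholds.
#'
#' @slot table data.frame, one row per scanned series, ordered by ascending
#'   p-value, with columns seriesId, sampleI, sampleJ, covered, coverage,
#'   nInformative, kPositive, proportion, pValue, holmAdjusted, selected.
#' @slot mTests number of hypotheses the Holm correction was applied over.
#' @slot params list of scan parameters (thresholds, tie policy, ...).
#' @export
setClass("ScanResult",
  representation(table = "data.frame", mTests = "integer", params = "list"))

setValidity("ScanResult", function(object) {
  tab <- object@table
  need <- c("seriesId", "sampleI", "sampleJ", "covered", "nInformative",
            "kPositive", "proportion", "pValue", "holmAdjusted", "selected")
  if (!all(need %in% names(tab)))
    return(paste("missing scan columns:", paste(setdiff(need, names(tab)), collapse = ", ")))
  if (nrow(tab)) {
    if (is.unsorted(tab$pValue)) return("table must be sorted by ascending p-value")
    if (any(tab$holmAdjusted < tab$pValue - 1e-12))
      return("Holm-adjusted p-values must dominate raw p-values")
  }
  TRUE
})

#' NeighborMatrix: Boolean signature-gene x neighbor relation
#'
#' Models per-query-gene co-expression neighbor lists as a Boolean matrix
#' m(i, j): row i is a queried signature gene, column j a neighbor gene, and
#' m(i, j) is TRUE iff j was returned as a neighbor of i. A gene may appear
#' both as a query row and a neighbor column.
#'
#' @slot lGenes queried signature-gene identifiers (rows).
#' @slot neighbors union of returned neighbor identifiers (columns).
#' @slot m logical matrix, dim = length(lGenes) x length(neighbors).
#' @slot support numeric per-neighbor support counts (series-occurrence
#'   metadata; NA when not supplied). Plays no role in clustering.
#' @export
setClass("NeighborMatrix",
  representation(lGenes = "character", neighbors = "character",
                 m = "matrix", support = "numeric"))

setValidity("NeighborMatrix", function(object) {
  msg <- NULL
  if (anyDuplicated(object@lGenes)) msg <- c(msg, "duplicate query genes")
  if (anyDuplicated(object@neighbors)) msg <- c(msg, "duplicate neighbor genes")
  if (!is.logical(object@m)) msg <- c(msg, "m must be logical")
  if (!identical(dim(object@m),
                 c(length(object@lGenes), length(object@neighbors))))
    msg <- c(msg, "m dimensions inconsistent with identifier lists")
  if (length(object@support) != length(object@neighbors))
    msg <- c(msg, "support length must equal neighbor count")
  if (is.null(msg)) TRUE else msg
})

#' SummaryGraph: biclique-constrained cluster graph
#'
#' The condensed view of the gene co-expression neighborhood: nodes are
#' fully-connected gene clusters (every signature gene pairwise connected,
#' every neighbor connected to all signature genes in the cluster), edges
#' link cluster pairs whose inter-cluster connectivity meets the threshold.
#'
#' @slot clusters list; each element has character vectors $members and
#'   $lMembers (the subset that are signature genes).
#' @slot nodes data.frame with clusterId, size, lCount.
#' @slot edges data.frame with from, to (cluster ids), connectivity.
#' @slot threshold the connectivity threshold used at construction.
#' @export
setClass("SummaryGraph",
  representation(clusters = "list", nodes = "data.frame",
                 edges = "data.frame", threshold = "numeric"))

setValidity("SummaryGraph", function(object) {
  msg <- NULL
  if (nrow(object@edges)) {
    if (!all(c("from", "to", "connectivity") %in% names(object@edges)))
      msg <- c(msg, "edges need from, to, connectivity")
    else if (any(object@edges$connectivity < object@threshold - 1e-12))
      msg <- c(msg, "edge below construction threshold")
  }
  all_members <- unlist(lapply(object@clusters, `[[`, "members"))
  if (anyDuplicated(all_members))
    msg <- c(msg, "clusters must be pairwise disjoint")
  if (is.null(msg)) TRUE else msg
})
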