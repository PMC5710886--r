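# Gene-set enrichment of a signature against an annotated background
# universe: the enrichment ratio (term frequency in the list over term
# frequency in the background), hypergeometric significance, and the
# assembled per-term table with BH FDR.

#' Enrichment ratio of a term in a gene list
#'
#' The fold enrichment (c / listSize) / (T / N): the frequency of the term
#' among the c list members annotated with it, relative to its frequency
#' among the T annotated genes of the N-gene background universe. Zero when
#' c = 0.
#'
#' @param c number of list genes annotated with the term.
#' @param listSize number of genes in the list.
#' @param T number of background genes annotated with the term (> 0).
#' @param N background universe size.
#' @return the fold-enrichment ratio (>= 0).
#' @examples
#' enrichmentRatio(22, 57, 921, 12982)
#' @export
enrichmentRatio <- function(c, listSize, T, N) {
  stopifnot(listSize >= 1, c >= 0, T >= 0, T <= N)
  if (T == 0) stop("enrichment undefined for an empty term")
  stopifnot(c <= min(listSize, T))
  if (c == 0) return(0)
  (c / listSize) / (T / N)
}

#' Hypergeometric over-representation significance
#'
#' One-sided p-value P(X >= c) for X hypergeometric with T annotated genes
#' among N, drawing listSize genes: the probability of observing at least
#' the attained overlap by chance. Exact tail summation (via the
#' hypergeometric distribution function).
#'
#' @inheritParams enrichmentRatio
#' @param lower compute the under-representation tail P(X <= c) instead.
#' @return the tail probability.
#' @examples
#' termSignificance(4, 4, 5, 10)  # 5 / 210
#' @export
termSignificance <- function(c, listSize, T, N, lower = FALSE) {
  stopifnot(c >= 0, c <= min(listSize, T), T <= N, listSize >= 1)
  if (lower) stats::phyper(c, T, N - T, listSize, lower.tail = TRUE)
  else stats::phyper(c - 1, T, N - T, listSize, lower.tail = FALSE)
}

#' Enrich a gene signature against annotated gene sets
#'
#' For every annotation term with at least one list member, computes the
#' member counts against the background universe, the fold-enrichment
#' ratio, the over-representation p-value (with the under-representation
#' tail in a separate column), -log10(p) and the BH FDR, sorted by
#' ascending p. Signature genes absent from the background are dropped with
#' a warning; term members outside the background are ignored.
#'
#' @param signature a \linkS4class{GeneSignature} or character vector of
#'   gene identifiers.
#' @param annotations list of gene sets; each element a list with
#'   \code{$termId}, \code{$termName} and \code{$genes} (as returned by
#'   \code{\link{readGmt}}).
#' @param background character vector: the gene universe (non-empty).
#' @return data.frame with columns termId, termName, totalGenes,
#'   changedGenes, enrichment, pValue, pUnder, log10P, fdr.
#' @export
enrichList <- function(signature, annotations, background) {
  genes <- if (is(signature, "GeneSignature")) signatureGenes(signature)
           else as.character(signature)
  if (length(background) == 0L) stop("empty background universe")
  background <- unique(background)
  N <- length(background)
  outside <- setdiff(genes, background)
  if (length(outside)) {
    warning("dropping ", length(outside),
            " signature gene(s) absent from the background: ",
            paste(utils::head(outside, 5), collapse = ", "))
    genes <- intersect(genes, background)
  }
  listSize <- length(genes)
  if (listSize == 0L) stop("no signature gene in the background universe")
  rows <- lapply(annotations, function(ann) {
    members <- intersect(ann$genes, background)
    T <- length(members)
    c_ <- length(intersect(members, genes))
    if (c_ == 0L || T == 0L) return(NULL)
    data.frame(termId = ann$termId, termName = ann$termName,
               totalGenes = T, changedGenes = c_,
               enrichment = enrichmentRatio(c_, listSize, T, N),
               pValue = termSignificance(c_, listSize, T, N),
               pUnder = termSignificance(c_, listSize, T, N, lower = TRUE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(termId = character(0), termName = character(0),
                      totalGenes = integer(0), changedGenes = integer(0),
                      enrichment = numeric(0), pValue = numeric(0),
                      pUnder = numeric(0), log10P = numeric(0),
                      fdr = numeric(0)))
  tab <- do.call(rbind, rows)
  tab$log10P <- -log10(tab$pValue)
  tab$fdr <- stats::p.adjust(tab$pValue, method = "BH")
  tab <- tab[order(tab$pValue, tab$termId), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
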