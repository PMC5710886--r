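# Annotation term mining: bag-of-words tokenization of series titles and
# summaries, per-term Fisher tests of selected vs remaining series, and the
# ranked significant-term table.

# Compact built-in English stop-word list. Tokenization already drops
# tokens shorter than 3 characters, so only longer function words appear.
.STOPWORDS <- c(
  "the", "and", "for", "are", "was", "were", "with", "from", "that", "this",
  "these", "those", "have", "has", "had", "not", "but", "all", "can",
  "which", "their", "there", "been", "into", "using", "used", "use",
  "between", "within", "during", "after", "before", "than", "then", "when",
  "where", "while", "also", "such", "each", "per", "via", "upon", "both",
  "its", "his", "her", "our", "your", "they", "them", "were", "being",
  "other", "more", "most", "some", "any", "may", "might", "will", "would",
  "could", "should", "does", "did", "done", "about", "against", "because",
  "study", "studies", "data", "dataset", "datasets", "analysis", "series",
  "samples", "sample", "gene", "genes", "expression", "profiling",
  "profiles", "profile", "microarray", "array", "arrays")

#' Tokenize series annotations into term sets
#'
#' Lower-cases the concatenated title and summary, strips punctuation and
#' digits, drops tokens shorter than \code{minLength} and built-in English
#' stop words (plus generic expression-study boilerplate), and returns the
#' unique token set: presence, not frequency, is what the term test uses.
#'
#' @param title,summary annotation text (may be empty strings).
#' @param minLength minimum token length (default 3).
#' @param stopwords character vector of words to drop.
#' @return character vector of unique terms (possibly empty).
#' @examples
#' tokenizeAnnotations("Breast cancer tumor profiling", "")
#' @export
tokenizeAnnotations <- function(title, summary = "", minLength = 3L,
                                stopwords = .STOPWORDS) {
  text <- tolower(paste(title, summary))
  tokens <- strsplit(gsub("[^a-z]+", " ", text), " +")[[1]]
  tokens <- tokens[nchar(tokens) >= minLength]
  unique(setdiff(tokens, stopwords))
}

# 2x2 odds ratio with the Haldane-Anscombe 0.5 correction applied when any
# cell is empty.
haldaneOdds <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Fisher test of one term between selected and remaining series
#'
#' Builds the 2x2 table (term present/absent x selected/remaining), each
#' series counted once, and computes the two-sided Fisher exact p together
#' with the sample odds ratio (Haldane-corrected when a cell is zero). A
#' term absent from every series gives p = 1, odds ratio 1.
#'
#' @param term the term to test.
#' @param selectedSets,remainingSets lists of per-series term sets (from
#'   \code{\link{tokenizeAnnotations}}), both non-empty.
#' @return one-row data.frame: term, selectedWith, selectedTotal,
#'   remainingWith, remainingTotal, oddsRatio, pValue.
#' @export
termFisher <- function(term, selectedSets, remainingSets) {
  stopifnot(length(selectedSets) > 0, length(remainingSets) > 0)
  a <- sum(vapply(selectedSets, function(s) term %in% s, logical(1)))
  c_ <- sum(vapply(remainingSets, function(s) term %in% s, logical(1)))
  b <- length(selectedSets) - a
  d <- length(remainingSets) - c_
  if (a + c_ == 0L) {
    p <- 1; or <- 1
  } else {
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
    or <- haldaneOdds(a, b, c_, d)
  }
  data.frame(term = term, selectedWith = a, selectedTotal = length(selectedSets),
             remainingWith = c_, remainingTotal = length(remainingSets),
             oddsRatio = or, pValue = p, stringsAsFactors = FALSE)
}

#' Mine annotation terms enriched in a series selection
#'
#' Tokenizes the annotations of every series in the collection, compares
#' each sufficiently frequent term between the selected series and the
#' remaining series with a two-sided Fisher exact test, applies a multiple-
#' testing correction, and returns the table sorted by ascending p.
#'
#' @param collection a \linkS4class{SeriesCollection}.
#' @param selection character vector of selected series identifiers (subset
#'   of the collection; typically \code{selectedSeries(scanResult)}).
#' @param minOccurrence minimum number of series a term must occur in to be
#'   tested (default 3).
#' @param correction p-value adjustment method: "BH" (default) or "holm".
#' @param minLength,stopwords passed to \code{\link{tokenizeAnnotations}}.
#' @return data.frame with the \code{\link{termFisher}} columns plus
#'   adjusted, sorted by pValue.
#' @export
significantTerms <- function(collection, selection, minOccurrence = 3L,
                             correction = c("BH", "holm"), minLength = 3L,
                             stopwords = .STOPWORDS) {
  correction <- match.arg(correction)
  if (length(selection) == 0L) stop("empty selection")
  ids <- names(collection)
  if (!all(selection %in% ids))
    stop("selection contains series not in the collection")
  sets <- lapply(ids, function(id) {
    s <- collection[[id]]
    tokenizeAnnotations(seriesTitle(s), seriesSummary(s),
                        minLength = minLength, stopwords = stopwords)
  })
  names(sets) <- ids
  sel <- sets[ids %in% selection]
  rem <- sets[!ids %in% selection]
  if (length(rem) == 0L) stop("no remaining series to compare against")
  counts <- table(unlist(lapply(sets, unique)))
  vocab <- names(counts)[counts >= minOccurrence]
  if (length(vocab) == 0L)
    return(data.frame(term = character(0), selectedWith = integer(0),
                      selectedTotal = integer(0), remainingWith = integer(0),
                      remainingTotal = integer(0), oddsRatio = numeric(0),
                      pValue = numeric(0), adjusted = numeric(0)))
  tab <- do.call(rbind, lapply(vocab, termFisher, selectedSets = sel,
                               remainingSets = rem))
  tab$adjusted <- stats::p.adjust(tab$pValue,
                                  method = if (correction == "BH") "BH" else "holm")
  tab <- tab[order(tab$pValue, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
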