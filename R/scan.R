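# Conservation scan: rank normalization, the exact binomial
# sign-coordination statistic over sample pairs, per-series best-pair scan,
# and collection-level ranking with Holm correction and selection.

#' Rank-based normalization of one sample
#'
#' Replaces the expression values of one sample by (rank - 1) / (n - 1),
#' with average ranks for ties, mapping every sample profile onto [0, 1].
#' Order-preserving, hence invariant to strictly monotone per-sample
#' distortions; a fully tied sample maps to 0.5 throughout.
#'
#' @param x numeric vector of one sample's expression values (length >= 2).
#' @return numeric vector in [0, 1].
#' @examples
#' rankNormalize(c(3.2, 1.1, 5.0))
#' @export
rankNormalize <- function(x) {
  if (length(x) < 2L) stop("rank normalization needs at least 2 values")
  (rank(x, ties.method = "average") - 1) / (length(x) - 1)
}

#' Exact fair-coin binomial upper tail
#'
#' P(X >= k) for X ~ Binomial(n, 1/2). For n <= 64 the tail is the rational
#' sum of binomial coefficients over 2^n, always accumulated over the
#' smaller side of the distribution so the summed coefficients stay small
#' (and exactly representable wherever they fit in double precision);
#' beyond that range the log-space cumulative is used.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials; n = 0 returns 1.
#' @return the upper-tail probability in (0, 1].
#' @examples
#' binomTail(10, 10)  # 2^-10
#' binomTail(44, 48)  # 213053 / 2^48
#' @export
binomTail <- function(k, n) {
  stopifnot(k >= 0, k <= n)
  if (n == 0L || k == 0L) return(1)
  if (n <= 64L) {
    p <- if (n - k < k) sum(choose(n, k:n)) / 2^n
         else 1 - sum(choose(n, 0:(k - 1))) / 2^n
    min(max(p, 2^-n), 1)
  } else {
    stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  }
}

# Signs of the per-gene differences between two samples over the covered
# signature genes. Returns counts of positive, negative and tied genes.
pairSigns <- function(exprs, genes, i, j) {
  covered <- intersect(genes, rownames(exprs))
  d <- exprs[covered, i] - exprs[covered, j]
  list(covered = length(covered), pos = sum(d > 0), neg = sum(d < 0),
       ties = sum(d == 0))
}

# Assemble one PairScore row for an ordered pair with kPositive positives.
pairRow <- function(seriesId, si, sj, covered, k, n, ties,
                    orientationCorrection) {
  p <- binomTail(max(k, n - k), n)
  if (orientationCorrection) p <- min(1, 2 * p)
  if (n == 0L) p <- 1
  data.frame(seriesId = seriesId, sampleI = si, sampleJ = sj,
             covered = covered, nInformative = n, kPositive = k,
             proportion = if (n > 0L) k / n else NA_real_,
             pValue = p, stringsAsFactors = FALSE)
}

#' Sign-coordination statistic for one ordered sample pair
#'
#' For signature genes covered by the series, counts the genes whose
#' difference s_i - s_j is strictly positive. Under the fair-Bernoulli null
#' the sign of each difference is a fair coin, so the p-value is the exact
#' binomial tail at the orientation-maximal count. A perfectly coordinated
#' change gives proportion 1 in one orientation.
#'
#' Tied genes (zero difference) are excluded from both numerator and
#' denominator under the default \code{tiePolicy = "exclude"} (the sign
#' model is undefined at zero, and rank normalization makes ties rare);
#' \code{"against"} keeps them in the denominator. With no informative gene
#' the p-value is 1 by convention, never an error.
#'
#' @param series an \linkS4class{ExpressionSeries} (values used as stored;
#'   apply \code{\link{rankNormalize}} first for the standard pipeline, as
#'   \code{\link{scanSeries}} does).
#' @param signature a \linkS4class{GeneSignature}; genes absent from the
#'   series are skipped.
#' @param i,j distinct sample identifiers (the ordered pair).
#' @param tiePolicy "exclude" (default) or "against".
#' @param orientationCorrection double the one-sided tail to correct for
#'   scoring both orientations (off by default: the scan works on ordered
#'   pairs).
#' @return one-row data.frame: seriesId, sampleI, sampleJ, covered,
#'   nInformative, kPositive, proportion, pValue.
#' @export
pairStatistic <- function(series, signature, i, j,
                          tiePolicy = c("exclude", "against"),
                          orientationCorrection = FALSE) {
  tiePolicy <- match.arg(tiePolicy)
  stopifnot(i != j)
  exprs <- exprsMatrix(series)
  stopifnot(i %in% colnames(exprs), j %in% colnames(exprs))
  s <- pairSigns(exprs, signatureGenes(signature), i, j)
  if (s$covered == 0L)
    stop("no signature gene covered by series ", seriesId(series))
  n <- if (tiePolicy == "exclude") s$pos + s$neg else s$covered
  pairRow(seriesId(series), i, j, s$covered, s$pos, n, s$ties,
          orientationCorrection)
}

#' Best coordinated sample pair of one series
#'
#' Rank-normalizes each sample (optional), evaluates every sample pair in
#' both orientations, and returns the pair with the smallest sign-
#' coordination p-value, reported in its winning orientation. Equal
#' p-values break lexicographically by (sampleI, sampleJ) for determinism.
#'
#' @inheritParams pairStatistic
#' @param rankNormalizeFirst apply per-sample rank normalization before
#'   scoring (default TRUE, the standard preprocessing).
#' @return one-row data.frame as \code{\link{pairStatistic}}.
#' @export
scanSeries <- function(series, signature, tiePolicy = c("exclude", "against"),
                       orientationCorrection = FALSE,
                       rankNormalizeFirst = TRUE) {
  tiePolicy <- match.arg(tiePolicy)
  exprs <- exprsMatrix(series)
  if (ncol(exprs) < 2L)
    stop("series ", seriesId(series), " has fewer than 2 samples")
  if (rankNormalizeFirst) exprs <- apply(exprs, 2L, rankNormalize)
  genes <- signatureGenes(signature)
  covered_genes <- intersect(genes, rownames(exprs))
  if (length(covered_genes) == 0L)
    stop("no signature gene covered by series ", seriesId(series))
  samples <- sort(colnames(exprs))
  best <- NULL
  for (a_idx in seq_len(length(samples) - 1L)) {
    for (b_idx in seq((a_idx + 1L), length(samples))) {
      a <- samples[a_idx]; b <- samples[b_idx]
      s <- pairSigns(exprs, covered_genes, a, b)
      n <- if (tiePolicy == "exclude") s$pos + s$neg else s$covered
      # orientation with the larger positive count wins; on a tie the
      # lexicographically first ordering (a, b) is kept
      if (s$pos >= n - s$pos) {
        row <- pairRow(seriesId(series), a, b, s$covered, s$pos, n, s$ties,
                       orientationCorrection)
      } else {
        row <- pairRow(seriesId(series), b, a, s$covered, n - s$pos, n,
                       s$ties, orientationCorrection)
      }
      if (is.null(best) || row$pValue < best$pValue) best <- row
    }
  }
  best
}

#' Holm step-down adjustment
#'
#' Family-wise-error control: sort p-values ascending, multiply the rank-r
#' value by (m - r + 1), take the running maximum, cap at 1, and restore the
#' input order. Thin wrapper over \code{stats::p.adjust(method = "holm")}.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
holmAdjust <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Scan a series collection for conserved signature coordination
#'
#' Retains the best (smallest p) sample pair of every scannable series,
#' ranks the per-series p-values ascending, applies the Holm correction
#' with m = number of scanned series, and selects the first \code{topN}
#' entries of the ranking that also satisfy the proportion, raw-p and
#' adjusted-p thresholds. Default thresholds are the published selection
#' rule: 250 pairs, proportion >= 0.9, p < 1.9e-8, Holm-adjusted p <
#' 3.0e-5.
#'
#' Series with fewer than 2 samples, or covering less than
#' \code{minCoverage} of the signature (default 0.8, the smallest platform
#' coverage tolerated), are excluded with a warning and absent from the
#' result.
#'
#' @param collection a \linkS4class{SeriesCollection}.
#' @inheritParams scanSeries
#' @param topN maximum number of selected pairs.
#' @param minProportion minimum positive-change proportion for selection.
#' @param maxP maximum raw p-value for selection.
#' @param maxAdjusted maximum Holm-adjusted p-value for selection.
#' @param minCoverage minimum fraction of signature genes a series must
#'   cover to be scanned.
#' @return a \linkS4class{ScanResult}.
#' @export
scanCollection <- function(collection, signature, topN = 250,
                           minProportion = 0.9, maxP = 1.9e-8,
                           maxAdjusted = 3.0e-5, minCoverage = 0.8,
                           tiePolicy = c("exclude", "against"),
                           orientationCorrection = FALSE,
                           rankNormalizeFirst = TRUE) {
  tiePolicy <- match.arg(tiePolicy)
  nsig <- length(signatureGenes(signature))
  rows <- list()
  coverage <- numeric(0)
  for (id in names(collection)) {
    ser <- collection[[id]]
    exprs <- exprsMatrix(ser)
    if (ncol(exprs) < 2L) {
      warning("skipping ", id, ": fewer than 2 samples")
      next
    }
    cov <- length(intersect(signatureGenes(signature), rownames(exprs))) / nsig
    if (cov < minCoverage) {
      warning("skipping ", id, ": signature coverage ",
              signif(cov, 3), " below ", minCoverage)
      next
    }
    best <- scanSeries(ser, signature, tiePolicy = tiePolicy,
                       orientationCorrection = orientationCorrection,
                       rankNormalizeFirst = rankNormalizeFirst)
    coverage[id] <- cov
    rows[[id]] <- best
  }
  if (length(rows) == 0L) stop("no scannable series in the collection")
  tab <- do.call(rbind, rows)
  tab$coverage <- unname(coverage[tab$seriesId])
  ord <- order(tab$pValue, tab$seriesId, tab$sampleI, tab$sampleJ)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$holmAdjusted <- holmAdjust(tab$pValue)
  passes <- !is.na(tab$proportion) & tab$proportion >= minProportion &
    tab$pValue <= maxP & tab$holmAdjusted <= maxAdjusted
  tab$selected <- passes & cumsum(passes) <= topN
  new("ScanResult", table = tab, mTests = nrow(tab),
      params = list(topN = topN, minProportion = minProportion,
                    maxP = maxP, maxAdjusted = maxAdjusted,
                    minCoverage = minCoverage, tiePolicy = tiePolicy,
                    orientationCorrection = orientationCorrection,
                    rankNormalizeFirst = rankNormalizeFirst))
}
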