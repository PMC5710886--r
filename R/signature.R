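# Driver-stratified signature extraction: low-expression filtering,
# stratification on a driver gene, per-gene t tests, analytic FDR, and the
# published two-gene linear risk scores.

#' Filter genes with low expression across most samples
#'
#' A gene is rejected when its value is strictly below the per-sample median
#' (the median over all genes of that sample) in more than
#' \code{maxLowFraction} of the samples. The reference medians are those of
#' the matrix as supplied — the full post-normalization profile of each
#' sample, before any filtering. Because removing low genes shifts a
#' recomputed median upward, re-applying the filter is only a no-op when the
#' original reference is reused; pass \code{sampleMedians} to hold it fixed.
#' Gene order is preserved.
#'
#' @param exprs numeric genes x samples matrix with dimnames.
#' @param maxLowFraction maximum tolerated fraction of below-median samples
#'   (default 2/3).
#' @param sampleMedians optional per-sample reference medians (aligned to
#'   the columns); default: the medians of \code{exprs} itself.
#' @return the filtered matrix (possibly zero rows).
#' @examples
#' m <- matrix(c(10, 1, 10, 1, 10, 1, 1, 10, 10, 1, 10, 1), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' rownames(filterLowExpression(m))
#' @export
filterLowExpression <- function(exprs, maxLowFraction = 2 / 3,
                                sampleMedians = NULL) {
  stopifnot(is.matrix(exprs), is.numeric(exprs))
  if (nrow(exprs) < 1L || ncol(exprs) < 2L)
    stop("need at least 1 gene and 2 samples to filter")
  med <- if (is.null(sampleMedians)) apply(exprs, 2L, stats::median)
         else {
           stopifnot(length(sampleMedians) == ncol(exprs))
           sampleMedians
         }
  below <- sweep(exprs, 2L, med, `<`)
  low_count <- rowSums(below)
  keep <- low_count <= maxLowFraction * ncol(exprs)
  exprs[keep, , drop = FALSE]
}

#' Stratify samples by driver-gene expression
#'
#' Splits samples into a driver-high group (driver value >= \code{highCut})
#' and a driver-low group (<= \code{lowCut}); samples between the cuts are
#' excluded from both. Both cut comparisons are inclusive.
#'
#' @param driverValues named numeric vector of per-sample driver expression;
#'   names must cover the samples of interest.
#' @param highCut,lowCut inclusive thresholds, highCut > lowCut. Defaults 2
#'   and 1, the conventional cuts for normalized driver transcript level.
#' @return list with character vectors \code{$high} and \code{$low} of sample
#'   identifiers.
#' @export
stratifyByDriver <- function(driverValues, highCut = 2, lowCut = 1) {
  stopifnot(highCut > lowCut)
  if (is.null(names(driverValues)))
    stop("driverValues must be named by sample identifier")
  high <- names(driverValues)[driverValues >= highCut]
  low <- names(driverValues)[driverValues <= lowCut]
  if (length(high) == 0L || length(low) == 0L)
    stop("stratification failed: high group has ", length(high),
         " samples, low group has ", length(low))
  list(high = high, low = low)
}

# Vectorized two-sample t over matrix rows. Equal-variance by default
# (classic microarray practice); Welch behind a flag. Zero-variance genes:
# p = 1 when the group means are equal, otherwise the variance is floored at
# the smallest positive per-gene variance in the matrix times 1e-6 so the
# statistic stays finite and the gene ranks at the top.
rowTTest <- function(exprs, high, low, welch = FALSE) {
  x <- exprs[, high, drop = FALSE]
  y <- exprs[, low, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- pooled * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  diff <- m1 - m2
  degenerate <- se2 <= 0 | !is.finite(df)
  if (any(degenerate)) {
    pos <- se2[se2 > 0 & is.finite(se2)]
    floor_se2 <- if (length(pos)) min(pos) * 1e-6 else 1e-12
    se2[degenerate] <- floor_se2
    df[degenerate] <- n1 + n2 - 2
  }
  tstat <- diff / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[degenerate & diff == 0] <- 1
  tstat[degenerate & diff == 0] <- 0
  list(t = tstat, p = p, diff = diff)
}

#' Extract the differential gene signature between driver strata
#'
#' Computes a per-gene two-sample t statistic (equal-variance by default,
#' Welch behind \code{welch = TRUE}) between the driver-high and driver-low
#' sample groups, selects genes with two-sided p < \code{alpha}, sets each
#' selected gene's direction to the sign of (mean high - mean low), and
#' attaches the analytic FDR estimate \code{m * alpha / k}.
#'
#' Genes with zero variance in both groups never produce NaN: identical
#' group means give p = 1, a non-zero mean difference with zero variance is
#' assigned the floor-variance limit (effectively p ~ 0) so it still ranks.
#'
#' @param exprs filtered numeric genes x samples matrix.
#' @param groups list with \code{$high} and \code{$low} sample identifier
#'   vectors (from \code{\link{stratifyByDriver}}).
#' @param alpha per-gene two-sided risk level (default 0.001).
#' @param welch use the Welch unequal-variance t instead of the pooled t.
#' @return a \linkS4class{DEResult}.
#' @export
differentialSignature <- function(exprs, groups, alpha = 0.001, welch = FALSE) {
  stopifnot(is.matrix(exprs), all(c("high", "low") %in% names(groups)))
  high <- groups$high; low <- groups$low
  if (length(high) < 2L || length(low) < 2L)
    stop("both groups need at least 2 samples")
  missing <- setdiff(c(high, low), colnames(exprs))
  if (length(missing))
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  tt <- rowTTest(exprs, high, low, welch = welch)
  selected <- tt$p < alpha
  tab <- data.frame(gene = rownames(exprs), t = unname(tt$t), p = unname(tt$p),
                    direction = ifelse(tt$diff >= 0, 1L, -1L),
                    selected = unname(selected), row.names = NULL,
                    stringsAsFactors = FALSE)
  sig <- new("GeneSignature", genes = tab$gene[selected],
             direction = tab$direction[selected])
  fdr <- if (any(selected))
    estimateFdr(nrow(exprs), alpha, sum(selected)) else NA_real_
  new("DEResult", table = tab, testedCount = nrow(exprs),
      alpha = alpha, fdrEstimate = fdr, signature = sig)
}

#' Analytic false-discovery-rate estimate
#'
#' Under the per-gene risk level alpha, the expected number of false
#' positives among m tested genes is m * alpha; dividing by the observed
#' selected count k gives the FDR estimate m * alpha / k, capped at 1.
#'
#' @param testedCount number of genes tested (m).
#' @param alpha per-gene risk level.
#' @param selectedCount number of genes selected (k >= 1).
#' @return the FDR estimate in [0, 1].
#' @examples
#' estimateFdr(14455, 1e-04, 57)
#' @export
estimateFdr <- function(testedCount, alpha, selectedCount) {
  if (selectedCount < 1L)
    stop("FDR estimate undefined for an empty selection")
  min(1, testedCount * alpha / selectedCount)
}

# Risk-class assignment shared by the two scores. Boundaries are written as
# strict inequalities in the published thresholds; a value exactly at a
# boundary goes to the higher-risk class (conservative).
riskClass <- function(score, lowMax, highMin) {
  if (score < lowMax) "low" else if (score < highMin) "intermediate" else "high"
}

#' Two-gene risk score (TGS)
#'
#' The published two-gene linear score TGS = -0.32 * LMO2 - 0.29 * TNFRSF9,
#' with risk classes low (TGS < -1.60), intermediate (-1.60 <= TGS < -0.91)
#' and high (TGS >= -0.91). Boundary values fall in the higher-risk class.
#'
#' @param lmo2,tnfrsf9 expression values of LMO2 and TNFRSF9.
#' @return list with \code{$tgs} and \code{$class}.
#' @examples
#' computeTGS(3, 1)  # intermediate
#' @export
computeTGS <- function(lmo2, tnfrsf9) {
  stopifnot(is.finite(lmo2), is.finite(tnfrsf9))
  tgs <- -0.32 * lmo2 - 0.29 * tnfrsf9
  list(tgs = tgs, class = riskClass(tgs, lowMax = -1.60, highMin = -0.91))
}

#' TGS-IPI combined risk score
#'
#' Extends the two-gene score with the clinical International Prognostic
#' Index: TGS-IPI = 0.93 * TGS + 0.6 * IPI + 4, with classes low
#' (< 3.47), intermediate (3.47 <= score < 4.51) and high (>= 4.51).
#'
#' @param tgs a TGS value (see \code{\link{computeTGS}}).
#' @param ipi non-negative integer IPI score.
#' @return list with \code{$tgsIpi} and \code{$class}.
#' @export
computeTGSIPI <- function(tgs, ipi) {
  stopifnot(is.finite(tgs), ipi >= 0)
  v <- 0.93 * tgs + 0.6 * ipi + 4
  list(tgsIpi = v, class = riskClass(v, lowMax = 3.47, highMin = 4.51))
}
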