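# Shared fixtures, built in code.

# 4 genes x 3 samples toy for the low-expression filter: every sample has
# median 5.5; g2 is below it everywhere, g3 once, g4 twice.
toyFilterMatrix <- function() {
  matrix(c(10, 10, 10,
           1, 1, 1,
           10, 1, 10,
           1, 10, 1),
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
}

# Small series with explicit values for the pair statistic.
pairSeries <- function() {
  m <- cbind(si = c(5, 4, 3, 2, 1), sj = c(1, 2, 3, 4, 0))
  rownames(m) <- paste0("g", 1:5)
  ExpressionSeries("PAIR1", m)
}

fiveGeneSignature <- function() GeneSignature(paste0("g", 1:5))

# Independent brute-force oracles -----------------------------------------

# Upper binomial tail via the log-space cumulative (independent of the
# package's coefficient summation).
oracleBinomTail <- function(k, n) {
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

# Hypergeometric upper tail by explicit enumeration of the pmf.
oracleHyperTail <- function(c, listSize, T, N) {
  xs <- c:min(listSize, T)
  sum(choose(T, xs) * choose(N - T, listSize - xs)) / choose(N, listSize)
}

# Two-sided Fisher p on a 2x2 by enumerating all tables with the observed
# margins and summing those no more probable than the observed one.
oracleFisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Holm step-down by hand: sort, multiply by (m - r + 1), running max, cap.
oracleHolm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummax(p[ord] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Jaccard similarity between two cluster member sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best Jaccard match of each truth cluster among recovered clusters.
bestJaccard <- function(truth, recovered) {
  vapply(truth, function(tc) {
    if (length(recovered) == 0L) return(0)
    max(vapply(recovered, function(rc) jaccard(tc$members, rc$members),
               numeric(1)))
  }, numeric(1))
}
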