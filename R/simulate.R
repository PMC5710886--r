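# Synthetic-data generators with planted, recorded truth: a series
# collection for the conservation scan and annotation mining, a
# driver-stratified expression dataset for signature extraction, and a
# planted-biclique neighbor matrix for the graph module. All generators are
# deterministic under a fixed seed.

# Background vocabulary for synthetic annotations; deliberately free of the
# default planted terms.
.SIM_VOCAB <- c(
  "breast", "liver", "kidney", "lung", "colon", "skin", "brain", "muscle",
  "cell", "line", "treatment", "response", "control", "knockdown",
  "mouse", "human", "rat", "tissue", "blood", "culture", "biopsy",
  "infection", "diabetes", "cardiac", "neuronal", "hepatic", "renal",
  "differentiation", "proliferation", "stimulation", "timecourse",
  "comparison", "cohort", "patients", "healthy", "normal", "disease")

#' Simulate a series collection with planted coordinated pairs
#'
#' Background expression is i.i.d. Normal(0, noiseSd) — only orderings
#' matter to the rank-based scan, so the marginal shape is immaterial. In
#' each planted series one randomly chosen sample of a randomly chosen
#' sample pair receives +pairShift on every signature gene, creating a
#' coordinated expression change for that pair. Annotations draw words
#' from a background vocabulary; each planted term additionally appears
#' with probability \code{plantedTermRate} in planted series and
#' \code{termBackgroundRate} elsewhere.
#'
#' @param nSeries number of series in the collection.
#' @param samplesPerSeries samples per series.
#' @param nGenes genes per series (the signature is the first
#'   \code{signatureSize} of them).
#' @param signatureSize number of signature genes (default 57).
#' @param plantedFraction fraction of series carrying a planted pair.
#' @param pairShift expression-unit shift applied to signature genes in one
#'   member of the planted pair.
#' @param noiseSd background standard deviation.
#' @param plantedTerms annotation terms enriched in planted series.
#' @param termBackgroundRate probability of a planted term in a null series.
#' @param plantedTermRate probability of a planted term in a planted series.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with \code{$collection} (\linkS4class{SeriesCollection}),
#'   \code{$signature} (\linkS4class{GeneSignature}) and \code{$truth}
#'   (data.frame: seriesId, planted, sampleI, sampleJ — sampleI is the
#'   shifted sample).
#' @export
simulateSeriesCollection <- function(nSeries = 100, samplesPerSeries = 10,
                                     nGenes = 1000, signatureSize = 57,
                                     plantedFraction = 0.1, pairShift = 2,
                                     noiseSd = 1,
                                     plantedTerms = c("tumor", "carcinoma",
                                                      "immunity", "lymphocyte"),
                                     termBackgroundRate = 0.05,
                                     plantedTermRate = 0.9, seed = 1L) {
  if (signatureSize > nGenes) stop("signatureSize exceeds nGenes")
  stopifnot(plantedFraction >= 0, plantedFraction <= 1,
            termBackgroundRate >= 0, termBackgroundRate <= 1)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(nGenes))
  sig_genes <- genes[seq_len(signatureSize)]
  samples <- sprintf("S%03d", seq_len(samplesPerSeries))
  n_planted <- round(plantedFraction * nSeries)
  planted_idx <- sort(sample.int(nSeries, n_planted))
  series <- vector("list", nSeries)
  truth <- data.frame(seriesId = sprintf("SIM%04d", seq_len(nSeries)),
                      planted = seq_len(nSeries) %in% planted_idx,
                      sampleI = NA_character_, sampleJ = NA_character_,
                      stringsAsFactors = FALSE)
  for (s in seq_len(nSeries)) {
    vals <- matrix(stats::rnorm(nGenes * samplesPerSeries, 0, noiseSd),
                   nGenes, samplesPerSeries,
                   dimnames = list(genes, samples))
    if (truth$planted[s]) {
      pair <- sample(samples, 2L)
      vals[sig_genes, pair[1L]] <- vals[sig_genes, pair[1L]] + pairShift
      truth$sampleI[s] <- pair[1L]
      truth$sampleJ[s] <- pair[2L]
    }
    title <- paste(sample(.SIM_VOCAB, 4L), collapse = " ")
    words <- sample(.SIM_VOCAB, 8L, replace = TRUE)
    rate <- if (truth$planted[s]) plantedTermRate else termBackgroundRate
    extra <- plantedTerms[stats::runif(length(plantedTerms)) < rate]
    series[[s]] <- ExpressionSeries(truth$seriesId[s], vals, title = title,
                                    summary = paste(c(words, extra),
                                                    collapse = " "))
  }
  list(collection = SeriesCollection(series),
       signature = GeneSignature(sig_genes,
                                 rep(1L, signatureSize)),
       truth = truth)
}

#' Simulate a driver-stratified expression dataset
#'
#' Emulates a cohort in which a block of truth genes is under-expressed in
#' driver-high samples: background i.i.d. Normal(0, noiseSd), driver values
#' drawn bimodally on either side of the conventional high/low cuts
#' (uniform on [2, 3] for high samples, [0.2, 1] for low), and the truth
#' genes shifted down by \code{effect * noiseSd} in the high group.
#'
#' Truth genes additionally carry a baseline elevation of
#' \code{truthBaseline * noiseSd} in every sample: a gene that loses
#' expression in one stratum can only survive the low-expression filter if
#' it is expressed above the typical gene elsewhere.
#'
#' @param nGenes background gene count.
#' @param nHigh,nLow samples per driver stratum.
#' @param truthSize number of planted differential genes.
#' @param effect shift in units of noiseSd applied (downward) to truth
#'   genes in driver-high samples.
#' @param truthBaseline baseline elevation of truth genes in units of
#'   noiseSd (default 1).
#' @param noiseSd background standard deviation.
#' @param seed integer seed.
#' @return list with \code{$exprs} (matrix), \code{$driver} (named vector)
#'   and \code{$truthGenes} (character).
#' @export
simulateDriverDataset <- function(nGenes = 5000, nHigh = 10, nLow = 10,
                                  truthSize = 50, effect = 3,
                                  truthBaseline = 1, noiseSd = 1,
                                  seed = 1L) {
  stopifnot(truthSize <= nGenes)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(nGenes))
  samples <- c(sprintf("H%02d", seq_len(nHigh)),
               sprintf("L%02d", seq_len(nLow)))
  exprs <- matrix(stats::rnorm(nGenes * (nHigh + nLow), 0, noiseSd),
                  nGenes, nHigh + nLow, dimnames = list(genes, samples))
  truth <- sort(sample(genes, truthSize))
  high <- samples[seq_len(nHigh)]
  exprs[truth, ] <- exprs[truth, ] + truthBaseline * noiseSd
  exprs[truth, high] <- exprs[truth, high] - effect * noiseSd
  driver <- c(stats::runif(nHigh, 2, 3), stats::runif(nLow, 0.2, 1))
  names(driver) <- samples
  list(exprs = exprs, driver = driver, truthGenes = truth)
}

#' Simulate a neighbor matrix with planted bicliques
#'
#' Builds disjoint complete bicliques: each block allocates fresh signature
#' (query) genes and neighbor genes; within a block every query gene lists
#' all block neighbors and all other block query genes (so signature genes
#' are interconnected), and blocks share no genes. Spurious cross-block
#' query-neighbor relations are then added independently with probability
#' \code{crossEdgeNoise}.
#'
#' @param bicliqueSpec list of integer pairs c(nQueryGenes, nNeighbors),
#'   one per planted block.
#' @param crossEdgeNoise probability of a spurious cross-block relation.
#' @param seed integer seed.
#' @return list with \code{$nm} (\linkS4class{NeighborMatrix}) and
#'   \code{$truth} (list of planted clusters with \code{$members},
#'   \code{$lMembers}).
#' @export
simulateNeighborMatrix <- function(bicliqueSpec = list(c(3L, 10L), c(4L, 20L)),
                                   crossEdgeNoise = 0, seed = 1L) {
  stopifnot(length(bicliqueSpec) > 0, crossEdgeNoise >= 0,
            crossEdgeNoise <= 1)
  set.seed(seed)
  lists <- list()
  truth <- list()
  block_of <- character(0)
  l_off <- 0L; n_off <- 0L
  for (b in seq_along(bicliqueSpec)) {
    spec <- bicliqueSpec[[b]]
    k <- spec[1L]; q <- spec[2L]
    ls <- sprintf("L%03d", l_off + seq_len(k))
    ns <- if (q > 0L) sprintf("N%04d", n_off + seq_len(q)) else character(0)
    l_off <- l_off + k; n_off <- n_off + q
    for (g in ls) lists[[g]] <- sort(c(setdiff(ls, g), ns))
    truth[[b]] <- list(members = sort(c(ls, ns)), lMembers = ls)
    block_of[c(ls, ns)] <- as.character(b)
  }
  if (crossEdgeNoise > 0) {
    all_targets <- names(block_of)
    for (g in names(lists)) {
      foreign <- all_targets[block_of[all_targets] != block_of[g]]
      spurious <- foreign[stats::runif(length(foreign)) < crossEdgeNoise]
      lists[[g]] <- sort(unique(c(lists[[g]], spurious)))
    }
  }
  list(nm = buildNeighborMatrix(lists), truth = truth)
}
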