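# Co-expression neighborhood summarization: Boolean neighbor matrix,
# weak-neighbor filtering, biclique-constrained agglomerative clustering,
# pruning, and the inter-cluster-connectivity summary graph.

#' Build the Boolean neighbor matrix from per-query neighbor lists
#'
#' Rows are the queried signature genes (in input order), columns the
#' sorted union of all returned neighbors, and m(i, j) is TRUE iff
#' neighbor j was returned for query gene i. Duplicate entries within one
#' list are deduplicated with a warning; query genes with empty lists are
#' retained as all-FALSE rows. A gene may appear both as a query row and a
#' neighbor column.
#'
#' @param neighborLists named list: one character vector of neighbor gene
#'   identifiers per query (signature) gene.
#' @param support optional named numeric vector of per-neighbor support
#'   counts (number of series with observed co-expression); metadata only.
#' @return a \linkS4class{NeighborMatrix}.
#' @examples
#' buildNeighborMatrix(list(A = c("x", "y"), B = c("y", "z")))
#' @export
buildNeighborMatrix <- function(neighborLists, support = NULL) {
  stopifnot(is.list(neighborLists), !is.null(names(neighborLists)),
            length(neighborLists) > 0)
  deduped <- lapply(names(neighborLists), function(g) {
    v <- neighborLists[[g]]
    if (anyDuplicated(v)) {
      warning("duplicate neighbor entries for ", g, "; deduplicated")
      v <- unique(v)
    }
    v
  })
  names(deduped) <- names(neighborLists)
  lGenes <- names(deduped)
  neighbors <- sort(unique(unlist(deduped)))
  m <- matrix(FALSE, length(lGenes), length(neighbors),
              dimnames = list(lGenes, neighbors))
  for (g in lGenes) m[g, deduped[[g]]] <- TRUE
  sup <- rep(NA_real_, length(neighbors))
  names(sup) <- neighbors
  if (!is.null(support)) {
    common <- intersect(names(support), neighbors)
    sup[common] <- support[common]
  }
  new("NeighborMatrix", lGenes = lGenes, neighbors = neighbors,
      m = m, support = unname(sup))
}

#' Discard neighbors supported by too few query genes
#'
#' Removes neighbor columns returned for fewer than \code{minDegree} query
#' genes (default 3: a neighbor must be connected to at least three
#' signature genes to be retained). Rows are untouched; a zero-column
#' matrix is a valid, empty-downstream result, not an error.
#'
#' @param nm a \linkS4class{NeighborMatrix}.
#' @param minDegree minimum number of query genes per neighbor (>= 1).
#' @return the filtered \linkS4class{NeighborMatrix}.
#' @export
filterNeighbors <- function(nm, minDegree = 3L) {
  stopifnot(is(nm, "NeighborMatrix"), minDegree >= 1L)
  keep <- colSums(nm@m) >= minDegree
  new("NeighborMatrix", lGenes = nm@lGenes,
      neighbors = nm@neighbors[keep],
      m = nm@m[, keep, drop = FALSE], support = nm@support[keep])
}

# Symmetric gene-level adjacency over the union of query genes and
# neighbors: an edge is present between two genes if one is the neighbor
# of the other (this makes a query gene listed as another query gene's
# neighbor a symmetric edge). Returns the adjacency matrix and the
# signature-gene indicator.
geneAdjacency <- function(nm) {
  genes <- sort(unique(c(nm@lGenes, nm@neighbors)))
  A <- matrix(FALSE, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (length(nm@neighbors)) {
    for (g in nm@lGenes) {
      nb <- nm@neighbors[nm@m[g, ]]
      nb <- setdiff(nb, g)
      A[g, nb] <- TRUE
      A[nb, g] <- TRUE
    }
  }
  list(A = A, isL = stats::setNames(genes %in% nm@lGenes, genes))
}

# Full-connectivity test of a candidate cluster: all signature members
# pairwise connected, every non-signature member connected to every
# signature member. Vacuously true for singletons.
isFullyConnected <- function(members, adj) {
  lmem <- members[adj$isL[members]]
  nonl <- setdiff(members, lmem)
  if (length(lmem) >= 2L) {
    sub <- adj$A[lmem, lmem, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) return(FALSE)
  }
  if (length(nonl) && length(lmem)) {
    if (!all(adj$A[nonl, lmem, drop = FALSE])) return(FALSE)
  }
  TRUE
}

# TRUE if any edge links the two member sets.
clustersConnected <- function(a, b, adj) {
  any(adj$A[a, b, drop = FALSE])
}

#' Agglomerate genes into fully-connected clusters
#'
#' Hierarchical agglomeration starting from singleton gene nodes: pairs of
#' connected clusters are iteratively joined, a join being admitted iff the
#' merged cluster remains fully connected (all signature genes pairwise
#' interconnected, every neighbor connected to all signature genes of the
#' cluster). Candidate pairs are scanned in lexicographic order of their
#' smallest member identifier and merged clusters re-enter the pool, which
#' makes the procedure deterministic and invariant to input permutation.
#' Iteration stops when no admissible join remains; every gene ends up in
#' exactly one cluster (singletons allowed before pruning).
#'
#' @param nm a \linkS4class{NeighborMatrix} (typically after
#'   \code{\link{filterNeighbors}}).
#' @return list of clusters; each a list with sorted character vectors
#'   \code{$members} and \code{$lMembers}.
#' @export
agglomerate <- function(nm) {
  stopifnot(is(nm, "NeighborMatrix"))
  adj <- geneAdjacency(nm)
  genes <- rownames(adj$A)
  if (length(genes) == 0L) return(list())
  clusters <- lapply(genes, function(g) g)
  repeat {
    keys <- vapply(clusters, min, character(1))
    ord <- order(keys)
    clusters <- clusters[ord]
    keys <- keys[ord]
    merged <- FALSE
    nc <- length(clusters)
    for (a in seq_len(nc - 1L)) {
      for (b in seq((a + 1L), nc)) {
        if (!clustersConnected(clusters[[a]], clusters[[b]], adj)) next
        cand <- c(clusters[[a]], clusters[[b]])
        if (isFullyConnected(cand, adj)) {
          clusters[[a]] <- cand
          clusters[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  lapply(clusters, function(mem) {
    mem <- sort(mem)
    list(members = mem, lMembers = mem[adj$isL[mem]])
  })
}

#' Drop clusters below a minimum size
#'
#' @param clusters list of clusters from \code{\link{agglomerate}}.
#' @param minSize minimum member count to keep a cluster (default 3).
#' @return the retained clusters; the genes of the removed clusters are
#'   attached as attribute \code{"pruned"}.
#' @export
pruneClusters <- function(clusters, minSize = 3L) {
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  kept <- clusters[sizes >= minSize]
  attr(kept, "pruned") <-
    sort(unlist(lapply(clusters[sizes < minSize], `[[`, "members")))
  kept
}

#' Inter-cluster connectivity
#'
#' The proportion of realizable cross-cluster gene pairs that carry an
#' edge. Under the default \code{denominator = "admissible"} only pairs
#' with at least one signature gene count, since edges cannot exist
#' between two non-signature genes under the neighbor relation; the naive
#' all-pairs denominator is available as \code{"all"}. Zero admissible
#' pairs give connectivity 0 by convention.
#'
#' @param a,b disjoint clusters (lists with \code{$members},
#'   \code{$lMembers}).
#' @param nm the \linkS4class{NeighborMatrix} defining the gene graph.
#' @param denominator "admissible" (default) or "all".
#' @return connectivity in [0, 1].
#' @export
interclusterConnectivity <- function(a, b, nm,
                                     denominator = c("admissible", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(length(intersect(a$members, b$members)) == 0L)
  adj <- geneAdjacency(nm)
  edges <- sum(adj$A[a$members, b$members, drop = FALSE])
  npairs <- if (denominator == "all") {
    length(a$members) * length(b$members)
  } else {
    nA <- length(a$members); nAL <- length(a$lMembers)
    nB <- length(b$members); nBL <- length(b$lMembers)
    # pairs with at least one signature gene
    nA * nB - (nA - nAL) * (nB - nBL)
  }
  if (npairs == 0L) return(0)
  edges / npairs
}

#' Build the cluster summary graph
#'
#' Condenses the gene graph to one node per cluster, drawing an edge
#' between two clusters iff their inter-cluster connectivity reaches the
#' threshold (default 0.2). Node metadata records cluster sizes and
#' signature-gene counts; edges carry the connectivity value.
#'
#' @param clusters pairwise-disjoint clusters (from
#'   \code{\link{pruneClusters}}).
#' @param nm the \linkS4class{NeighborMatrix} defining the gene graph.
#' @param threshold minimum connectivity for an edge.
#' @param denominator passed to \code{\link{interclusterConnectivity}}.
#' @return a \linkS4class{SummaryGraph}.
#' @export
buildSummaryGraph <- function(clusters, nm, threshold = 0.2,
                              denominator = c("admissible", "all")) {
  denominator <- match.arg(denominator)
  n <- length(clusters)
  ids <- if (n) paste0("c", seq_len(n)) else character(0)
  nodes <- data.frame(clusterId = ids,
                      size = vapply(clusters, function(cl)
                        length(cl$members), integer(1)),
                      lCount = vapply(clusters, function(cl)
                        length(cl$lMembers), integer(1)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      connectivity = numeric(0), stringsAsFactors = FALSE)
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        conn <- interclusterConnectivity(clusters[[a]], clusters[[b]], nm,
                                         denominator = denominator)
        if (conn >= threshold)
          edges[nrow(edges) + 1L, ] <- list(ids[a], ids[b], conn)
      }
    }
  }
  named <- clusters
  names(named) <- ids
  new("SummaryGraph", clusters = named, nodes = nodes, edges = edges,
      threshold = threshold)
}

#' Audit clusters against the full-connectivity definition
#'
#' Re-checks every cluster against the source gene graph: all signature
#' members pairwise connected and every non-signature member connected to
#' all signature members.
#'
#' @param clusters list of clusters.
#' @param nm the \linkS4class{NeighborMatrix} they were built from.
#' @return logical vector, one entry per cluster.
#' @export
verifyClusters <- function(clusters, nm) {
  adj <- geneAdjacency(nm)
  vapply(clusters, function(cl) isFullyConnected(cl$members, adj),
         logical(1))
}
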