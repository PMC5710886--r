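test_that("the neighbor matrix is built from lists with deduplication", {
  nm <- buildNeighborMatrix(list(A = c("x", "y"), B = c("y", "z")))
  expect_identical(nm@lGenes, c("A", "B"))
  expect_identical(nm@neighbors, c("x", "y", "z"))
  expect_identical(unname(nm@m),
                   matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
                          2, byrow = TRUE))
  expect_warning(dup <- buildNeighborMatrix(list(A = c("x", "x", "y"))),
                 "duplicate")
  expect_identical(dup@neighbors, c("x", "y"))

  # empty lists are retained as all-FALSE rows
  nm2 <- buildNeighborMatrix(list(A = "x", B = character(0)))
  expect_identical(nm2@lGenes, c("A", "B"))
  expect_false(any(nm2@m["B", ]))
  lone <- buildNeighborMatrix(list(A = character(0)))
  expect_identical(dim(lone@m), c(1L, 0L))

  # a query gene may appear as another query's neighbor
  nm3 <- buildNeighborMatrix(list(A = c("B", "x"), B = "x"))
  expect_true("B" %in% nm3@neighbors)
  expect_true("B" %in% nm3@lGenes)
})

test_that("weak neighbors are filtered by query-degree", {
  lists <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "z"))
  nm <- buildNeighborMatrix(lists)
  f3 <- filterNeighbors(nm, minDegree = 3)
  expect_identical(f3@neighbors, "x")  # x has degree 3, y 2, z 1
  f1 <- filterNeighbors(nm, minDegree = 1)
  expect_identical(f1@neighbors, nm@neighbors)
  # all columns removed: empty downstream, not an error
  f9 <- filterNeighbors(nm, minDegree = 9)
  expect_length(f9@neighbors, 0L)
  expect_length(agglomerate(f9), length(nm@lGenes))  # query singletons remain
})

test_that("agglomeration admits only fully-connected merges", {
  # A and B mutually neighbors; x, y each neighbor of both:
  # one cluster {A, B, x, y}; x-y edge is not required
  nm <- buildNeighborMatrix(list(A = c("B", "x", "y"), B = c("A", "x", "y")))
  cl <- agglomerate(nm)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$members, c("A", "B", "x", "y"))
  expect_identical(cl[[1]]$lMembers, c("A", "B"))

  # A and B not connected to each other, x neighbor of both:
  # no 3-cluster (query genes must be interconnected); deterministic choice
  nm2 <- buildNeighborMatrix(list(A = "x", B = "x"))
  cl2 <- agglomerate(nm2)
  sizes <- sort(vapply(cl2, function(c) length(c$members), integer(1)))
  expect_identical(sizes, c(1L, 2L))
  expect_identical(cl2[[1]]$members, c("A", "x"))  # lexicographic join order
  expect_true(all(verifyClusters(cl2, nm2)))
})

test_that("planted disjoint bicliques are recovered exactly at zero noise", {
  sim <- simulateNeighborMatrix(list(c(3L, 10L), c(4L, 20L)),
                                crossEdgeNoise = 0, seed = 13)
  cl <- agglomerate(sim$nm)
  expect_length(cl, 2L)
  sizes <- sort(vapply(cl, function(c) length(c$members), integer(1)))
  expect_identical(sizes, c(13L, 24L))
  expect_equal(sort(bestJaccard(sim$truth, cl)), c(1, 1))
  expect_true(all(verifyClusters(cl, sim$nm)))
})

test_that("biclique recovery survives 5% cross-edge noise at Jaccard >= 0.9", {
  for (seed in c(7, 23, 59)) {
    sim <- simulateNeighborMatrix(list(c(3L, 12L), c(4L, 16L), c(3L, 8L)),
                                  crossEdgeNoise = 0.05, seed = seed)
    cl <- agglomerate(sim$nm)
    cl <- pruneClusters(cl, minSize = 3L)
    expect_true(all(bestJaccard(sim$truth, cl) >= 0.9))
    expect_true(all(verifyClusters(cl, sim$nm)))
  }
})

test_that("agglomeration partitions the gene set and ignores input order", {
  sim <- simulateNeighborMatrix(list(c(2L, 5L), c(3L, 6L)),
                                crossEdgeNoise = 0.1, seed = 3)
  cl <- agglomerate(sim$nm)
  genes <- sort(unique(c(sim$nm@lGenes, sim$nm@neighbors)))
  members <- sort(unlist(lapply(cl, `[[`, "members")))
  expect_identical(members, genes)  # no gene lost or duplicated

  # permute rows/columns via a reshuffled list order: same clustering
  lists <- lapply(sim$nm@lGenes, function(g)
    rev(sim$nm@neighbors[sim$nm@m[g, ]]))
  names(lists) <- sim$nm@lGenes
  set.seed(1)
  lists <- lists[sample(length(lists))]
  cl2 <- agglomerate(buildNeighborMatrix(lists))
  key <- function(cls) sort(vapply(cls, function(c)
    paste(c$members, collapse = "+"), character(1)))
  expect_identical(key(cl), key(cl2))
})

test_that("pruning drops small clusters and reports their genes", {
  mk <- function(members, l = character(0))
    list(members = members, lMembers = l)
  cls <- list(mk(letters[1:5]), mk(letters[6:7]), mk("z"), mk(letters[8:11]))
  kept <- pruneClusters(cls, minSize = 3)
  expect_length(kept, 2L)
  expect_identical(attr(kept, "pruned"), sort(c(letters[6:7], "z")))
  expect_length(pruneClusters(list(mk("a"), mk("b"))), 0L)
  expect_length(pruneClusters(cls, minSize = 1), 4L)
})

test_that("inter-cluster connectivity counts admissible pairs", {
  # a = {A(L), x}, b = {B(L), y}; admissible pairs (A,B), (A,y), (B,x);
  # one present edge (A lists y) -> 1/3
  nm <- buildNeighborMatrix(list(A = c("x", "y"), B = "y"))
  a <- list(members = c("A", "x"), lMembers = "A")
  b <- list(members = c("B", "y"), lMembers = "B")
  expect_equal(interclusterConnectivity(a, b, nm), 1 / 3)
  # naive denominator counts all four pairs
  expect_equal(interclusterConnectivity(a, b, nm, denominator = "all"), 1 / 4)

  # complete cross-bipartite relations
  full <- buildNeighborMatrix(list(A = c("x", "B", "y"), B = c("y", "A", "x")))
  expect_equal(interclusterConnectivity(a, b, full), 1)
  # no cross edges at all
  none <- buildNeighborMatrix(list(A = "x", B = "y"))
  expect_equal(interclusterConnectivity(a, b, none), 0)
  # no admissible pairs: convention 0
  expect_equal(interclusterConnectivity(list(members = "x", lMembers = character(0)),
                                        list(members = "y", lMembers = character(0)),
                                        nm), 0)
  expect_error(interclusterConnectivity(a, list(members = "x",
                                                lMembers = character(0)), nm))
})

test_that("the summary graph thresholds inter-cluster connectivity", {
  nm <- buildNeighborMatrix(list(A = c("x", "y"), B = "y"))
  a <- list(members = c("A", "x"), lMembers = "A")
  b <- list(members = c("B", "y"), lMembers = "B")
  g <- buildSummaryGraph(list(a, b), nm, threshold = 0.2)
  expect_equal(nrow(graphEdges(g)), 1L)
  expect_equal(graphEdges(g)$connectivity, 1 / 3)
  expect_equal(g@nodes$size, c(2L, 2L))
  expect_equal(g@nodes$lCount, c(1L, 1L))

  g0 <- buildSummaryGraph(list(a, b), nm, threshold = 0)
  expect_equal(nrow(graphEdges(g0)), 1L)  # any cross edge
  g1 <- buildSummaryGraph(list(a, b), nm, threshold = 1)
  expect_equal(nrow(graphEdges(g1)), 0L)
  empty <- buildSummaryGraph(list(), nm)
  expect_equal(nrow(empty@nodes), 0L)
})
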