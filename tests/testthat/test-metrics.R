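completeDigraph <- function(N) {
  A <- matrix(1L, N, N); diag(A) <- 0L
  DirectedNetwork(A)
}

chain012 <- function() {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- 1L; A[2, 3] <- 1L
  DirectedNetwork(A)
}

test_that("clustering coefficients match closed forms", {
  expect_equal(clusteringCoefficients(completeDigraph(4))$perNode,
               rep(1, 4), ignore_attr = TRUE)
  expect_equal(clusteringCoefficients(completeDigraph(4))$mean, 1)

  # directed 3-cycle: each node's two neighbours joined by 1 of 2 edges
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 3] <- A[3, 1] <- 1L
  expect_equal(clusteringCoefficients(DirectedNetwork(A))$perNode,
               rep(0.5, 3), ignore_attr = TRUE)

  empty <- DirectedNetwork(matrix(0L, 5, 5))
  expect_equal(clusteringCoefficients(empty)$perNode, rep(0, 5),
               ignore_attr = TRUE)
})

test_that("shortest paths respect direction with Inf for unreachable", {
  D <- shortestPaths(chain012())
  expect_equal(D[1, 3], 2)
  expect_equal(D[3, 1], Inf)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  Dc <- shortestPaths(completeDigraph(5))
  expect_true(all(Dc[row(Dc) != col(Dc)] == 1))
})

test_that("path length and efficiency match hand computations", {
  apl <- averagePathLength(chain012())
  expect_equal(apl$value, 4 / 3)             # pairs 1->2, 1->3, 2->3
  expect_equal(apl$reachableFraction, 0.5)
  expect_equal(globalEfficiency(chain012()), 5 / 12)

  expect_equal(averagePathLength(completeDigraph(4))$value, 1)
  expect_equal(averagePathLength(completeDigraph(4))$reachableFraction, 1)
  expect_equal(globalEfficiency(completeDigraph(4)), 1)

  empty <- DirectedNetwork(matrix(0L, 3, 3))
  expect_warning(res <- averagePathLength(empty), "undefined")
  expect_true(is.na(res$value))
  expect_equal(globalEfficiency(empty), 0)
})

test_that("degrees and causal flow are row/column sums with zero total", {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[1, 3] <- A[2, 3] <- 1L  # edges 1->2, 1->3, 2->3
  d <- degreesAndCausalFlow(DirectedNetwork(A))
  expect_equal(as.integer(d$out), c(2L, 1L, 0L))
  expect_equal(as.integer(d$in_), c(0L, 1L, 2L))
  expect_equal(as.integer(d$cf), c(2L, 0L, -2L))

  d5 <- degreesAndCausalFlow(completeDigraph(5))
  expect_true(all(d5$cf == 0L) && all(d5$out == 4L))
})

test_that("all metrics agree exactly with independent oracles", {
  set.seed(30)
  for (i in 1:200) {
    N <- sample(4:12, 1)
    net <- randomNet(N, runif(1, 0.1, 0.9), seed = 1000 + i)
    A <- adjacencyMatrix(net)
    D <- shortestPaths(net)
    expect_identical(D, fwDistances(A), ignore_attr = TRUE)
    expect_equal(clusteringCoefficients(net)$perNode, naiveClustering(A),
                 ignore_attr = TRUE)
    d <- degreesAndCausalFlow(net)
    expect_equal(sum(d$cf), 0L)
    expect_equal(sum(d$out), sum(A))
    expect_true(all(d$out <= N - 1) && all(d$in_ <= N - 1))
    offd <- D[row(D) != col(D)]
    E <- globalEfficiency(net)
    expect_equal(E, sum(1 / offd[is.finite(offd)]) / (N * (N - 1)))
    expect_gte(E, 0); expect_lte(E, 1)
    cc <- clusteringCoefficients(net)$perNode
    expect_true(all(cc >= 0 & cc <= 1))
    if (any(is.finite(offd)))
      expect_gte(averagePathLength(net)$value, 1)
  }
})

test_that("shortest paths agree with igraph on random digraphs", {
  set.seed(31)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    net <- randomNet(N, runif(1, 0.1, 0.9), seed = 2000 + i)
    gr <- igraph::graph_from_adjacency_matrix(adjacencyMatrix(net),
                                              mode = "directed")
    expect_equal(shortestPaths(net), igraph::distances(gr, mode = "out"),
                 ignore_attr = TRUE)
  }
})

test_that("relabeling nodes permutes metrics without changing means", {
  net <- randomNet(8, 0.4, seed = 40)
  perm <- sample(8)
  A <- adjacencyMatrix(net)
  netP <- DirectedNetwork(A[perm, perm])
  expect_equal(clusteringCoefficients(netP)$perNode,
               clusteringCoefficients(net)$perNode[perm],
               ignore_attr = TRUE)
  expect_equal(clusteringCoefficients(netP)$mean,
               clusteringCoefficients(net)$mean)
  expect_equal(globalEfficiency(netP), globalEfficiency(net))
  expect_equal(averagePathLength(netP)$value, averagePathLength(net)$value)
})

test_that("region means average per-node values within each region", {
  rm2 <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  v <- c(a1 = 1, a2 = 2, a3 = 3, b1 = 10, b2 = 20, b3 = 30)
  expect_equal(regionMeans(v, rm2), c(A = 2, B = 20))
  expect_equal(regionMeans(c(a1 = 5, b1 = 7), rm2), c(A = 5, B = 7))
  cv <- setNames(rep(4.2, 6), names(rm2))
  expect_equal(regionMeans(cv, rm2), c(A = 4.2, B = 4.2))
  expect_error(regionMeans(c(zz = 1), rm2), "zz")
})

test_that("inter-region flow tallies edges and totals the edge count", {
  A <- matrix(0L, 4, 4)
  A[1, 3] <- A[1, 4] <- A[3, 1] <- A[3, 4] <- 1L
  net <- DirectedNetwork(A, labels = c("a1", "a2", "b1", "b2"))
  rmap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  flow <- interregionFlow(net, rmap)
  expect_equal(flow["A", "B"], 2L, ignore_attr = TRUE)  # a1->b1, a1->b2
  expect_equal(flow["B", "A"], 1L, ignore_attr = TRUE)  # b1->a1
  expect_equal(flow["B", "B"], 1L, ignore_attr = TRUE)  # b1->b2
  expect_equal(sum(flow), sum(A))

  oneRegion <- c(a1 = "R", a2 = "R", b1 = "R", b2 = "R")
  f1 <- interregionFlow(net, oneRegion)
  expect_equal(as.integer(f1), sum(A))

  net2 <- randomNet(10, 0.5, seed = 50)
  rmap2 <- setNames(rep(c("X", "Y"), 5), channelLabels(net2))
  expect_equal(sum(interregionFlow(net2, rmap2)),
               sum(adjacencyMatrix(net2)))
})

test_that("the default region map follows the 10-10 prefix rules", {
  rm <- defaultRegionMap(channelLabels(montage1010()))
  expect_equal(unname(rm[c("Fp2", "AF3", "Fz", "FC3", "Cz", "CP4", "Pz",
                           "PO4", "Oz", "T7", "FT8", "TP7")]),
               c("pre-frontal", "frontal", "frontal", "fronto-central",
                 "central", "central-parietal", "parietal",
                 "parietal-occipital", "occipital", "temporal", "temporal",
                 "temporal"))
  expect_error(defaultRegionMap("XX9"), "XX9")
  expect_setequal(unique(rm), c(anteriorRegions(), posteriorRegions(),
                                "central", "central-parietal", "temporal"))
})
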