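## Directed-graph metrics: clustering coefficient, shortest paths, global
## efficiency, degrees and causal flow, plus region-level aggregations.

#' Directed clustering coefficients
#'
#' For node i, the neighbour set is the union of in- and out-neighbours
#' (excluding i), of size `k_i`; `M_i` counts the directed edges among the
#' neighbours (each direction separately), and
#' `C_i = M_i / (k_i (k_i - 1))`, with `C_i = 0` when `k_i < 2`.
#'
#' @param net a [DirectedNetwork-class].
#' @return List with `perNode` (named numeric vector) and `mean`.
#' @export
clusteringCoefficients <- function(net) {
  A <- adjacencyMatrix(net)
  N <- nrow(A)
  ci <- numeric(N)
  nb <- (A + t(A)) > 0
  for (i in seq_len(N)) {
    ns <- which(nb[i, ])
    k <- length(ns)
    if (k < 2) next
    ci[i] <- sum(A[ns, ns]) / (k * (k - 1))
  }
  names(ci) <- channelLabels(net)
  list(perNode = ci, mean = mean(ci))
}

#' Directed shortest-path hop counts
#'
#' Breadth-first hop counts respecting edge direction; `Inf` marks
#' unreachable ordered pairs, the diagonal is 0.
#'
#' @param net a [DirectedNetwork-class].
#' @return N x N numeric matrix of hop counts.
#' @export
shortestPaths <- function(net) {
  A <- adjacencyMatrix(net) > 0
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  diag(D) <- 0
  reach <- A
  off <- row(D) != col(D)
  newHits <- reach & off & !is.finite(D)
  D[newHits] <- 1
  k <- 1
  while (any(newHits) && k < N) {
    k <- k + 1
    reach <- (reach %*% A) > 0
    newHits <- reach & off & !is.finite(D)
    D[newHits] <- k
  }
  dimnames(D) <- list(channelLabels(net), channelLabels(net))
  D
}

#' Average directed shortest-path length over reachable pairs
#'
#' Mean hop count over the ordered reachable pairs (i != j), together with
#' the fraction of ordered pairs that are reachable. For a strongly
#' connected network the fraction is 1 and the value is the classical
#' average path length.
#'
#' @param net a [DirectedNetwork-class].
#' @return List with `value` (NA with a warning when no pair is reachable)
#'   and `reachableFraction`.
#' @export
averagePathLength <- function(net) {
  D <- shortestPaths(net)
  off <- D[row(D) != col(D)]
  reachable <- is.finite(off)
  if (!any(reachable)) {
    warning("no reachable ordered pair; average path length undefined")
    return(list(value = NA_real_, reachableFraction = 0))
  }
  list(value = mean(off[reachable]),
       reachableFraction = mean(reachable))
}

#' Global efficiency of a directed network
#'
#' `E = (1 / (N (N - 1))) * sum_{i != j} 1 / L_ij`, with `1 / Inf = 0`, so
#' disconnection is handled natively. Range `[0, 1]`.
#'
#' @param net a [DirectedNetwork-class].
#' @return A single number in `[0, 1]`.
#' @export
globalEfficiency <- function(net) {
  D <- shortestPaths(net)
  N <- nrow(D)
  if (N < 2) return(0)
  off <- D[row(D) != col(D)]
  sum(1 / off[is.finite(off) & off > 0]) / (N * (N - 1))
}

#' Degrees and causal flow
#'
#' Out-degree = adjacency row sums, in-degree = column sums, causal flow
#' `CF_i = k_out_i - k_in_i` (positive: net sender; negative: net
#' receiver). `sum(CF) = 0` always.
#'
#' @param net a [DirectedNetwork-class].
#' @return List of named integer vectors `out`, `in_` and `cf`.
#' @export
degreesAndCausalFlow <- function(net) {
  A <- adjacencyMatrix(net)
  out <- as.integer(rowSums(A))
  inn <- as.integer(colSums(A))
  labs <- channelLabels(net)
  list(out = stats::setNames(out, labs),
       in_ = stats::setNames(inn, labs),
       cf = stats::setNames(out - inn, labs))
}

#' Region means of a per-node metric
#'
#' @param perNodeValues named numeric vector (names = electrode labels).
#' @param regionMap named character vector label -> region; every value
#'   label must be mapped.
#' @return Named numeric vector: region -> mean of the member nodes.
#' @export
regionMeans <- function(perNodeValues, regionMap) {
  labs <- names(perNodeValues)
  missing <- setdiff(labs, names(regionMap))
  if (length(missing))
    stop("label(s) missing from region map: ",
         paste(missing, collapse = ", "))
  reg <- regionMap[labs]
  means <- tapply(as.numeric(perNodeValues), reg, mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Inter-region directed edge counts
#'
#' Entry `[A, B]` is the number of directed edges from nodes of region A to
#' nodes of region B; within-region edges sit on the diagonal. The grand
#' total equals the network's edge count.
#'
#' @param net a [DirectedNetwork-class].
#' @param regionMap named character vector label -> region.
#' @return Region x region integer matrix.
#' @export
interregionFlow <- function(net, regionMap) {
  labs <- channelLabels(net)
  missing <- setdiff(labs, names(regionMap))
  if (length(missing))
    stop("label(s) missing from region map: ",
         paste(missing, collapse = ", "))
  reg <- regionMap[labs]
  regions <- sort(unique(reg))
  A <- adjacencyMatrix(net)
  out <- matrix(0L, length(regions), length(regions),
                dimnames = list(regions, regions))
  for (a in regions) for (b in regions)
    out[a, b] <- sum(A[reg == a, reg == b, drop = FALSE])
  out
}

#' All per-network metrics in one record
#'
#' Convenience wrapper returning the scalar metrics and per-node vectors of
#' one network as a list (used by the pipeline to build tidy tables).
#'
#' @param net a [DirectedNetwork-class].
#' @return List with `cMean`, `lMean`, `eGlobal`, `reachableFraction`,
#'   `out`, `in_`, `cf`.
#' @export
networkMetrics <- function(net) {
  cc <- clusteringCoefficients(net)
  apl <- averagePathLength(net)
  deg <- degreesAndCausalFlow(net)
  list(cMean = cc$mean, lMean = apl$value,
       eGlobal = globalEfficiency(net),
       reachableFraction = apl$reachableFraction,
       perNodeC = cc$perNode, out = deg$out, in_ = deg$in_, cf = deg$cf)
}
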