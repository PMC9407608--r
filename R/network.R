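## Sparsity thresholding of connectivity matrices and global-cost-efficiency
## (GCE = E - S) optimal sparsity selection.

# round half away from zero (so 0.5 -> 1), documented threshold convention
roundHalfUp <- function(x) floor(x + 0.5)

#' Binarise a connectivity matrix by keeping the strongest fraction of edges
#'
#' Exactly `k = round(S * N * (N-1))` of the off-diagonal entries with the
#' largest strengths become directed edges (rounding half away from zero;
#' the diagonal is never eligible). Ties at the cutoff are broken by
#' ascending (row, column) index of the connectivity matrix, so the result
#' is deterministic and edge sets are nested across S.
#'
#' @param conn a [ConnectivityMatrix-class]; entry `[i, j]` is the flow
#'   j -> i and maps to the adjacency edge j -> i.
#' @param S sparsity in (0, 1): fraction of the N(N-1) possible edges kept.
#' @return A [DirectedNetwork-class] with `sparsityUsed = S`.
#' @examples
#' b <- RhythmBand("theta", 4, 8)
#' set.seed(1); v <- matrix(runif(16), 4); diag(v) <- 0
#' net <- binarizeTopFraction(ConnectivityMatrix(v / rowSums(v), b), 0.3)
#' sum(adjacencyMatrix(net))  # round(0.3 * 12) = 4 edges
#' @export
binarizeTopFraction <- function(conn, S) {
  if (S <= 0 || S >= 1) stop("S must lie strictly between 0 and 1")
  V <- connectivityValues(conn)
  N <- nrow(V)
  off <- which(row(V) != col(V))
  k <- roundHalfUp(S * N * (N - 1))
  if (k == 0 || k == N * (N - 1))
    warning(sprintf("sparsity %g rounds to %s network", S,
                    if (k == 0) "an empty" else "a complete"))
  ord <- off[order(-V[off], row(V)[off], col(V)[off])]
  adj <- matrix(0L, N, N)
  if (k > 0) {
    sel <- ord[seq_len(k)]
    # conn[i, j] is flow j -> i: edge source = column, sink = row
    adj[cbind(col(V)[sel], row(V)[sel])] <- 1L
  }
  DirectedNetwork(adj, labels = channelLabels(conn), sparsity = S)
}

#' Global cost efficiency of a connectivity matrix at a sparsity
#'
#' `GCE(S) = E(S) - S`, where E is the global efficiency of the network
#' binarised at sparsity S.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param S sparsity in (0, 1).
#' @return A single number in (-1, 1).
#' @export
globalCostEfficiency <- function(conn, S) {
  globalEfficiency(binarizeTopFraction(conn, S)) - S
}

#' Select the GCE-optimal sparsity
#'
#' @param gceBySparsity named numeric vector: names are sparsity values,
#'   entries the (mean) GCE at that sparsity.
#' @return The sparsity with maximal GCE; ties resolve to the smallest S.
#' @examples
#' selectOptimalSparsity(c("0.2" = 0.24, "0.3" = 0.27, "0.4" = 0.26))
#' @export
selectOptimalSparsity <- function(gceBySparsity) {
  if (!length(gceBySparsity)) stop("empty GCE map")
  s <- as.numeric(names(gceBySparsity))
  if (anyNA(s)) stop("names must be numeric sparsity values")
  ord <- order(s)
  s <- s[ord]
  g <- as.numeric(gceBySparsity)[ord]
  s[which.max(g)]  # which.max takes the first (smallest S) on ties
}

#' Traverse a sparsity grid over a collection of connectivity matrices
#'
#' Computes the mean GCE at each sparsity of the grid, grouped by stage
#' label -- the traversal report used to pick one fixed sparsity for a whole
#' dataset.
#'
#' @param conns list of [ConnectivityMatrix-class] objects.
#' @param grid numeric vector of sparsity values in (0, 1), strictly
#'   increasing (default `seq(0.2, 0.6, by = 0.05)`).
#' @param stages optional character vector, one stage label per matrix;
#'   default a single group `"all"`.
#' @return A data.frame with column `sparsity` and one column of mean GCE
#'   per stage group.
#' @seealso [selectOptimalSparsity()]
#' @export
sparsityTraversal <- function(conns, grid = seq(0.2, 0.6, by = 0.05),
                              stages = NULL) {
  if (!length(conns)) stop("empty connectivity collection")
  if (any(diff(grid) <= 0)) stop("sparsity grid must be strictly increasing")
  if (is.null(stages)) stages <- rep("all", length(conns))
  if (length(stages) != length(conns))
    stop("need one stage label per connectivity matrix")
  groups <- unique(stages)
  out <- data.frame(sparsity = grid)
  gce <- matrix(NA_real_, length(grid), length(conns))
  for (j in seq_along(conns))
    gce[, j] <- vapply(grid, function(S)
      globalCostEfficiency(conns[[j]], S), numeric(1))
  for (g in groups)
    out[[g]] <- rowMeans(gce[, stages == g, drop = FALSE])
  out
}
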