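#' Construct a Montage
#'
#' @param labels character vector of unique electrode labels.
#' @param positions numeric matrix (electrodes x 3); rows are normalised to
#'   unit length if within 1e-6 of it, otherwise validity fails.
#' @return A [Montage-class].
#' @examples
#' m <- montage1010()
#' nChannels(m)
#' @export
Montage <- function(labels, positions) {
  positions <- as.matrix(positions)
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  new("Montage", labels = as.character(labels), positions = positions)
}

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param labels channel labels; defaults to rownames of `data` or `ch1..chN`.
#' @param unit `"scalp_potential"` (default) or `"csd"`.
#' @return A [Recording-class].
#' @export
Recording <- function(data, fs, labels = NULL, unit = "scalp_potential") {
  data <- as.matrix(data)
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  }
  rownames(data) <- labels
  new("Recording", data = data, fs = fs, labels = as.character(labels),
      unit = unit)
}

#' Construct a RhythmBand
#'
#' @param name band name.
#' @param lowHz,highHz band edges in Hz.
#' @return A [RhythmBand-class].
#' @export
RhythmBand <- function(name, lowHz, highHz) {
  new("RhythmBand", name = name, lowHz = lowHz, highHz = highHz)
}

#' Canonical EEG rhythm bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-45 Hz. The
#' gamma band is capped at 45 Hz to stay clear of the 50 Hz mains notch.
#'
#' @return Named list of [RhythmBand-class] objects.
#' @export
defaultBands <- function() {
  list(delta = RhythmBand("delta", 0.5, 4),
       theta = RhythmBand("theta", 4, 8),
       alpha = RhythmBand("alpha", 8, 13),
       beta  = RhythmBand("beta", 13, 30),
       gamma = RhythmBand("gamma", 30, 45))
}

#' Construct a ground-truth directed coupling graph
#'
#' Couplings act at lag 1; every node additionally carries the same stable
#' self-dynamics `selfCoeffs` over `order` lags. The implied MVAR companion
#' matrix is checked for stability and construction fails, reporting the
#' spectral radius, if it is not stable.
#'
#' @param nNodes number of nodes.
#' @param edges two-column matrix (source, sink), 1-based, no self-pairs; or
#'   NULL for no couplings.
#' @param strengths numeric coupling per edge (recycled if length 1).
#' @param groups character group tag per edge (recycled; default `""`).
#' @param order model order p (default 2).
#' @param noiseSd innovation standard deviation (default 1).
#' @param selfCoeffs diagonal AR coefficients, length `order`; default
#'   `c(0.5, -0.2)` truncated/padded with zeros to `order`.
#' @return A [GroundTruthGraph-class].
#' @examples
#' g <- GroundTruthGraph(3, edges = rbind(c(1, 2), c(2, 3)), strengths = 0.4)
#' g
#' @export
GroundTruthGraph <- function(nNodes, edges = NULL, strengths = numeric(),
                             groups = "", order = 2L, noiseSd = 1,
                             selfCoeffs = NULL) {
  if (is.null(edges)) edges <- matrix(integer(), 0, 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  ne <- nrow(edges)
  strengths <- rep_len(as.numeric(strengths), ne)
  groups <- rep_len(as.character(groups), ne)
  if (is.null(selfCoeffs)) selfCoeffs <- c(0.5, -0.2)
  selfCoeffs <- c(selfCoeffs, numeric(order))[seq_len(order)]
  g <- new("GroundTruthGraph", nNodes = as.integer(nNodes), edges = edges,
           strengths = strengths, groups = groups, order = as.integer(order),
           noiseSd = noiseSd, selfCoeffs = selfCoeffs)
  rho <- spectralRadius(g)
  if (rho >= 1)
    stop(sprintf(
      "coupling graph is unstable: companion spectral radius %.4f >= 1", rho))
  g
}

#' Construct a session configuration
#'
#' @param montage a [Montage-class]; source nodes sit one under each
#'   electrode.
#' @param stages ordered stage labels (default `T0`..`T6`).
#' @param stageDurationS per-stage duration in seconds (default 600).
#' @param fs sampling rate in Hz (default 250).
#' @param stageModulation named list: stage -> named numeric vector scaling
#'   edge groups (e.g. `list(T4 = c(posterior_to_anterior = 0.5))`).
#' @param mixingSpread volume-conduction kernel width in radians (default
#'   0.15; 0 disables mixing).
#' @param seed integer master seed (default 1).
#' @return A [SessionConfig-class].
#' @export
SessionConfig <- function(montage, stages = paste0("T", 0:6),
                          stageDurationS = 600, fs = 250,
                          stageModulation = list(), mixingSpread = 0.15,
                          seed = 1L) {
  new("SessionConfig", stages = stages, stageDurationS = stageDurationS,
      fs = fs, montage = montage, stageModulation = stageModulation,
      mixingSpread = mixingSpread, seed = as.integer(seed))
}

#' Construct a ConnectivityMatrix
#'
#' @param values N x N nonnegative matrix, entry `[i, j]` = strength of flow
#'   j -> i.
#' @param band the [RhythmBand-class] the values belong to.
#' @param labels channel labels.
#' @param epochIndex source epoch index (default NA).
#' @return A [ConnectivityMatrix-class].
#' @export
ConnectivityMatrix <- function(values, band, labels = NULL,
                               epochIndex = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(values)))
  }
  dimnames(values) <- list(labels, labels)
  new("ConnectivityMatrix", values = values, band = band,
      epochIndex = as.integer(epochIndex), labels = as.character(labels))
}

#' Construct a DirectedNetwork
#'
#' @param adjacency N x N 0/1 matrix, `[i, j] = 1` iff edge i -> j.
#' @param labels node labels.
#' @param sparsity sparsity used to derive the network (default NA).
#' @return A [DirectedNetwork-class].
#' @export
DirectedNetwork <- function(adjacency, labels = NULL, sparsity = NA_real_) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- paste0("n", seq_len(nrow(adjacency)))
  }
  dimnames(adjacency) <- list(labels, labels)
  new("DirectedNetwork", adjacency = adjacency, labels = as.character(labels),
      sparsity = sparsity)
}
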