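#' @import methods
NULL

#' Electrode montage on the unit sphere
#'
#' Ordered electrode labels with unit-sphere positions. The montage fixes the
#' geometry used by the spherical-spline CSD transform (angular distances
#' between electrodes), by the synthetic volume-conduction kernel, and by the
#' electrode-to-region mapping.
#'
#' @slot labels character vector of unique electrode labels.
#' @slot positions numeric matrix (electrodes x 3) of unit vectors
#'   (x anterior, y left, z superior); rownames are the labels.
#'
#' @seealso [Montage()], [montage1010()], [readMontage()]
#' @export
setClass("Montage",
  representation(labels = "character", positions = "matrix"))

setValidity("Montage", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@positions))
    msg <- c(msg, "labels length must equal number of position rows")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "electrode labels must be unique")
  if (ncol(object@positions) != 3)
    msg <- c(msg, "positions must have 3 columns")
  nrm <- sqrt(rowSums(object@positions^2))
  if (any(abs(nrm - 1) > 1e-9))
    msg <- c(msg, "positions must be unit vectors (|norm - 1| <= 1e-9)")
  if (nrow(object@positions) > 1) {
    ct <- tcrossprod(object@positions)
    diag(ct) <- -Inf
    if (max(ct) >= 1 - 1e-12)
      msg <- c(msg, "electrode positions must be pairwise distinct")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled multichannel recording
#'
#' A channels-by-samples matrix with its sampling rate, channel labels and a
#' unit tag distinguishing raw scalp potentials from current-source-density
#' estimates. All signal-processing stages consume and produce `Recording`s.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot labels ordered channel labels (length = number of rows of `data`).
#' @slot unit either `"scalp_potential"` or `"csd"`.
#'
#' @seealso [Recording()], [computeCSD()], [conditionRecording()]
#' @export
setClass("Recording",
  representation(data = "matrix", fs = "numeric", labels = "character",
                 unit = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@data))
    msg <- c(msg, "labels length must equal channel count")
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!object@unit %in% c("scalp_potential", "csd"))
    msg <- c(msg, "unit must be 'scalp_potential' or 'csd'")
  if (length(object@data) && !all(is.finite(object@data)))
    msg <- c(msg, "data must contain no NaN/Inf")
  if (length(msg)) msg else TRUE
})

#' Sliding-window epochs of a recording
#'
#' @slot epochs list of channels x window-samples matrices, identical shapes.
#' @slot windowS window length in seconds.
#' @slot stepS step between window onsets in seconds.
#' @slot fs parent sampling rate in Hz.
#' @slot labels parent channel labels.
#'
#' @seealso [slidingWindows()]
#' @export
setClass("EpochSet",
  representation(epochs = "list", windowS = "numeric", stepS = "numeric",
                 fs = "numeric", labels = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (length(object@epochs)) {
    dims <- vapply(object@epochs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all epochs must have identical shape")
    if (dims[1, 1] != length(object@labels))
      msg <- c(msg, "epoch channel count must match labels")
  }
  if (object@stepS <= 0) msg <- c(msg, "stepS must be positive")
  if (length(msg)) msg else TRUE
})

#' Rhythm (frequency) band
#'
#' @slot name band name, e.g. `"theta"`.
#' @slot lowHz,highHz band edges in Hz, `0 < lowHz < highHz`.
#'
#' @seealso [RhythmBand()], [defaultBands()]
#' @export
setClass("RhythmBand",
  representation(name = "character", lowHz = "numeric", highHz = "numeric"))

setValidity("RhythmBand", function(object) {
  if (object@lowHz <= 0 || object@highHz <= object@lowHz)
    "band edges must satisfy 0 < lowHz < highHz" else TRUE
})

#' Ground-truth directed coupling graph for synthetic data
#'
#' Defines the multivariate autoregressive (MVAR) process the synthetic
#' generator realises: a set of directed couplings (source -> sink) acting at
#' lag 1, per-node self-dynamics acting over `order` lags, and innovation
#' noise. The implied companion matrix must be stable (spectral radius < 1);
#' the constructor enforces this.
#'
#' @slot nNodes number of nodes (channels at source level).
#' @slot edges integer matrix with columns `source`, `sink` (1-based), no
#'   self-pairs.
#' @slot strengths coupling coefficient per edge.
#' @slot groups character tag per edge (e.g. `"posterior_to_anterior"`), used
#'   by stage modulation; `""` for untagged edges.
#' @slot order model order p (lags of the self-dynamics).
#' @slot noiseSd innovation standard deviation (i.i.d. Gaussian, diagonal).
#' @slot selfCoeffs numeric vector of length `order`: diagonal AR coefficients
#'   shared by all nodes.
#'
#' @seealso [GroundTruthGraph()], [simulateMVAR()], [simulateSession()]
#' @export
setClass("GroundTruthGraph",
  representation(nNodes = "integer", edges = "matrix", strengths = "numeric",
                 groups = "character", order = "integer", noiseSd = "numeric",
                 selfCoeffs = "numeric"))

setValidity("GroundTruthGraph", function(object) {
  msg <- character()
  if (object@nNodes < 1) msg <- c(msg, "nNodes must be positive")
  if (nrow(object@edges)) {
    if (ncol(object@edges) != 2) msg <- c(msg, "edges must have 2 columns")
    else {
      if (any(object@edges < 1) || any(object@edges > object@nNodes))
        msg <- c(msg, "edge indices must lie in [1, nNodes]")
      if (any(object@edges[, 1] == object@edges[, 2]))
        msg <- c(msg, "self-edges are not allowed")
    }
    if (length(object@strengths) != nrow(object@edges))
      msg <- c(msg, "one strength per edge required")
    if (length(object@groups) != nrow(object@edges))
      msg <- c(msg, "one group tag per edge required")
  }
  if (object@order < 1) msg <- c(msg, "order must be >= 1")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (length(object@selfCoeffs) != object@order)
    msg <- c(msg, "selfCoeffs must have length = order")
  if (length(msg)) msg else TRUE
})

#' Synthetic driving-session configuration
#'
#' Describes a stage-structured recording session: stage labels and duration,
#' sampling rate, montage (source nodes sit under the electrodes), per-stage
#' multiplicative scaling of named edge groups (emulating e.g. weakened
#' posterior-to-anterior coupling under fatigue), and the width of the
#' volume-conduction mixing kernel.
#'
#' @slot stages ordered stage labels (default `T0`..`T6`).
#' @slot stageDurationS duration of each stage in seconds.
#' @slot fs sampling rate in Hz.
#' @slot montage a [Montage-class].
#' @slot stageModulation named list: stage label -> named numeric vector of
#'   scale factors per edge group. Unlisted stages/groups scale by 1.
#' @slot mixingSpread volume-conduction kernel width in radians (0 disables
#'   mixing).
#' @slot seed integer master seed.
#'
#' @seealso [SessionConfig()], [simulateSession()]
#' @export
setClass("SessionConfig",
  representation(stages = "character", stageDurationS = "numeric",
                 fs = "numeric", montage = "Montage",
                 stageModulation = "list", mixingSpread = "numeric",
                 seed = "integer"))

setValidity("SessionConfig", function(object) {
  msg <- character()
  if (!length(object@stages)) msg <- c(msg, "at least one stage required")
  n <- object@stageDurationS * object@fs
  if (abs(n - round(n)) > 1e-8)
    msg <- c(msg, "stageDurationS * fs must be an integer sample count")
  scl <- unlist(object@stageModulation, use.names = FALSE)
  if (length(scl) && any(scl < 0))
    msg <- c(msg, "all stage modulation scalings must be >= 0")
  bad <- setdiff(names(object@stageModulation), object@stages)
  if (length(bad))
    msg <- c(msg, paste("modulation refers to unknown stage(s):",
                        paste(bad, collapse = ", ")))
  if (object@mixingSpread < 0) msg <- c(msg, "mixingSpread must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Directed connectivity matrix for one epoch and band
#'
#' N x N nonnegative matrix of band-aggregated DTF values; entry `[i, j]` is
#' the directed strength of the flow from channel j into channel i, so each
#' row sums to 1 under the inflow-normalised DTF.
#'
#' @slot values numeric N x N matrix in `[0, 1]`.
#' @slot band the [RhythmBand-class] the values were aggregated over.
#' @slot epochIndex index of the source epoch (NA when not epoch-bound).
#' @slot labels channel labels.
#'
#' @seealso [bandDTF()], [binarizeTopFraction()]
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", band = "RhythmBand",
                 epochIndex = "integer", labels = "character"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != ncol(object@values))
    msg <- c(msg, "values must be square")
  if (length(object@labels) != nrow(object@values))
    msg <- c(msg, "labels length must match matrix dimension")
  if (length(object@values) &&
      (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-9))
    msg <- c(msg, "values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Binary directed network
#'
#' Adjacency convention: `adjacency[i, j] = 1` iff there is a directed edge
#' i -> j. Derived from a [ConnectivityMatrix-class] by keeping the strongest
#' fraction `sparsity` of the N(N-1) off-diagonal entries.
#'
#' @slot adjacency integer N x N 0/1 matrix with zero diagonal.
#' @slot labels node labels.
#' @slot sparsity the sparsity S the network was thresholded at (NA when
#'   constructed directly).
#'
#' @seealso [binarizeTopFraction()], [clusteringCoefficients()],
#'   [globalEfficiency()]
#' @export
setClass("DirectedNetwork",
  representation(adjacency = "matrix", labels = "character",
                 sparsity = "numeric"))

setValidity("DirectedNetwork", function(object) {
  msg <- character()
  a <- object@adjacency
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (length(object@labels) != nrow(a))
    msg <- c(msg, "labels length must match adjacency dimension")
  if (length(a)) {
    if (!all(a %in% c(0L, 1L))) msg <- c(msg, "adjacency must be binary")
    if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted multivariate autoregressive model
#'
#' @slot order model order p.
#' @slot coeffs list of p coefficient matrices (N x N); `coeffs[[r]][i, j]` is
#'   the effect of channel j at lag r on channel i.
#' @slot noiseCov residual (innovation) covariance, N x N symmetric.
#' @slot fs sampling rate of the fitted data in Hz.
#' @slot labels channel labels.
#'
#' @seealso [fitMVAR()], [transferMatrix()], [dtf()]
#' @export
setClass("MVARModel",
  representation(order = "integer", coeffs = "list", noiseCov = "matrix",
                 fs = "numeric", labels = "character"))

setValidity("MVARModel", function(object) {
  msg <- character()
  if (length(object@coeffs) != object@order)
    msg <- c(msg, "need one coefficient matrix per lag")
  if (max(abs(object@noiseCov - t(object@noiseCov))) > 1e-10)
    msg <- c(msg, "noiseCov must be symmetric within 1e-10")
  if (length(msg)) msg else TRUE
})
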