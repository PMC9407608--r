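## Synthetic ground-truth MVAR sessions: the generator realises the model the
## analysis stages fit, so every downstream operation can be checked against a
## known directed coupling structure.

#' Companion-matrix spectral radius of a coupling graph or MVAR model
#'
#' The process is stationary iff the spectral radius of the p*N x p*N
#' companion matrix is < 1.
#'
#' @param x a [GroundTruthGraph-class] or [MVARModel-class].
#' @return The spectral radius (largest eigenvalue modulus).
#' @export
spectralRadius <- function(x) {
  A <- if (is(x, "GroundTruthGraph")) coefMatricesFromGraph(x)
       else coefMatrices(x)
  companionRadius(A)
}

companionRadius <- function(A) {
  p <- length(A)
  n <- nrow(A[[1]])
  comp <- matrix(0, n * p, n * p)
  for (r in seq_len(p)) comp[seq_len(n), (r - 1) * n + seq_len(n)] <- A[[r]]
  if (p > 1)
    comp[n + seq_len(n * (p - 1)), seq_len(n * (p - 1))] <-
      diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# lag coefficient matrices implied by a coupling graph: shared diagonal
# self-dynamics at all lags, couplings (source -> sink) at lag 1
coefMatricesFromGraph <- function(graph, scales = NULL) {
  n <- graph@nNodes
  A <- lapply(graph@selfCoeffs, function(a) diag(a, n))
  st <- graph@strengths
  if (!is.null(scales) && length(scales) && nrow(graph@edges)) {
    m <- match(graph@groups, names(scales))
    idx <- !is.na(m)
    st[idx] <- st[idx] * scales[m[idx]]
  }
  if (nrow(graph@edges))
    A[[1]][cbind(graph@edges[, 2], graph@edges[, 1])] <-
      A[[1]][cbind(graph@edges[, 2], graph@edges[, 1])] + st
  A
}

#' Simulate a stationary MVAR process from a coupling graph
#'
#' Realises `X(n) = sum_r A_r X(n-r) + W(n)` with i.i.d. Gaussian innovations
#' of standard deviation `noiseSd` (diagonal covariance). A burn-in of
#' `max(10 * order, 200)` samples is generated and discarded so the returned
#' series is stationary.
#'
#' @param graph a [GroundTruthGraph-class].
#' @param nSamples number of samples to return (> 10 * order).
#' @param fs sampling rate tag for the output in Hz.
#' @param seed integer seed; identical seeds give identical output.
#' @param labels optional channel labels.
#' @return A [Recording-class] with `nNodes` channels.
#' @examples
#' g <- GroundTruthGraph(2, edges = rbind(c(1, 2)), strengths = 0.4)
#' simulateMVAR(g, 1000, fs = 250, seed = 1)
#' @export
simulateMVAR <- function(graph, nSamples, fs, seed, labels = NULL) {
  rho <- spectralRadius(graph)
  if (rho >= 1)
    stop(sprintf("unstable coupling graph: spectral radius %.4f >= 1", rho))
  if (nSamples <= 10 * graph@order)
    stop("nSamples must exceed 10 * model order")
  A <- coefMatricesFromGraph(graph)
  simulateFromCoeffs(A, graph@noiseSd, nSamples, fs, seed, labels)
}

simulateFromCoeffs <- function(A, noiseSd, nSamples, fs, seed, labels = NULL) {
  p <- length(A)
  n <- nrow(A[[1]])
  burn <- max(10L * p, 200L)
  total <- nSamples + burn
  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(n * total, sd = noiseSd), n, total)
  X <- matrix(0, n, total)
  X[, seq_len(p)] <- W[, seq_len(p)]
  for (t in (p + 1):total) {
    x <- W[, t]
    for (r in seq_len(p)) x <- x + A[[r]] %*% X[, t - r]
    X[, t] <- x
  }
  Recording(X[, burn + seq_len(nSamples), drop = FALSE], fs = fs,
            labels = labels)
}

#' Volume-conduction mixing of source signals to scalp channels
#'
#' Emulates the spatial smearing of scalp EEG: each output channel is a
#' normalised Gaussian-in-angle mixture of all source channels,
#' `w_ik = exp(-theta_ik^2 / (2 spread^2))` row-normalised to sum to 1, where
#' `theta_ik` is the great-circle angle between electrodes i and k. This is a
#' smearing surrogate, not a physical head model. `spread = 0` returns the
#' input unchanged (identity kernel).
#'
#' @param rec a [Recording-class] whose channels match the montage.
#' @param montage a [Montage-class].
#' @param spread kernel width in radians, >= 0.
#' @return A mixed [Recording-class] of the same shape.
#' @export
applyVolumeConduction <- function(rec, montage, spread) {
  if (nChannels(rec) != nChannels(montage))
    stop(sprintf("recording has %d channels but montage has %d electrodes",
                 nChannels(rec), nChannels(montage)))
  if (spread < 0) stop("spread must be >= 0")
  if (spread == 0) return(rec)
  W <- volumeConductionKernel(montage, spread)
  Recording(W %*% signalData(rec), fs = samplingRate(rec),
            labels = channelLabels(rec), unit = unitTag(rec))
}

#' @rdname applyVolumeConduction
#' @export
volumeConductionKernel <- function(montage, spread) {
  th <- angularDistances(montage)
  W <- exp(-th^2 / (2 * spread^2))
  W / rowSums(W)
}

subSeed <- function(seed, k) {
  as.integer(((as.double(seed) %% 2147483647) * 1009 + k * 9973) %%
               2147483647)
}

#' Simulate a stage-structured recording session
#'
#' Generates one recording per stage from `baseGraph`, with the coupling
#' strengths of named edge groups scaled per stage by
#' `stageModulation(config)` (e.g. halving `"posterior_to_anterior"` edges in
#' stage T4 to emulate fatigue). Each stage draws an independent noise stream
#' sub-seeded from `(seed, stage index)`, and is mixed to the scalp by the
#' volume-conduction kernel when `mixingSpread > 0`.
#'
#' @param config a [SessionConfig-class].
#' @param baseGraph a [GroundTruthGraph-class] with `nNodes` equal to the
#'   montage size.
#' @return Named list: stage label -> [Recording-class].
#' @seealso [defaultSessionGraph()], [runPipeline()]
#' @export
simulateSession <- function(config, baseGraph) {
  if (baseGraph@nNodes != nChannels(config@montage))
    stop("baseGraph node count must equal montage size")
  nSamples <- round(config@stageDurationS * config@fs)
  labs <- channelLabels(config@montage)
  out <- vector("list", length(config@stages))
  names(out) <- config@stages
  for (k in seq_along(config@stages)) {
    stage <- config@stages[k]
    scales <- config@stageModulation[[stage]]
    A <- coefMatricesFromGraph(baseGraph, scales)
    rho <- companionRadius(A)
    if (rho >= 1)
      stop(sprintf("stage %s: scaled graph unstable (spectral radius %.4f)",
                   stage, rho))
    rec <- simulateFromCoeffs(A, baseGraph@noiseSd, nSamples, config@fs,
                              subSeed(config@seed, k), labels = labs)
    if (config@mixingSpread > 0)
      rec <- applyVolumeConduction(rec, config@montage, config@mixingSpread)
    out[[k]] <- rec
  }
  out
}

#' Default ground-truth session graph over a montage
#'
#' Builds a coupling graph suited to directional fatigue benchmarks: a
#' fronto-parietal pathway in which each of a handful of anterior hub
#' electrodes receives couplings from many posterior sources (group
#' `"posterior_to_anterior"`), a set of anterior-to-posterior return
#' couplings (group `"anterior_to_posterior"`), and seeded random background
#' couplings (untagged). Concentrating the modulated inflow on hub sinks is
#' what makes a stage-wise scaling of the posterior-to-anterior group
#' visible in binarised node degrees: a single weak inflow per sink would
#' drown in the sparsity threshold's noise floor. The hub coupling strength
#' is sized so that its full-strength band DTF clears the top-30% cutoff
#' while the halved version falls near it.
#'
#' @param montage a [Montage-class].
#' @param sinkLabels anterior hub electrodes (default Fp1, Fpz, Fp2, F1,
#'   F3, Fz -- the fronto-polar/frontal set fatigue studies implicate).
#' @param sourcesPerSink posterior sources coupled into each sink
#'   (default 10).
#' @param hubCoupling posterior-to-anterior coupling strength
#'   (default 0.25).
#' @param nAnt anterior-to-posterior return couplings (default 12).
#' @param nBackground random background couplings (default 20).
#' @param coupling strength of return and background couplings
#'   (default 0.4).
#' @param order model order (default 2).
#' @param seed seed for the background edges (default 1).
#' @return A [GroundTruthGraph-class].
#' @export
defaultSessionGraph <- function(montage,
                                sinkLabels = c("Fp1", "Fpz", "Fp2", "F1",
                                               "F3", "Fz"),
                                sourcesPerSink = 10L, hubCoupling = 0.25,
                                nAnt = 12L, nBackground = 20L,
                                coupling = 0.4, order = 2L, seed = 1L) {
  labs <- channelLabels(montage)
  reg <- defaultRegionMap(labs)
  ant <- which(reg %in% anteriorRegions())
  post <- which(reg %in% posteriorRegions())
  sinks <- match(sinkLabels, labs)
  if (anyNA(sinks))
    stop("sink label(s) absent from montage: ",
         paste(sinkLabels[is.na(sinks)], collapse = ", "))
  hub <- do.call(rbind, lapply(seq_along(sinks), function(j)
    cbind(post[((j - 1) * 3 + seq_len(sourcesPerSink) - 1) %% length(post)
               + 1], sinks[j])))
  ret <- cbind(ant[(seq_len(nAnt) - 1) %% length(ant) + 1],
               rev(post)[(seq_len(nAnt) - 1) %% length(post) + 1])
  edges <- rbind(hub, ret)
  groups <- c(rep("posterior_to_anterior", nrow(hub)),
              rep("anterior_to_posterior", nrow(ret)))
  strengths <- c(rep(hubCoupling, nrow(hub)), rep(coupling, nrow(ret)))
  if (nBackground > 0) {
    set.seed(as.integer(seed))
    key <- paste(edges[, 1], edges[, 2])
    got <- 0L
    while (got < nBackground) {
      s <- sample.int(length(labs), 1)
      d <- sample.int(length(labs), 1)
      if (s == d || paste(s, d) %in% key) next
      edges <- rbind(edges, c(s, d))
      key <- c(key, paste(s, d))
      groups <- c(groups, "")
      strengths <- c(strengths, coupling)
      got <- got + 1L
    }
  }
  GroundTruthGraph(length(labs), edges = edges, strengths = strengths,
                   groups = groups, order = order)
}
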