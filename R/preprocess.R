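## Signal conditioning: re-referencing, zero-phase filtering, polyphase
## downsampling, rhythm-band decomposition and sliding-window epoching.
## All filters are applied forward-backward (signal::filtfilt), so the
## effective response is zero-phase and the magnitude response is squared.

#' Re-reference a recording to the mean of reference channels
#'
#' Subtracts the average of the named reference channels (e.g. the two
#' mastoids) from every channel, then drops the reference channels.
#'
#' @param rec a [Recording-class].
#' @param referenceLabels labels of the reference channels, all present in
#'   `rec`.
#' @return A [Recording-class] with `nChannels(rec) - length(referenceLabels)`
#'   channels.
#' @export
rereference <- function(rec, referenceLabels) {
  labs <- channelLabels(rec)
  missing <- setdiff(referenceLabels, labs)
  if (length(missing))
    stop("reference label(s) not present in recording: ",
         paste(missing, collapse = ", "))
  refIdx <- match(referenceLabels, labs)
  X <- signalData(rec)
  refMean <- colMeans(X[refIdx, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(X)), refIdx)
  out <- X[keep, , drop = FALSE] -
    matrix(refMean, length(keep), ncol(X), byrow = TRUE)
  Recording(out, fs = samplingRate(rec), labels = labs[keep],
            unit = unitTag(rec))
}

# second-order IIR notch (RBJ biquad) at f0 with quality factor Q
notchCoefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# forward-backward filtering with odd-reflection edge padding (the
# MATLAB-style filtfilt convention), which suppresses start/end transients
zeroPhase <- function(flt, x, padLen = 0) {
  t(apply(x, 1, function(ch) {
    n <- length(ch)
    p <- min(n - 1, padLen)
    if (p > 0) {
      ch2 <- c(2 * ch[1] - ch[(p + 1):2], ch, 2 * ch[n] - ch[(n - 1):(n - p)])
      out <- signal::filtfilt(flt, ch2)
      out[(p + 1):(p + n)]
    } else {
      signal::filtfilt(flt, ch)
    }
  }))
}

#' Condition a recording: high-pass, notch, downsample
#'
#' Zero-phase 4th-order Butterworth high-pass, zero-phase 2nd-order IIR
#' notch (quality factor 30), then anti-aliased polyphase resampling to
#' `targetFs`. The resampled length is `ceiling(n * p / q)` for the reduced
#' rational rate ratio `p/q`. Calling it again on its own output (already
#' band-limited, already at `targetFs`) reproduces the input up to numerical
#' tolerance; resampling is skipped when `targetFs == samplingRate(rec)`.
#'
#' @param rec a [Recording-class].
#' @param highpassHz high-pass cutoff in Hz (default 0.5); `NULL` skips.
#' @param notchHz mains notch frequency in Hz (default 50); `NULL` skips.
#' @param targetFs output sampling rate, `<= samplingRate(rec)` (default 250).
#' @param notchQ notch quality factor (default 30).
#' @return The conditioned [Recording-class] at `targetFs`.
#' @export
conditionRecording <- function(rec, highpassHz = 0.5, notchHz = 50,
                               targetFs = 250, notchQ = 30) {
  fs <- samplingRate(rec)
  if (targetFs > fs)
    stop(sprintf("targetFs (%g) must not exceed the sampling rate (%g)",
                 targetFs, fs))
  if (!is.null(notchHz) && notchHz >= targetFs / 2)
    stop("notch frequency must be below the target Nyquist rate")
  X <- signalData(rec)
  if (!is.null(highpassHz)) {
    X <- X - rowMeans(X)   # remove DC first so the slow filter sees no step
    hp <- signal::butter(4, highpassHz / (fs / 2), type = "high")
    X <- zeroPhase(hp, X)  # no padding: the 0.5 Hz filter has long memory
                           # and would drag reflected edge content inward
  }
  if (!is.null(notchHz)) {
    nc <- notchCoefficients(notchHz, fs, notchQ)
    flt <- signal::Arma(b = nc$b, a = nc$a)
    X <- zeroPhase(flt, X, padLen = round(fs))
  }
  if (targetFs < fs) {
    frac <- ratioReduce(targetFs, fs)
    X <- t(apply(X, 1, function(ch) signal::resample(ch, frac[1], frac[2])))
  }
  Recording(X, fs = targetFs, labels = channelLabels(rec),
            unit = unitTag(rec))
}

ratioReduce <- function(p, q) {
  # reduce p/q to lowest integer terms (rates may be non-integer)
  scale <- 1
  while (abs(p * scale - round(p * scale)) > 1e-9 ||
         abs(q * scale - round(q * scale)) > 1e-9) scale <- scale * 10
  p <- round(p * scale); q <- round(q * scale)
  g <- gcdInt(p, q)
  c(p / g, q / g)
}

gcdInt <- function(a, b) if (b == 0) a else gcdInt(b, a %% b)

#' Decompose a recording into rhythm bands
#'
#' Zero-phase 4th-order Butterworth band-pass per band.
#'
#' @param rec a [Recording-class].
#' @param bands list of [RhythmBand-class] objects (default [defaultBands()]).
#' @return Named list: band name -> band-passed [Recording-class].
#' @export
bandDecompose <- function(rec, bands = defaultBands()) {
  fs <- samplingRate(rec)
  out <- list()
  for (b in bands) {
    if (b@highHz > fs / 2)
      stop(sprintf("band %s (%g-%g Hz) exceeds the Nyquist rate %g Hz",
                   b@name, b@lowHz, b@highHz, fs / 2))
    bp <- signal::butter(4, c(b@lowHz, b@highHz) / (fs / 2), type = "pass")
    out[[b@name]] <- Recording(zeroPhase(bp, signalData(rec),
                                         padLen = round(fs)), fs = fs,
                               labels = channelLabels(rec),
                               unit = unitTag(rec))
  }
  out
}

#' Cut a recording into sliding-window epochs
#'
#' Windows are half-open sample ranges `[start, start + window)` with starts
#' at integer multiples of the step from sample 1, so a recording of duration
#' `D` yields `floor((D - windowS) / stepS) + 1` epochs.
#'
#' @param rec a [Recording-class].
#' @param windowS window length in seconds (default 4).
#' @param stepS step in seconds (default 1).
#' @return An [EpochSet-class].
#' @examples
#' rec <- Recording(matrix(rnorm(2 * 2500), 2), fs = 250)
#' nEpochs(slidingWindows(rec, 4, 1))  # 7 epochs from 10 s
#' @export
slidingWindows <- function(rec, windowS = 4, stepS = 1) {
  fs <- samplingRate(rec)
  X <- signalData(rec)
  winN <- round(windowS * fs)
  stepN <- round(stepS * fs)
  if (winN > ncol(X))
    stop(sprintf("window (%g s) longer than recording (%g s)", windowS,
                 ncol(X) / fs))
  if (stepN < 1) stop("step must be positive")
  starts <- seq(1, ncol(X) - winN + 1, by = stepN)
  epochs <- lapply(starts, function(s) X[, s + seq_len(winN) - 1,
                                         drop = FALSE])
  new("EpochSet", epochs = epochs, windowS = windowS, stepS = stepS,
      fs = fs, labels = channelLabels(rec))
}

#' Apply an externally supplied channel-space operator
#'
#' Hook for users with real data who have derived an artifact-removal
#' operator (e.g. an ICA unmixing/pruning matrix) outside the package:
#' multiplies the channel dimension by `operator`.
#'
#' @param rec a [Recording-class].
#' @param operator channels x channels numeric matrix.
#' @return The transformed [Recording-class].
#' @export
applyChannelOperator <- function(rec, operator) {
  operator <- as.matrix(operator)
  if (ncol(operator) != nChannels(rec) || nrow(operator) != nChannels(rec))
    stop("operator must be channels x channels")
  Recording(operator %*% signalData(rec), fs = samplingRate(rec),
            labels = channelLabels(rec), unit = unitTag(rec))
}
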