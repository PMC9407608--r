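## MVAR fitting and the directed transfer function.
##
## X(n) = sum_{r=1}^{p} A_r X(n-r) + W(n); the spectral transfer matrix is
## H(f) = [I - sum_r A_r e^{-i 2 pi f r / fs}]^{-1} and the (inflow-
## normalised) DTF from channel j into channel i at frequency f is
## |H_ij(f)|^2 / sum_k |H_ik(f)|^2.

#' Fit an MVAR model to one epoch by least squares
#'
#' Ordinary least squares on the stacked lag regression; the residual
#' covariance is the innovation covariance estimate (degrees-of-freedom
#' corrected).
#'
#' @param epoch channels x samples numeric matrix.
#' @param p model order, >= 1; the epoch must have more than
#'   `nchannels * p + 1` samples.
#' @param fs sampling rate of the epoch in Hz (default 250); carried into
#'   the model for frequency evaluation.
#' @param labels optional channel labels (default rownames).
#' @return An [MVARModel-class].
#' @export
fitMVAR <- function(epoch, p, fs = 250, labels = NULL) {
  epoch <- as.matrix(epoch)
  N <- nrow(epoch)
  n <- ncol(epoch)
  if (p < 1) stop("model order p must be >= 1")
  p <- as.integer(p)
  if (n <= N * p + 1)
    stop(sprintf(
      "epoch too short (%d samples) for N = %d, p = %d; use longer epochs or smaller p",
      n, N, p))
  if (is.null(labels)) {
    labels <- rownames(epoch)
    if (is.null(labels)) labels <- paste0("ch", seq_len(N))
  }
  Y <- epoch[, (p + 1):n, drop = FALSE]
  Z <- do.call(rbind, lapply(seq_len(p), function(r)
    epoch[, (p + 1 - r):(n - r), drop = FALSE]))
  # Truncated-SVD least squares (relative tolerance 1e-8). Band-filtered
  # epochs make the lag regressors nearly collinear (a narrowband signal's
  # lags span few dimensions), so plain QR would reject them; the
  # minimum-norm solution is the standard remedy and is deterministic.
  sv <- svd(t(Z))
  if (sv$d[1] <= 0)
    stop(sprintf(
      "rank-deficient regressor matrix (N = %d, p = %d, %d samples); use longer epochs or smaller p",
      N, p, n))
  keep <- sv$d > 1e-8 * sv$d[1]
  dInv <- ifelse(keep, 1 / sv$d, 0)
  A <- t(sv$v %*% (dInv * (t(sv$u) %*% t(Y))))
  E <- Y - A %*% Z
  nEff <- n - p
  Sigma <- tcrossprod(E) / max(1, nEff - N * p)
  Sigma <- (Sigma + t(Sigma)) / 2
  coeffs <- lapply(seq_len(p), function(r)
    A[, (r - 1) * N + seq_len(N), drop = FALSE])
  new("MVARModel", order = p, coeffs = coeffs, noiseCov = Sigma, fs = fs,
      labels = as.character(labels))
}

#' Select the MVAR model order by information criteria
#'
#' Fits every order in `pRange` over a common sample span and returns the
#' BIC argmin. The AIC argmin is attached as attribute `"aic"`; a warning is
#' raised when the two disagree by more than 2.
#'
#' @param epoch channels x samples matrix.
#' @param pRange integer vector of candidate orders (default `2:15`).
#' @param fs sampling rate in Hz (default 250).
#' @return The selected order (integer) with attributes `aic` (AIC argmin)
#'   and `table` (per-order criteria).
#' @export
selectOrder <- function(epoch, pRange = 2:15, fs = 250) {
  if (!length(pRange)) stop("pRange must be non-empty")
  pRange <- sort(unique(as.integer(pRange)))
  epoch <- as.matrix(epoch)
  N <- nrow(epoch)
  n <- ncol(epoch)
  pMax <- max(pRange)
  if (n <= N * pMax + 1)
    stop("epoch too short for the largest candidate order")
  nEff <- n - pMax  # common span so criteria are comparable across orders
  crit <- vapply(pRange, function(p) {
    sub <- epoch[, (pMax - p + 1):n, drop = FALSE]
    m <- fitMVAR(sub, p, fs = fs)
    Y <- sub[, (p + 1):ncol(sub), drop = FALSE]
    Z <- do.call(rbind, lapply(seq_len(p), function(r)
      sub[, (p + 1 - r):(ncol(sub) - r), drop = FALSE]))
    A <- do.call(cbind, coefMatrices(m))
    E <- Y - A %*% Z
    SigmaML <- tcrossprod(E) / nEff
    ld <- determinant(SigmaML, logarithm = TRUE)$modulus
    k <- p * N^2
    c(aic = ld + 2 * k / nEff, bic = ld + log(nEff) * k / nEff)
  }, numeric(2))
  pBic <- pRange[which.min(crit["bic", ])]
  pAic <- pRange[which.min(crit["aic", ])]
  if (abs(pBic - pAic) > 2)
    warning(sprintf("AIC (%d) and BIC (%d) disagree by more than 2",
                    pAic, pBic))
  structure(pBic, aic = pAic,
            table = data.frame(p = pRange, aic = crit["aic", ],
                               bic = crit["bic", ]))
}

#' Spectral transfer matrix of an MVAR model
#'
#' `H(f) = [I - sum_r A_r exp(-i 2 pi f r / fs)]^{-1}`.
#'
#' @param model an [MVARModel-class].
#' @param fHz frequency in Hz, `0 <= fHz <= fs/2`.
#' @return N x N complex matrix. A warning is raised when the bracket is
#'   near-singular (condition estimate above 1e12).
#' @export
transferMatrix <- function(model, fHz) {
  fs <- samplingRate(model)
  if (fHz < 0 || fHz > fs / 2)
    stop(sprintf("frequency %g Hz outside [0, %g]", fHz, fs / 2))
  A <- coefMatrices(model)
  N <- nrow(A[[1]])
  Abar <- diag(N) + 0i
  for (r in seq_along(A))
    Abar <- Abar - A[[r]] * exp(-2i * pi * fHz * r / fs)
  H <- tryCatch(solve(Abar), error = function(e)
    stop(sprintf("transfer matrix singular at %g Hz", fHz)))
  if (norm(abs(Abar), "1") * norm(abs(H), "1") > 1e12)
    warning(sprintf("transfer matrix poorly conditioned at %g Hz", fHz))
  H
}

#' Directed transfer function at one frequency
#'
#' Row-normalised (inflow) DTF:
#' `DTF[i, j] = |H_ij|^2 / sum_k |H_ik|^2`, so the total inflow into each
#' sink i sums to 1. Column normalisation (outflows from each source sum
#' to 1) is available for sensitivity analysis.
#'
#' @param model an [MVARModel-class].
#' @param fHz frequency in Hz.
#' @param normalization `"row"` (default, inflow) or `"column"`.
#' @return N x N real matrix with entries in `[0, 1]`; under `"row"`, every
#'   row sums to 1.
#' @export
dtf <- function(model, fHz, normalization = c("row", "column")) {
  normalization <- match.arg(normalization)
  H <- transferMatrix(model, fHz)
  P <- Mod(H)^2
  if (normalization == "row") {
    s <- rowSums(P)
    if (any(s == 0)) stop("zero row in |H|^2; cannot normalise")
    P / s
  } else {
    s <- colSums(P)
    if (any(s == 0)) stop("zero column in |H|^2; cannot normalise")
    sweep(P, 2, s, "/")
  }
}

#' Band-aggregated DTF connectivity matrix
#'
#' Arithmetic mean of [dtf()] over the uniform frequency grid
#' `seq(lowHz, highHz, by = dfHz)` (grid points above `highHz` excluded).
#' Averaging preserves the row-normalisation exactly.
#'
#' @param model an [MVARModel-class].
#' @param band a [RhythmBand-class] within the Nyquist range.
#' @param dfHz grid resolution in Hz (default 0.5).
#' @param epochIndex epoch index recorded in the result (default NA).
#' @param normalization passed to [dtf()].
#' @return A [ConnectivityMatrix-class]; entry `[i, j]` is the band-mean
#'   flow j -> i.
#' @export
bandDTF <- function(model, band, dfHz = 0.5, epochIndex = NA_integer_,
                    normalization = c("row", "column")) {
  normalization <- match.arg(normalization)
  if (dfHz <= 0) stop("dfHz must be positive")
  grid <- seq(band@lowHz, band@highHz, by = dfHz)
  if (!length(grid)) stop("empty frequency grid")
  acc <- 0
  for (f in grid) acc <- acc + dtf(model, f, normalization)
  vals <- acc / length(grid)
  vals[vals < 0] <- 0
  vals[vals > 1] <- 1
  ConnectivityMatrix(vals, band = band, labels = channelLabels(model),
                     epochIndex = epochIndex)
}
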