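## Spherical-spline surface Laplacian (current source density).
##
## The scalp potential map at each time sample is interpolated by a
## spherical spline built from the Legendre series kernel g, and the surface
## Laplacian of that spline -- the CSD estimate -- is evaluated through the
## companion kernel h. The construction follows the standard Perrin-style
## spherical spline: g uses the exponent (n(n+1))^m, h uses (n(n+1))^(m-1)
## with a leading minus sign.

#' Spherical-spline parameters
#'
#' @param m spline flexibility constant, integer >= 2 (default 4). Larger m
#'   gives smoother splines; m = 4 is the established CSD default.
#' @param nTerms Legendre series truncation, >= 10 (default 50; the series
#'   converges rapidly for m >= 2).
#' @param lambda ridge/smoothing constant added to the diagonal of the
#'   interpolation matrix (default 1e-5).
#' @param headRadiusCm head radius used to scale the CSD output to
#'   per-cm^2 units (default 10). Affects units only; rank-based
#'   thresholding downstream is unaffected.
#' @return A `SplineParams` object.
#' @export
SplineParams <- function(m = 4, nTerms = 50, lambda = 1e-5,
                         headRadiusCm = 10) {
  if (m < 2) stop("m must be >= 2")
  if (nTerms < 10) stop("nTerms must be >= 10")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(m = m, nTerms = nTerms, lambda = lambda,
                 headRadiusCm = headRadiusCm), class = "SplineParams")
}

# P_1(x) .. P_nmax(x) by the three-term recurrence; x may be a vector.
# Returns a length(x) x nmax matrix.
legendreTable <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pPrev <- rep(1, length(x))   # P_0
  pCur <- x                    # P_1
  out[, 1] <- pCur
  if (nmax >= 2) {
    for (n in 1:(nmax - 1)) {
      pNext <- ((2 * n + 1) * x * pCur - n * pPrev) / (n + 1)
      out[, n + 1] <- pNext
      pPrev <- pCur
      pCur <- pNext
    }
  }
  out
}

#' Spherical-spline interpolation and Laplacian kernels
#'
#' `legendreSeriesG` evaluates
#' `g(x) = (1/4pi) * sum_{n=1}^{nTerms} (2n+1) / (n(n+1))^m * P_n(x)`,
#' the spline interpolation kernel; `legendreSeriesH` evaluates the
#' Laplacian kernel
#' `h(x) = -(1/4pi) * sum (2n+1) / (n(n+1))^(m-1) * P_n(x)`.
#'
#' @param x cosine of the angular distance, in `[-1, 1]` (vectorised).
#' @param params a [SplineParams()] object.
#' @return Numeric vector of kernel values.
#' @export
legendreSeriesG <- function(x, params = SplineParams()) {
  if (any(abs(x) > 1 + 1e-12)) stop("|x| must be <= 1")
  x <- pmin(1, pmax(-1, x))
  n <- seq_len(params$nTerms)
  w <- (2 * n + 1) / (n * (n + 1))^params$m
  as.numeric(legendreTable(x, params$nTerms) %*% w) / (4 * pi)
}

#' @rdname legendreSeriesG
#' @export
legendreSeriesH <- function(x, params = SplineParams()) {
  if (any(abs(x) > 1 + 1e-12)) stop("|x| must be <= 1")
  x <- pmin(1, pmax(-1, x))
  n <- seq_len(params$nTerms)
  w <- (2 * n + 1) / (n * (n + 1))^(params$m - 1)
  -as.numeric(legendreTable(x, params$nTerms) %*% w) / (4 * pi)
}

# bordered spherical-spline system for a montage:
#   [G + lambda I, 1; 1', 0] [c; c0] = [v; 0]
# Returns the pieces needed to solve for any number of potential vectors.
splineSystem <- function(montage, params) {
  ct <- tcrossprod(positionMatrix(montage))
  ct[ct > 1] <- 1
  ct[ct < -1] <- -1
  n <- nrow(ct)
  G <- matrix(legendreSeriesG(as.numeric(ct), params), n, n)
  G <- G + params$lambda * diag(n)
  B <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Binv <- tryCatch(solve(B), error = function(e)
    stop("singular spherical-spline system (duplicate electrodes?): ",
         conditionMessage(e)))
  H <- matrix(legendreSeriesH(as.numeric(ct), params), n, n)
  list(Binv = Binv, H = H, n = n)
}

#' Fit the spherical spline to one potential map
#'
#' Solves the regularised system `G c + c0 1 = v` under the zero-sum
#' constraint `sum(c) = 0`.
#'
#' @param potentials numeric vector, one value per montage electrode.
#' @param montage a [Montage-class].
#' @param params a [SplineParams()].
#' @return List with elements `c` (coefficients, summing to zero) and `c0`
#'   (the constant term).
#' @export
fitSpline <- function(potentials, montage, params = SplineParams()) {
  if (length(potentials) != nChannels(montage))
    stop("potential vector length must equal montage size")
  sys <- splineSystem(montage, params)
  sol <- sys$Binv %*% c(potentials, 0)
  list(c = as.numeric(sol[seq_len(sys$n)]), c0 = as.numeric(sol[sys$n + 1]))
}

#' Current-source-density transform of a recording
#'
#' Per time sample, fits the spherical spline to the potential map and
#' evaluates its surface Laplacian at every electrode:
#' `CSD_i = sum_k c_k h(cos theta_ik) / headRadiusCm^2`. The transform is
#' linear and is applied as a single precomputed matrix across all time
#' samples. The output is reference-free: adding a constant to all input
#' channels leaves it unchanged.
#'
#' @param rec a [Recording-class] with `unitTag` `"scalp_potential"` whose
#'   labels match the montage.
#' @param montage a [Montage-class].
#' @param params a [SplineParams()].
#' @return A [Recording-class] with `unitTag` `"csd"`.
#' @seealso [csdMatrix()] for the bare transform matrix.
#' @export
computeCSD <- function(rec, montage, params = SplineParams()) {
  if (unitTag(rec) != "scalp_potential")
    stop("input recording must be scalp potentials, not ", unitTag(rec))
  if (!identical(channelLabels(rec), channelLabels(montage)))
    stop("recording labels must match the montage labels (same order)")
  M <- csdMatrix(montage, params)
  Recording(M %*% signalData(rec), fs = samplingRate(rec),
            labels = channelLabels(rec), unit = "csd")
}

#' @rdname computeCSD
#' @param montage a [Montage-class].
#' @export
csdMatrix <- function(montage, params = SplineParams()) {
  sys <- splineSystem(montage, params)
  P <- sys$Binv[seq_len(sys$n), seq_len(sys$n)]
  (sys$H %*% P) / params$headRadiusCm^2
}
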