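# Independent oracles and small generators shared across the test files.
# Each oracle deliberately uses a different algorithm than the package code.

# Floyd-Warshall all-pairs hop counts (package code uses layered BFS)
fwDistances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# naive double-loop directed clustering (union neighbourhood)
naiveClustering <- function(A) {
  N <- nrow(A)
  out <- numeric(N)
  for (i in seq_len(N)) {
    nb <- integer(0)
    for (j in seq_len(N))
      if (j != i && (A[i, j] == 1 || A[j, i] == 1)) nb <- c(nb, j)
    k <- length(nb)
    if (k < 2) next
    mcount <- 0
    for (u in nb) for (v in nb) if (u != v && A[u, v] == 1)
      mcount <- mcount + 1
    out[i] <- mcount / (k * (k - 1))
  }
  out
}

# literal Benjamini-Hochberg step-up on sorted p-values
naiveBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# independent Legendre-series oracle: P_n evaluated through the Laplace
# integral P_n(x) = (1/pi) Int_0^pi (x + i sqrt(1-x^2) cos t)^n dt by
# high-order Gauss-Legendre quadrature -- a completely different route than
# the package's three-term recurrence
oracleLegendre <- function(n, x) {
  gl <- pracma::gaussLegendre(2000, 0, pi)
  vapply(x, function(xi)
    Re(sum(gl$w * (xi + 1i * sqrt(max(0, 1 - xi^2)) * cos(gl$x))^n)) / pi,
    numeric(1))
}

oracleSeries <- function(x, m, nTerms) {
  tot <- 0
  for (n in seq_len(nTerms))
    tot <- tot + (2 * n + 1) / (n * (n + 1))^m * oracleLegendre(n, x)
  tot / (4 * pi)
}

# rank-based AUC of scores for a binary truth vector
rankAUC <- function(scores, truth) {
  r <- rank(scores)
  nPos <- sum(truth)
  nNeg <- sum(!truth)
  (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# random Erdos-Renyi digraph as a DirectedNetwork
randomNet <- function(N, density, seed) {
  set.seed(seed)
  A <- matrix(as.integer(runif(N * N) < density), N, N)
  diag(A) <- 0L
  DirectedNetwork(A)
}

# random stable MVAR model: random coefficients rescaled so the companion
# spectral radius is exactly 0.8 (scaling A_r by s^r scales eigenvalues
# by s)
randomStableModel <- function(N, p, seed, fs = 250, targetRho = 0.8) {
  set.seed(seed)
  A <- lapply(seq_len(p), function(r) matrix(rnorm(N * N, sd = 0.3), N, N))
  companion <- function(A) {
    comp <- matrix(0, N * p, N * p)
    for (r in seq_len(p)) comp[seq_len(N), (r - 1) * N + seq_len(N)] <- A[[r]]
    if (p > 1)
      comp[N + seq_len(N * (p - 1)), seq_len(N * (p - 1))] <-
        diag(N * (p - 1))
    comp
  }
  rho <- max(Mod(eigen(companion(A), only.values = TRUE)$values))
  s <- targetRho / rho
  A <- lapply(seq_len(p), function(r) A[[r]] * s^r)
  new("MVARModel", order = as.integer(p), coeffs = A,
      noiseCov = diag(N), fs = fs, labels = paste0("ch", seq_len(N)))
}

# small montage for fast end-to-end runs: a subset of the built-in 10-10
smallMontage <- function(labels = c("Fp1", "Fpz", "Fp2", "F3", "Fz", "F4",
                                    "C3", "Cz", "C4", "P3", "Pz", "P4",
                                    "PO3", "POz", "PO4", "Oz")) {
  full <- montage1010()
  idx <- match(labels, channelLabels(full))
  Montage(labels, positionMatrix(full)[idx, , drop = FALSE])
}

# connectivity matrix wrapper around a plain strength matrix
asConn <- function(V, bandName = "theta") {
  ConnectivityMatrix(V, band = RhythmBand(bandName, 4, 8))
}
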