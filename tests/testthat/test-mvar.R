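test_that("least-squares MVAR recovers known coefficients", {
  g <- GroundTruthGraph(2, order = 1L, selfCoeffs = 0.5)
  rec <- simulateMVAR(g, 5000, fs = 250, seed = 10)
  model <- fitMVAR(signalData(rec), 1, fs = 250)
  expect_lt(max(abs(coefMatrices(model)[[1]] - diag(0.5, 2))), 0.05)

  # richer model: couplings at lag 1 plus shared AR(2) self-dynamics
  g2 <- GroundTruthGraph(3, edges = rbind(c(1, 2), c(2, 3)),
                         strengths = 0.4)
  rec2 <- simulateMVAR(g2, 5000, fs = 250, seed = 11)
  m2 <- fitMVAR(signalData(rec2), 2, fs = 250)
  truthA1 <- diag(0.5, 3); truthA1[2, 1] <- 0.4; truthA1[3, 2] <- 0.4
  rmse <- sqrt(mean((coefMatrices(m2)[[1]] - truthA1)^2))
  expect_lt(rmse, 0.05)
  expect_lt(sqrt(mean((coefMatrices(m2)[[2]] - diag(-0.2, 3))^2)), 0.05)
})

test_that("white noise yields near-zero coefficients and rejects p = 0", {
  set.seed(12)
  X <- matrix(rnorm(2 * 5000), 2)
  model <- fitMVAR(X, 3, fs = 250)
  expect_lt(max(abs(unlist(coefMatrices(model)))), 0.1)
  expect_error(fitMVAR(X, 0), "p must be")
  expect_error(fitMVAR(X[, 1:5], 2), "too short")
})

test_that("BIC order selection recovers the true order", {
  hits <- 0
  for (s in 1:20) {
    g <- GroundTruthGraph(3, edges = rbind(c(1, 2)), strengths = 0.4)
    rec <- simulateMVAR(g, 5000, fs = 250, seed = 100 + s)
    p <- selectOrder(signalData(rec), 1:6, fs = 250)
    hits <- hits + (as.integer(p) == 2L)
  }
  expect_gte(hits, 18)  # >= 90% of 20 repeats
})

test_that("order selection picks the smallest order for white noise", {
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    X <- matrix(rnorm(3 * 5000), 3)
    p <- suppressWarnings(selectOrder(X, 1:5, fs = 250))
    hits <- hits + (as.integer(p) == 1L)
  }
  expect_gte(hits, 18)
  set.seed(1)
  expect_equal(as.integer(selectOrder(matrix(rnorm(2 * 500), 2), 5L)), 5L)
  expect_error(selectOrder(matrix(rnorm(20), 2), integer()), "non-empty")
})

test_that("the transfer matrix obeys identity, scalar and DC contracts", {
  idModel <- new("MVARModel", order = 1L,
                 coeffs = list(matrix(0, 3, 3)), noiseCov = diag(3),
                 fs = 250, labels = paste0("ch", 1:3))
  for (f in c(0, 10, 100))
    expect_equal(transferMatrix(idModel, f), diag(3) + 0i)

  a <- 0.6
  scalar <- new("MVARModel", order = 1L, coeffs = list(matrix(a, 1, 1)),
                noiseCov = diag(1), fs = 250, labels = "ch1")
  for (f in c(3, 17, 40)) {
    H <- transferMatrix(scalar, f)
    expect_equal(Mod(H[1, 1])^2,
                 1 / Mod(1 - a * exp(-2i * pi * f / 250))^2,
                 tolerance = 1e-12)
  }
  m <- randomStableModel(4, 2, seed = 13)
  expect_equal(Im(transferMatrix(m, 0)), matrix(0, 4, 4),
               tolerance = 1e-12)
  expect_error(transferMatrix(m, 200), "outside")
})

test_that("DTF rows always sum to one and uncoupled models are diagonal", {
  diagModel <- new("MVARModel", order = 2L,
                   coeffs = list(diag(0.4, 3), diag(-0.2, 3)),
                   noiseCov = diag(3), fs = 250,
                   labels = paste0("ch", 1:3))
  D <- dtf(diagModel, 10)
  expect_equal(D, diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  for (s in 1:10) {
    m <- randomStableModel(sample(3:6, 1), sample(1:3, 1), seed = 300 + s)
    f <- runif(1, 0, 125)
    expect_equal(rowSums(dtf(m, f)), rep(1, nrow(noiseCovariance(m))),
                 tolerance = 1e-10)
    expect_equal(colSums(dtf(m, f, normalization = "column")),
                 rep(1, nrow(noiseCovariance(m))), tolerance = 1e-10)
  }
})

test_that("DTF is invariant to common channel rescaling", {
  g <- GroundTruthGraph(3, edges = rbind(c(1, 3)), strengths = 0.4)
  rec <- simulateMVAR(g, 2000, fs = 250, seed = 14)
  d1 <- dtf(fitMVAR(signalData(rec), 2, fs = 250), 10)
  d2 <- dtf(fitMVAR(5.7 * signalData(rec), 2, fs = 250), 10)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("band DTF averages the grid and keeps normalisation", {
  m <- randomStableModel(4, 2, seed = 15)
  band <- RhythmBand("alpha", 8, 13)
  # singleton grid equals the pointwise DTF
  one <- bandDTF(m, RhythmBand("point", 10, 10.4), dfHz = 1)
  expect_equal(connectivityValues(one), dtf(m, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  cm <- bandDTF(m, band, dfHz = 0.5)
  expect_equal(unname(rowSums(connectivityValues(cm))), rep(1, 4),
               tolerance = 1e-10)
  grid <- seq(8, 13, by = 0.5)
  manual <- Reduce(`+`, lapply(grid, function(f) dtf(m, f))) / length(grid)
  expect_equal(connectivityValues(cm), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(bandDTF(m, band, dfHz = 0), "positive")
})

test_that("mean band DTF ranks true edges above absent ones (AUC >= 0.9)", {
  g <- GroundTruthGraph(5, edges = rbind(c(1, 2), c(2, 3), c(1, 4),
                                         c(4, 5)), strengths = 0.4)
  rec <- simulateMVAR(g, 60 * 1000, fs = 250, seed = 16)
  eps <- slidingWindows(rec, 4, 4)  # 60 non-overlapping 4 s epochs
  V <- 0
  for (i in seq_len(nEpochs(eps))) {
    mod <- fitMVAR(epochData(eps, i), 2, fs = 250)
    V <- V + connectivityValues(bandDTF(mod, RhythmBand("broad", 1, 45)))
  }
  V <- V / nEpochs(eps)
  truth <- matrix(FALSE, 5, 5)
  truth[cbind(g@edges[, 2], g@edges[, 1])] <- TRUE  # sink row, source col
  off <- row(V) != col(V)
  expect_gte(rankAUC(V[off], truth[off]), 0.9)
})
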