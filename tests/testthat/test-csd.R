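test_that("g and h match the independent partial-sum oracle to 1e-12", {
  par <- SplineParams(m = 4, nTerms = 50)
  xs <- c(-1, -0.3, 0, 0.5, 0.99, 1)
  expect_equal(legendreSeriesG(xs, par), oracleSeries(xs, 4, 50),
               tolerance = 1e-12)
  expect_equal(legendreSeriesH(xs, par), -oracleSeries(xs, 3, 50),
               tolerance = 1e-12)
  # closed form at x = 1: P_n(1) = 1 for all n
  n <- 1:50
  expect_equal(legendreSeriesG(1, par),
               sum((2 * n + 1) / (n * (n + 1))^4) / (4 * pi),
               tolerance = 1e-14)
})

test_that("the series converges fast for m = 4 and h relates to g by m - 1", {
  x <- seq(-1, 1, length.out = 21)
  g50 <- legendreSeriesG(x, SplineParams(m = 4, nTerms = 50))
  g100 <- legendreSeriesG(x, SplineParams(m = 4, nTerms = 100))
  expect_lt(max(abs(g50 - g100)), 1e-10)
  # h with flexibility m equals -g evaluated with flexibility m - 1
  h <- legendreSeriesH(x, SplineParams(m = 4, nTerms = 50))
  gm1 <- legendreSeriesG(x, SplineParams(m = 3, nTerms = 50))
  expect_equal(h, -gm1, tolerance = 1e-15)
  expect_error(legendreSeriesG(1.5), "<= 1")
  expect_true(all(is.finite(legendreSeriesG(runif(100, -1, 1)))))
})

test_that("spline fitting honours the constant map and permutations", {
  mont <- smallMontage()
  fit <- fitSpline(rep(4.2, 16), mont)
  expect_equal(fit$c0, 4.2, tolerance = 1e-9)
  expect_lt(max(abs(fit$c)), 1e-7)

  set.seed(4)
  v <- rnorm(16)
  fit1 <- fitSpline(v, mont)
  expect_lt(abs(sum(fit1$c)), 1e-10)
  perm <- sample(16)
  mont2 <- Montage(channelLabels(mont)[perm],
                   positionMatrix(mont)[perm, ])
  fit2 <- fitSpline(v[perm], mont2)
  expect_equal(fit2$c, fit1$c[perm], tolerance = 1e-8)
  expect_error(fitSpline(v[1:5], mont), "length")
})

test_that("the fitted spline reproduces the training potentials", {
  # residual of the interpolation system is tiny at small lambda
  mont <- smallMontage()
  par <- SplineParams(lambda = 0)
  set.seed(8)
  v <- rnorm(16)
  fit <- fitSpline(v, mont, par)
  ct <- tcrossprod(positionMatrix(mont))
  G <- matrix(legendreSeriesG(as.numeric(pmax(pmin(ct, 1), -1)), par),
              16, 16)
  recon <- as.numeric(G %*% fit$c) + fit$c0
  expect_lt(max(abs(recon - v)) / max(abs(v)), 1e-8)
})

test_that("CSD is zero for constant maps and reference-free", {
  mont <- smallMontage()
  labs <- channelLabels(mont)
  recConst <- Recording(matrix(3, 16, 20), fs = 250, labels = labs)
  expect_lt(max(abs(signalData(computeCSD(recConst, mont)))), 1e-9)

  set.seed(5)
  X <- matrix(rnorm(16 * 50), 16)
  rec <- Recording(X, fs = 250, labels = labs)
  shifted <- Recording(X + 7.3, fs = 250, labels = labs)
  expect_equal(signalData(computeCSD(rec, mont)),
               signalData(computeCSD(shifted, mont)), tolerance = 1e-9)
  expect_identical(unitTag(computeCSD(rec, mont)), "csd")
  expect_error(computeCSD(Recording(X, fs = 250), mont), "labels")
  expect_error(computeCSD(computeCSD(rec, mont), mont), "scalp")
})

test_that("CSD is linear in the input", {
  mont <- smallMontage()
  labs <- channelLabels(mont)
  set.seed(6)
  U <- matrix(rnorm(16 * 30), 16)
  V <- matrix(rnorm(16 * 30), 16)
  lhs <- signalData(computeCSD(
    Recording(2 * U + 3 * V, fs = 250, labels = labs), mont))
  rhs <- 2 * signalData(computeCSD(Recording(U, fs = 250, labels = labs),
                                   mont)) +
         3 * signalData(computeCSD(Recording(V, fs = 250, labels = labs),
                                   mont))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("CSD magnitude peaks at the electrode nearest a focal source", {
  mont <- montage1010()
  labs <- channelLabels(mont)
  pos <- positionMatrix(mont)
  target <- which(labs == "Cz")
  par <- SplineParams()
  # forward-construct potentials from the interpolation kernel g around Cz
  cosang <- as.numeric(pos %*% pos[target, ])
  v <- legendreSeriesG(pmax(pmin(cosang, 1), -1), par)
  rec <- Recording(matrix(v, ncol = 1), fs = 250, labels = labs)
  cs <- signalData(computeCSD(rec, mont, par))[, 1]
  expect_equal(unname(which.max(abs(cs))), target)
})

test_that("montage files round-trip through both text formats", {
  mont <- smallMontage()
  pos <- positionMatrix(mont)
  f1 <- tempfile()
  write.table(cbind(channelLabels(mont), round(pos, 9)), f1,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  m1 <- readMontage(f1)
  expect_equal(positionMatrix(m1), pos, tolerance = 1e-6,
               ignore_attr = TRUE)
  # spherical form
  th <- acos(pos[, 3]) * 180 / pi
  ph <- atan2(pos[, 2], pos[, 1]) * 180 / pi
  f2 <- tempfile()
  write.table(data.frame(channelLabels(mont), th, ph), f2,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  m2 <- readMontage(f2)
  expect_equal(positionMatrix(m2), pos, tolerance = 1e-6,
               ignore_attr = TRUE)
})
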