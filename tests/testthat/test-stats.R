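test_that("normality screening is calibrated and has power", {
  normHits <- 0; expHits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    kn <- ksNormality(rnorm(5000))
    normHits <- normHits + (kn$p > 0.05)
    ke <- ksNormality(rexp(5000))
    expHits <- expHits + (ke$p < 0.01)
  }
  expect_gte(normHits, 18)
  expect_gte(expHits, 18)
  expect_error(ksNormality(rnorm(7)), "at least 8")
  expect_error(ksNormality(rep(1, 20)), "constant")
})

test_that("one-way ANOVA matches the classical F in closed and oracle form", {
  r <- anovaOneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  # separation limit: tiny within-group jitter drives F up and p down
  eps <- 1e-6
  sep <- anovaOneway(list(c(0, eps, 0, -eps), c(1, 1 + eps, 1, 1 - eps)))
  expect_gt(sep$F, 1e9)
  expect_lt(sep$p, 1e-12)

  # three-group textbook-style case against an independent implementation
  g1 <- c(6.9, 5.4, 5.8, 4.6, 4.0)
  g2 <- c(8.3, 6.8, 7.8, 9.2, 6.5)
  g3 <- c(8.0, 10.5, 8.1, 6.9, 9.3)
  r3 <- anovaOneway(list(g1, g2, g3))
  df <- data.frame(y = c(g1, g2, g3),
                   g = factor(rep(1:3, each = 5)))
  oracle <- anova(lm(y ~ g, data = df))
  expect_equal(r3$F, oracle[["F value"]][1], tolerance = 1e-10)
  expect_equal(r3$p, oracle[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(c(r3$df1, r3$df2), c(2, 12))

  expect_error(anovaOneway(list(1:3)), "2 groups")
  expect_error(anovaOneway(list(c(2, 2), c(2, 2))), "degenerate")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    r <- anovaOneway(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the literal step-up on random vectors", {
  r <- fdrBH(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$adjusted, rep(0.04, 4))

  expect_equal(fdrBH(rep(1, 5))$adjusted, rep(1, 5))
  expect_false(any(fdrBH(rep(1, 5))$reject))
  expect_equal(fdrBH(0.03)$adjusted, 0.03)

  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdrBH(p)$adjusted, naiveBH(p), tolerance = 1e-14)
  }
  expect_error(fdrBH(c(0.2, 1.4)), "0, 1")
  expect_error(fdrBH(0.5, alpha = 1), "alpha")
})

makeMetricTable <- function(stages, nEpoch, nodes = NULL, shift = 0,
                            seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_along(stages)) {
    mu <- if (s > 1) shift else 0
    for (m in c("clustering", "path_length", "efficiency"))
      rows[[length(rows) + 1]] <- data.frame(
        stage = stages[s], band = "theta", epoch = seq_len(nEpoch),
        metric = m, node = NA_character_,
        value = rnorm(nEpoch, mean = mu))
    for (nd in nodes)
      rows[[length(rows) + 1]] <- data.frame(
        stage = stages[s], band = "theta", epoch = seq_len(nEpoch),
        metric = "causal_flow", node = nd,
        value = rnorm(nEpoch, mean = mu))
  }
  do.call(rbind, rows)
}

test_that("stage contrasts build the right families and respect alpha", {
  tab <- makeMetricTable(c("T0", "T1", "T2", "T4"), nEpoch = 30,
                         nodes = c("Fp1", "Oz"), shift = 3, seed = 2)
  res <- stageContrasts(tab, observation = "epoch")
  glob <- res[res$metric != "causal_flow", ]
  # three global metrics x three non-baseline stages
  expect_equal(nrow(glob), 9)
  expect_setequal(unique(glob$contrast),
                  c("T1 vs T0", "T2 vs T0", "T4 vs T0"))
  cf <- res[res$metric == "causal_flow", ]
  expect_equal(nrow(cf), 2)              # one per electrode, T4 vs T0
  expect_true(all(cf$contrast == "T4 vs T0"))
  expect_true(all(res$pFdr >= res$pRaw - 1e-15))
  expect_true(all(res$significant == (res$pFdr < 0.05)))
  # a three-sd shift must be detected
  expect_true(all(res$significant))

  # alpha = 0.999 flags practically everything on null data too
  nullTab <- makeMetricTable(c("T0", "T4"), nEpoch = 25, shift = 0,
                             seed = 3)
  resNull <- stageContrasts(nullTab, alpha = 0.999, observation = "epoch")
  expect_true(all(resNull$significant))
  expect_error(stageContrasts(nullTab, baselineStage = "T9"), "T9")
})

test_that("block averaging reduces the observation count per stage", {
  tab <- makeMetricTable(c("T0", "T4"), nEpoch = 57, shift = 0, seed = 4)
  resBlock <- stageContrasts(tab, observation = "block", blockS = 10,
                             stepS = 1)
  resEpoch <- stageContrasts(tab, observation = "epoch")
  # 57 epochs in blocks of 10 onsets -> 6 observations: df2 = 6 + 6 - 2
  expect_equal(unique(resBlock$df2), 10)
  expect_equal(unique(resEpoch$df2), 112)
})
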