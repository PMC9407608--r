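## Stage-contrast statistics: Lilliefors normality screening, classical
## one-way ANOVA, Benjamini-Hochberg FDR, and the stage-contrast driver.

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' Lilliefors-corrected one-sample KS test against a normal distribution
#' with the sample's own mean and standard deviation (the plain KS test is
#' anticonservative when parameters are estimated).
#'
#' @param sample numeric vector, `n >= 8`.
#' @return List with `statistic` and `p`.
#' @export
ksNormality <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 8) stop("need at least 8 observations")
  if (stats::sd(sample) == 0)
    stop("constant sample: normality test degenerate")
  t <- nortest::lillie.test(sample)
  list(statistic = unname(t$statistic), p = unname(t$p.value))
}

#' Classical one-way ANOVA
#'
#' Between/within F with degrees of freedom (k - 1, n - k).
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return List with `F`, `df1`, `df2` and `p`.
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(values) == 0)
    stop("all observations identical: ANOVA degenerate")
  t <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(t$statistic), df1 = unname(t$parameter[1]),
       df2 = unname(t$parameter[2]), p = unname(t$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`p.adjust` method `"BH"`) and the rejection
#' mask at level `alpha`.
#'
#' @param pValues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (logical; `adjusted < alpha`).
#' @export
fdrBH <- function(pValues, alpha = 0.05) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  adjusted <- stats::p.adjust(pValues, method = "BH")
  list(adjusted = adjusted, reject = adjusted < alpha)
}

# observation vectors per stage for one (band, metric, node) cell, with
# optional block averaging (blocks of blockS seconds of window onsets)
observationsByStage <- function(tab, observation, blockS, stepS) {
  split_ <- split(tab$value[order(tab$epoch)], tab$stage[order(tab$epoch)])
  if (observation == "epoch") return(split_)
  blockLen <- max(1L, round(blockS / stepS))
  lapply(split_, function(v) {
    as.numeric(tapply(v, (seq_along(v) - 1L) %/% blockLen, mean))
  })
}

#' Stage-contrast statistics for a metric table
#'
#' For each global metric (clustering, path length, efficiency) and band,
#' runs a one-way ANOVA of every non-baseline stage against the baseline
#' and applies BH-FDR across those contrasts. For the per-electrode causal
#' flow, runs one ANOVA per electrode between `contrastStage` and the
#' baseline and applies BH-FDR across the electrodes.
#'
#' Observations default to block means (`blockS` seconds of window onsets
#' per block, matching the per-minute averages used in fatigue studies);
#' `observation = "epoch"` treats every sliding-window epoch as an
#' observation, which is anticonservative because overlapping windows are
#' strongly autocorrelated.
#'
#' @param metrics tidy data.frame with columns `stage`, `band`, `epoch`,
#'   `metric`, `node` (NA for global metrics) and `value`, as produced by
#'   [runPipeline()].
#' @param baselineStage baseline stage label (default `"T0"`).
#' @param alpha significance level (default 0.05).
#' @param contrastStage stage contrasted per electrode for causal flow
#'   (default `"T4"`; skipped if absent from the table).
#' @param observation `"block"` (default) or `"epoch"`.
#' @param blockS block length in seconds of window onsets (default 60).
#' @param stepS window step the epochs were cut at, in seconds (default 1).
#' @return data.frame with columns `contrast`, `band`, `metric`, `node`,
#'   `F`, `df1`, `df2`, `pRaw`, `pFdr`, `significant`.
#' @export
stageContrasts <- function(metrics, baselineStage = "T0", alpha = 0.05,
                           contrastStage = "T4",
                           observation = c("block", "epoch"), blockS = 60,
                           stepS = 1) {
  observation <- match.arg(observation)
  stages <- unique(metrics$stage)
  if (!baselineStage %in% stages)
    stop("baseline stage ", baselineStage, " not present in the table")
  others <- setdiff(stages, baselineStage)
  res <- list()
  globalMetrics <- intersect(unique(metrics$metric),
                             c("clustering", "path_length", "efficiency"))
  for (b in unique(metrics$band)) {
    for (m in globalMetrics) {
      tab <- metrics[metrics$band == b & metrics$metric == m &
                       is.na(metrics$node), ]
      if (!nrow(tab)) next
      obs <- observationsByStage(tab, observation, blockS, stepS)
      rows <- lapply(others, function(s) {
        a <- anovaOneway(list(obs[[baselineStage]], obs[[s]]))
        data.frame(contrast = paste(s, "vs", baselineStage), band = b,
                   metric = m, node = NA_character_, F = a$F, df1 = a$df1,
                   df2 = a$df2, pRaw = a$p, stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, rows)
      adj <- fdrBH(fam$pRaw, alpha)
      fam$pFdr <- adj$adjusted
      fam$significant <- adj$reject
      res[[length(res) + 1]] <- fam
    }
    # per-electrode causal flow: contrastStage vs baseline, FDR over nodes
    cfTab <- metrics[metrics$band == b & metrics$metric == "causal_flow" &
                       !is.na(metrics$node), ]
    if (nrow(cfTab) && contrastStage %in% stages) {
      nodes <- unique(cfTab$node)
      rows <- lapply(nodes, function(nd) {
        tab <- cfTab[cfTab$node == nd &
                       cfTab$stage %in% c(baselineStage, contrastStage), ]
        obs <- observationsByStage(tab, observation, blockS, stepS)
        a <- anovaOneway(list(obs[[baselineStage]], obs[[contrastStage]]))
        data.frame(contrast = paste(contrastStage, "vs", baselineStage),
                   band = b, metric = "causal_flow", node = nd, F = a$F,
                   df1 = a$df1, df2 = a$df2, pRaw = a$p,
                   stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, rows)
      adj <- fdrBH(fam$pRaw, alpha)
      fam$pFdr <- adj$adjusted
      fam$significant <- adj$reject
      res[[length(res) + 1]] <- fam
    }
  }
  if (!length(res))
    return(data.frame(contrast = character(), band = character(),
                      metric = character(), node = character(),
                      F = numeric(), df1 = numeric(), df2 = numeric(),
                      pRaw = numeric(), pFdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
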