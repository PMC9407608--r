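## End-to-end orchestration: (synthesize or load) -> optional conditioning ->
## CSD -> band decomposition -> sliding windows -> MVAR/DTF per epoch ->
## sparsity traversal and thresholding -> per-epoch metrics -> stage stats.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Either `session`
#' (named list stage -> [Recording-class]) or both `sessionConfig` and
#' `graph` (to synthesize one) must be given.
#'
#' @param session named list of per-stage recordings, or NULL.
#' @param sessionConfig a [SessionConfig-class] for synthetic input, or NULL.
#' @param graph a [GroundTruthGraph-class] for synthetic input, or NULL.
#' @param montage the [Montage-class] (defaults to the session config's).
#' @param referenceLabels labels to re-reference against before analysis
#'   (NULL skips; synthetic data needs none).
#' @param csd logical: apply the CSD transform (default TRUE).
#' @param splineParams a [SplineParams()].
#' @param bands list of [RhythmBand-class] (default [defaultBands()]).
#' @param windowS,stepS sliding-window length and step in seconds
#'   (defaults 4 and 1).
#' @param order fixed MVAR order per epoch (default 5); set
#'   `orderSelection = TRUE` to choose per epoch by BIC instead.
#' @param orderSelection logical (default FALSE).
#' @param orderRange candidate orders when `orderSelection` (default 2:15).
#' @param fitOnBand logical: fit MVAR models on band-filtered epochs
#'   instead of broadband ones (default FALSE; see [epochConnectivity()]).
#' @param dfHz DTF band grid resolution in Hz (default 0.5).
#' @param sparsity fixed sparsity applied to every window (default 0.3).
#' @param perWindowSparsity logical: threshold each window at its own
#'   GCE-optimal sparsity from `sparsityGrid` instead (default FALSE).
#' @param sparsityGrid traversal grid (default `seq(0.2, 0.6, 0.05)`).
#' @param regionMap named character vector label -> region (default
#'   [defaultRegionMap()] of the montage labels).
#' @param baselineStage,contrastStage,alpha statistics options (defaults
#'   `"T0"`, `"T4"`, 0.05).
#' @param observation,blockS statistics observation unit (defaults
#'   `"block"`, 60; see [stageContrasts()]).
#' @param runStats logical: run stage contrasts (default TRUE).
#' @return A `PipelineConfig` list.
#' @export
PipelineConfig <- function(session = NULL, sessionConfig = NULL,
                           graph = NULL, montage = NULL,
                           referenceLabels = NULL, csd = TRUE,
                           splineParams = SplineParams(),
                           bands = defaultBands(), windowS = 4, stepS = 1,
                           order = 5L, orderSelection = FALSE,
                           orderRange = 2:15, fitOnBand = FALSE,
                           dfHz = 0.5, sparsity = 0.3,
                           perWindowSparsity = FALSE,
                           sparsityGrid = seq(0.2, 0.6, by = 0.05),
                           regionMap = NULL, baselineStage = "T0",
                           contrastStage = "T4", alpha = 0.05,
                           observation = "block", blockS = 60,
                           runStats = TRUE) {
  if (is.null(session) && (is.null(sessionConfig) || is.null(graph)))
    stop("provide either a session or a sessionConfig plus graph")
  if (is.null(montage) && !is.null(sessionConfig))
    montage <- sessionConfig@montage
  bad <- vapply(bands, function(b) !is(b, "RhythmBand"), logical(1))
  if (any(bad)) stop("bands must be RhythmBand objects")
  structure(list(
    session = session, sessionConfig = sessionConfig, graph = graph,
    montage = montage, referenceLabels = referenceLabels, csd = csd,
    splineParams = splineParams, bands = bands, windowS = windowS,
    stepS = stepS, order = as.integer(order),
    orderSelection = orderSelection, orderRange = orderRange,
    fitOnBand = fitOnBand, dfHz = dfHz,
    sparsity = sparsity, perWindowSparsity = perWindowSparsity,
    sparsityGrid = sparsityGrid, regionMap = regionMap,
    baselineStage = baselineStage, contrastStage = contrastStage,
    alpha = alpha, observation = observation, blockS = blockS,
    runStats = runStats), class = "PipelineConfig")
}

#' Band-resolved epoch connectivity of one recording
#'
#' Cuts the recording into sliding windows, fits one MVAR model per epoch
#' and aggregates the DTF over each rhythm band's frequency grid. By
#' default the model is fitted on the broadband epoch and only the DTF
#' evaluation is band-restricted: the MVAR spectral factorisation carries
#' the full rhythm content, and fitting narrowband-filtered epochs makes
#' the lag regression nearly singular and erases directed structure.
#' `fitOnBand = TRUE` fits each band-filtered epoch separately instead.
#'
#' @param rec a [Recording-class].
#' @param bands list of [RhythmBand-class].
#' @param windowS,stepS window parameters in seconds.
#' @param order fixed MVAR order (ignored when `orderRange` given).
#' @param dfHz DTF grid resolution.
#' @param orderRange optional integer vector: select the order per epoch by
#'   BIC over this range.
#' @param fitOnBand logical: fit the MVAR on band-filtered epochs instead
#'   of broadband ones (default FALSE).
#' @return Named list band -> list of [ConnectivityMatrix-class] per epoch.
#' @export
epochConnectivity <- function(rec, bands = defaultBands(), windowS = 4,
                              stepS = 1, order = 5L, dfHz = 0.5,
                              orderRange = NULL, fitOnBand = FALSE) {
  if (is.null(names(bands)))
    names(bands) <- vapply(bands, function(b) b@name, character(1))
  fitOne <- function(X) {
    p <- if (!is.null(orderRange))
      as.integer(selectOrder(X, orderRange, fs = samplingRate(rec)))
    else order
    fitMVAR(X, p, fs = samplingRate(rec), labels = channelLabels(rec))
  }
  out <- list()
  if (fitOnBand) {
    perBand <- bandDecompose(rec, bands)
    for (bn in names(bands)) {
      eps <- slidingWindows(perBand[[bn]], windowS, stepS)
      out[[bn]] <- lapply(seq_len(nEpochs(eps)), function(i)
        bandDTF(fitOne(epochData(eps, i)), bands[[bn]], dfHz = dfHz,
                epochIndex = i))
    }
  } else {
    eps <- slidingWindows(rec, windowS, stepS)
    models <- lapply(seq_len(nEpochs(eps)), function(i)
      fitOne(epochData(eps, i)))
    for (bn in names(bands))
      out[[bn]] <- lapply(seq_along(models), function(i)
        bandDTF(models[[i]], bands[[bn]], dfHz = dfHz, epochIndex = i))
  }
  out
}

metricRows <- function(stage, band, epoch, net, regionMap) {
  mm <- networkMetrics(net)
  glob <- data.frame(
    stage = stage, band = band, epoch = epoch,
    metric = c("clustering", "path_length", "efficiency",
               "reachable_fraction"),
    node = NA_character_,
    value = c(mm$cMean, mm$lMean, mm$eGlobal, mm$reachableFraction),
    stringsAsFactors = FALSE)
  labs <- names(mm$cf)
  pernode <- data.frame(
    stage = stage, band = band, epoch = epoch,
    metric = rep(c("out_degree", "in_degree", "causal_flow"),
                 each = length(labs)),
    node = rep(labs, 3),
    value = c(as.numeric(mm$out), as.numeric(mm$in_), as.numeric(mm$cf)),
    stringsAsFactors = FALSE)
  rbind(glob, pernode)
}

#' Run the end-to-end directed-brain-network pipeline
#'
#' Stage order: (synthesize/load) -> re-reference -> CSD -> band loop ->
#' epoch loop -> MVAR/DTF -> sparsity traversal and thresholding ->
#' metrics -> stage statistics. Deterministic given the configuration
#' (synthetic sessions carry their own seed).
#'
#' @param config a [PipelineConfig()].
#' @return List with elements `traversal` (band -> data.frame of mean GCE by
#'   sparsity and stage), `selectedSparsity` (band -> GCE-argmax S of the
#'   pooled traversal), `metrics` (tidy data.frame), `stats` (data.frame or
#'   NULL), `interregion` (band -> stage -> region x region edge-count
#'   matrix of the stage-mean connectivity thresholded at the fixed
#'   sparsity), and `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  session <- config$session
  if (is.null(session))
    session <- simulateSession(config$sessionConfig, config$graph)
  stages <- names(session)
  fs <- samplingRate(session[[1]])
  for (b in config$bands)
    if (b@highHz > fs / 2)
      stop(sprintf("band %s (%g-%g Hz) exceeds the Nyquist rate %g Hz",
                   b@name, b@lowHz, b@highHz, fs / 2))
  montage <- config$montage
  regionMap <- config$regionMap
  if (is.null(regionMap))
    regionMap <- defaultRegionMap(channelLabels(session[[1]]))

  # per-stage conditioning chain
  for (s in stages) {
    rec <- session[[s]]
    if (!is.null(config$referenceLabels))
      rec <- rereference(rec, config$referenceLabels)
    if (config$csd) {
      if (is.null(montage)) stop("CSD requested but no montage configured")
      rec <- computeCSD(rec, montage, config$splineParams)
    }
    session[[s]] <- rec
  }

  conns <- list()     # conns[[band]][[stage]] = list of per-epoch matrices
  for (s in stages) {
    ec <- epochConnectivity(
      session[[s]], bands = config$bands, windowS = config$windowS,
      stepS = config$stepS, order = config$order, dfHz = config$dfHz,
      orderRange = if (config$orderSelection) config$orderRange else NULL,
      fitOnBand = config$fitOnBand)
    for (bn in names(ec)) conns[[bn]][[s]] <- ec[[bn]]
  }

  traversal <- list()
  selectedSparsity <- list()
  metricTabs <- list()
  interregion <- list()
  for (bn in names(conns)) {
    flat <- unlist(conns[[bn]], recursive = FALSE, use.names = FALSE)
    stageOf <- rep(stages, vapply(conns[[bn]], length, integer(1)))
    traversal[[bn]] <- sparsityTraversal(flat, config$sparsityGrid,
                                         stages = stageOf)
    pooled <- rowMeans(as.matrix(traversal[[bn]][, -1, drop = FALSE]))
    names(pooled) <- as.character(traversal[[bn]]$sparsity)
    selectedSparsity[[bn]] <- selectOptimalSparsity(pooled)
    for (s in stages) {
      cl <- conns[[bn]][[s]]
      for (i in seq_along(cl)) {
        S <- if (config$perWindowSparsity) {
          gce <- vapply(config$sparsityGrid, function(S0)
            globalCostEfficiency(cl[[i]], S0), numeric(1))
          names(gce) <- as.character(config$sparsityGrid)
          selectOptimalSparsity(gce)
        } else config$sparsity
        net <- binarizeTopFraction(cl[[i]], S)
        metricTabs[[length(metricTabs) + 1]] <-
          metricRows(s, bn, i, net, regionMap)
      }
      # stage-level inter-region flow from the stage-mean connectivity
      meanConn <- ConnectivityMatrix(
        Reduce(`+`, lapply(cl, connectivityValues)) / length(cl),
        band = bandOf(cl[[1]]), labels = channelLabels(cl[[1]]))
      interregion[[bn]][[s]] <- interregionFlow(
        binarizeTopFraction(meanConn, config$sparsity), regionMap)
    }
  }
  metrics <- do.call(rbind, metricTabs)
  rownames(metrics) <- NULL

  statsTab <- NULL
  if (config$runStats && length(stages) > 1 &&
      config$baselineStage %in% stages)
    statsTab <- stageContrasts(
      metrics, baselineStage = config$baselineStage, alpha = config$alpha,
      contrastStage = config$contrastStage,
      observation = config$observation, blockS = config$blockS,
      stepS = config$stepS)

  manifest <- list(
    package = "dtfnet",
    version = as.character(utils::packageVersion("dtfnet")),
    stages = stages,
    nChannels = nChannels(session[[1]]),
    fs = samplingRate(session[[1]]),
    bands = vapply(config$bands, function(b)
      sprintf("%s:%g-%g", b@name, b@lowHz, b@highHz), character(1)),
    windowS = config$windowS, stepS = config$stepS,
    order = config$order, orderSelection = config$orderSelection,
    fitOnBand = config$fitOnBand, dfHz = config$dfHz, csd = config$csd,
    sparsity = config$sparsity,
    perWindowSparsity = config$perWindowSparsity,
    sparsityGrid = config$sparsityGrid,
    baselineStage = config$baselineStage,
    contrastStage = config$contrastStage, alpha = config$alpha,
    observation = config$observation, blockS = config$blockS,
    seed = if (!is.null(config$sessionConfig)) config$sessionConfig@seed
           else NA,
    inputChecksum = vapply(session, function(r)
      sum(signalData(r)^2), numeric(1)))

  list(traversal = traversal, selectedSparsity = selectedSparsity,
       metrics = metrics, stats = statsTab, interregion = interregion,
       manifest = manifest)
}

#' Write a pipeline result bundle to disk
#'
#' Emits one CSV per traversal band (`traversal_<band>.csv`), the tidy
#' metric table (`metrics.csv`), the statistics table (`stats.csv`, when
#' present) and the manifest (`manifest.json`).
#'
#' @param result the list returned by [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeResultBundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (bn in names(result$traversal))
    utils::write.csv(result$traversal[[bn]],
                     file.path(dir, paste0("traversal_", bn, ".csv")),
                     row.names = FALSE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(result$stats))
    utils::write.csv(result$stats, file.path(dir, "stats.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
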