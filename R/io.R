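## Plain-text recording archives: a TSV data table (samples x channels)
## plus a JSON sidecar holding sampling rate, labels and unit; synthetic
## sessions additionally carry their ground-truth graph and configuration
## so tests can reload the oracle.

#' Write / read a recording as a text array archive
#'
#' `writeRecordingArchive` writes `<base>.tsv` (samples x channels, header =
#' labels) and `<base>.json` (fs, labels, unit). `readRecordingArchive`
#' reads the pair back.
#'
#' @param rec a [Recording-class].
#' @param base path prefix (without extension).
#' @return `writeRecordingArchive` returns `base` invisibly;
#'   `readRecordingArchive` returns a [Recording-class].
#' @export
writeRecordingArchive <- function(rec, base) {
  X <- t(signalData(rec))
  colnames(X) <- channelLabels(rec)
  utils::write.table(X, paste0(base, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(fs = samplingRate(rec), labels = channelLabels(rec),
         unit = unitTag(rec)),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname writeRecordingArchive
#' @export
readRecordingArchive <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("archive sidecar lacks the fs field")
  X <- as.matrix(utils::read.table(paste0(base, ".tsv"), sep = "\t",
                                   header = TRUE, check.names = FALSE))
  labels <- as.character(meta$labels)
  if (!setequal(colnames(X), labels))
    stop("archive data columns do not match sidecar labels: missing ",
         paste(setdiff(labels, colnames(X)), collapse = ", "))
  Recording(t(X[, labels, drop = FALSE]), fs = meta$fs, labels = labels,
            unit = meta$unit)
}

#' Write / read a connectivity matrix as CSV
#'
#' Labels form the header; entry `[i, j]` is the flow j -> i.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param path CSV path.
#' @param band the [RhythmBand-class] to attach on read.
#' @return `writeConnectivityCSV` returns `path` invisibly;
#'   `readConnectivityCSV` returns a [ConnectivityMatrix-class].
#' @export
writeConnectivityCSV <- function(conn, path) {
  V <- connectivityValues(conn)
  utils::write.csv(as.data.frame(V), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConnectivityCSV
#' @export
readConnectivityCSV <- function(path, band) {
  V <- as.matrix(utils::read.csv(path, check.names = FALSE))
  ConnectivityMatrix(V, band = band, labels = colnames(V))
}

#' Write a directed network as an edge list
#'
#' One `src dst` label pair per line, whitespace-separated.
#'
#' @param net a [DirectedNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  A <- adjacencyMatrix(net)
  labs <- channelLabels(net)
  idx <- which(A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(paste(labs[idx[, 1]], labs[idx[, 2]]), path)
  invisible(path)
}

graphToList <- function(graph) {
  list(nNodes = graph@nNodes,
       edges = unname(apply(graph@edges, 1, as.list)),
       strengths = graph@strengths, groups = graph@groups,
       order = graph@order, noiseSd = graph@noiseSd,
       selfCoeffs = graph@selfCoeffs)
}

graphFromList <- function(x) {
  edges <- if (length(x$edges))
    do.call(rbind, lapply(x$edges, unlist)) else NULL
  strengths <- if (is.null(x$strengths)) numeric() else unlist(x$strengths)
  groups <- if (is.null(x$groups)) "" else unlist(x$groups)
  GroundTruthGraph(unlist(x$nNodes), edges = edges, strengths = strengths,
                   groups = groups, order = unlist(x$order),
                   noiseSd = unlist(x$noiseSd),
                   selfCoeffs = unlist(x$selfCoeffs))
}

#' Write / read a synthetic session with its ground-truth sidecar
#'
#' Writes one recording archive per stage under `dir` plus `session.json`
#' holding the [SessionConfig-class] and [GroundTruthGraph-class] so the
#' generating oracle can be reloaded alongside the data.
#'
#' @param session named list stage -> [Recording-class] (from
#'   [simulateSession()]).
#' @param config the [SessionConfig-class] used.
#' @param graph the [GroundTruthGraph-class] used.
#' @param dir output directory (created if needed).
#' @return `writeSession` returns `dir` invisibly; `readSession` returns a
#'   list with `session`, `config` and `graph`.
#' @export
writeSession <- function(session, config, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in names(session))
    writeRecordingArchive(session[[stage]], file.path(dir, stage))
  meta <- list(
    stages = config@stages, stageDurationS = config@stageDurationS,
    fs = config@fs, labels = channelLabels(config@montage),
    positions = unname(apply(positionMatrix(config@montage), 1, as.list)),
    stageModulation = lapply(config@stageModulation, as.list),
    mixingSpread = config@mixingSpread, seed = config@seed,
    graph = graphToList(graph))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = FALSE)
  pos <- do.call(rbind, lapply(meta$positions, function(p) unlist(p)))
  montage <- Montage(vapply(meta$labels, identity, character(1)), pos)
  mod <- lapply(meta$stageModulation, function(m) unlist(m))
  config <- SessionConfig(
    montage, stages = vapply(meta$stages, identity, character(1)),
    stageDurationS = meta$stageDurationS, fs = meta$fs,
    stageModulation = mod, mixingSpread = meta$mixingSpread,
    seed = meta$seed)
  graph <- graphFromList(meta$graph)
  session <- lapply(stats::setNames(config@stages, config@stages),
                    function(s) readRecordingArchive(file.path(dir, s)))
  list(session = session, config = config, graph = graph)
}
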