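#' Accessors for dtfnet classes
#'
#' Small generic accessors used across the package: channel/node counts,
#' labels, sampling rates, the underlying matrices, and epoch access.
#'
#' @param x an object of one of the dtfnet classes.
#' @param i epoch index (for `epochData`).
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("unitTag", function(x) standardGeneric("unitTag"))
#' @rdname accessors
#' @export
setGeneric("positionMatrix", function(x) standardGeneric("positionMatrix"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x, i) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("connectivityValues",
           function(x) standardGeneric("connectivityValues"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("sparsityUsed", function(x) standardGeneric("sparsityUsed"))
#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @rdname accessors
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))
#' @rdname accessors
#' @export
setGeneric("coefMatrices", function(x) standardGeneric("coefMatrices"))
#' @rdname accessors
#' @export
setGeneric("noiseCovariance", function(x) standardGeneric("noiseCovariance"))

#' @rdname accessors
setMethod("nChannels", "Recording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "Montage", function(x) length(x@labels))
#' @rdname accessors
setMethod("channelLabels", "Recording", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "Montage", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "ConnectivityMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "DirectedNetwork", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "MVARModel", function(x) x@labels)
#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "MVARModel", function(x) x@fs)
#' @rdname accessors
setMethod("signalData", "Recording", function(x) x@data)
#' @rdname accessors
setMethod("unitTag", "Recording", function(x) x@unit)
#' @rdname accessors
setMethod("positionMatrix", "Montage", function(x) x@positions)
#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(x) length(x@epochs))
#' @rdname accessors
setMethod("epochData", "EpochSet", function(x, i) x@epochs[[i]])
#' @rdname accessors
setMethod("connectivityValues", "ConnectivityMatrix", function(x) x@values)
#' @rdname accessors
setMethod("adjacencyMatrix", "DirectedNetwork", function(x) x@adjacency)
#' @rdname accessors
setMethod("sparsityUsed", "DirectedNetwork", function(x) x@sparsity)
#' @rdname accessors
setMethod("bandOf", "ConnectivityMatrix", function(x) x@band)
#' @rdname accessors
setMethod("modelOrder", "MVARModel", function(x) x@order)
#' @rdname accessors
setMethod("coefMatrices", "MVARModel", function(x) x@coeffs)
#' @rdname accessors
setMethod("noiseCovariance", "MVARModel", function(x) x@noiseCov)

#' Pairwise great-circle angles between montage electrodes
#'
#' @param montage a [Montage-class].
#' @return N x N matrix of angular distances in radians (zero diagonal).
#' @export
angularDistances <- function(montage) {
  ct <- tcrossprod(positionMatrix(montage))
  ct[ct > 1] <- 1
  ct[ct < -1] <- -1
  th <- acos(ct)
  diag(th) <- 0
  th
}

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage with %d electrodes: %s ... %s\n",
              length(object@labels), object@labels[1],
              object@labels[length(object@labels)]))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz [%s] (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs, object@unit,
              ncol(object@data) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  n <- length(object@epochs)
  cat(sprintf("EpochSet: %d epochs of %g s (step %g s), %d channels @ %g Hz\n",
              n, object@windowS, object@stepS, length(object@labels),
              object@fs))
})

setMethod("show", "RhythmBand", function(object) {
  cat(sprintf("RhythmBand %s: %g-%g Hz\n", object@name, object@lowHz,
              object@highHz))
})

setMethod("show", "GroundTruthGraph", function(object) {
  cat(sprintf(
    "GroundTruthGraph: %d nodes, %d directed couplings, order %d (rho = %.3f)\n",
    object@nNodes, nrow(object@edges), object@order, spectralRadius(object)))
})

setMethod("show", "SessionConfig", function(object) {
  cat(sprintf(
    "SessionConfig: %d stages (%s) x %g s @ %g Hz, %d channels, spread %g rad\n",
    length(object@stages), paste(object@stages, collapse = " "),
    object@stageDurationS, object@fs, nChannels(object@montage),
    object@mixingSpread))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s band): %d x %d, epoch %s\n",
              object@band@name, nrow(object@values), ncol(object@values),
              ifelse(is.na(object@epochIndex), "-", object@epochIndex)))
})

setMethod("show", "DirectedNetwork", function(object) {
  cat(sprintf("DirectedNetwork: %d nodes, %d edges%s\n",
              nrow(object@adjacency), sum(object@adjacency),
              ifelse(is.na(object@sparsity), "",
                     sprintf(" (S = %g)", object@sparsity))))
})

setMethod("show", "MVARModel", function(object) {
  cat(sprintf("MVARModel: order %d, %d channels @ %g Hz\n",
              object@order, nrow(object@noiseCov), object@fs))
})
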