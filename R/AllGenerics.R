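#' Accessors for spikeDTW classes
#'
#' \code{dtwValues} returns the raw distance matrix of a
#' \linkS4class{DTWMatrix}; \code{dtwUnits} its units tag (\code{"ms"} or
#' \code{"V"}); \code{dtwMeta} its stratification metadata;
#' \code{exclusionLog} the units excluded before computation;
#' \code{unitLabels} the retained unit labels. \code{spikeTimes} returns the
#' spike-time vector of a \linkS4class{SpikeTrain}; \code{voltages} the
#' sample vector of an \linkS4class{LFPSegment}; \code{trials} the trial
#' list of a \linkS4class{SessionBundle}; \code{geometry} its electrode
#' geometry; \code{groundTruth} its generator ground truth.
#'
#' @param x the object.
#' @return The slot contents described above.
#' @name accessors
#' @aliases dtwValues dtwUnits dtwMeta exclusionLog unitLabels spikeTimes
#'   voltages trials geometry groundTruth
NULL

#' @rdname accessors
#' @export
setGeneric("dtwValues", function(x) standardGeneric("dtwValues"))
#' @rdname accessors
#' @export
setGeneric("dtwUnits", function(x) standardGeneric("dtwUnits"))
#' @rdname accessors
#' @export
setGeneric("dtwMeta", function(x) standardGeneric("dtwMeta"))
#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))
#' @rdname accessors
#' @export
setGeneric("unitLabels", function(x) standardGeneric("unitLabels"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))
#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
setMethod("dtwValues", "DTWMatrix", function(x) x@values)
#' @rdname accessors
setMethod("dtwUnits", "DTWMatrix", function(x) x@units)
#' @rdname accessors
setMethod("dtwMeta", "DTWMatrix", function(x) x@meta)
#' @rdname accessors
setMethod("exclusionLog", "DTWMatrix", function(x) x@exclusions)
#' @rdname accessors
setMethod("unitLabels", "DTWMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
#' @rdname accessors
setMethod("voltages", "LFPSegment", function(x) x@voltages)
#' @rdname accessors
setMethod("trials", "SessionBundle", function(x) x@trials)
#' @rdname accessors
setMethod("geometry", "SessionBundle", function(x) x@geometry)
#' @rdname accessors
setMethod("groundTruth", "SessionBundle", function(x) x@groundTruth)

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain %s (electrode %s): %d spikes in [0, %d] ms\n",
              object@neuronId, object@electrodeId, length(object@times),
              SEGMENT_MS))
})

setMethod("show", "LFPSegment", function(object) {
  cat(sprintf("LFPSegment electrode %s: %d samples @ %g Hz\n",
              object@electrodeId, length(object@voltages), object@sampleRate))
})

setMethod("show", "DTWMatrix", function(object) {
  cat(sprintf("DTWMatrix: %d units, units = %s, %d excluded\n",
              nrow(object@values), object@units, nrow(object@exclusions)))
  if (length(object@meta)) {
    keys <- vapply(object@meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta: ", paste(names(keys), keys, sep = "=", collapse = " "), "\n",
        sep = "")
  }
})

setMethod("show", "SessionBundle", function(object) {
  nNeuron <- length(object@geometry@neuronMap)
  cat(sprintf(
    "SessionBundle %s/%s/%s: %d trials, %d neurons on %d electrodes\n",
    object@studyId, object@ratId, object@sessionId, length(object@trials),
    nNeuron, nrow(object@geometry@electrodes)))
})

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(
    paste0("SyntheticDesign: %d rats x %d sessions x %d trials; ",
           "%d electrodes x %d neurons, %d clusters\n"),
    object@nRats, object@sessionsPerRat, object@trialsPerSession,
    object@nElectrodes, object@neuronsPerElectrode, object@nClusters))
  cat(sprintf(
    paste0("  baseRate=%g Hz syncCopyProb=%g jitterSd=%g ms ",
           "effectTiming=%g effectCorrect=%g seed=%d\n"),
    object@baseRate, object@syncCopyProb, object@jitterSd,
    object@effectTiming, object@effectCorrect, object@seed))
})
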