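#' @import methods
#' @importFrom stats median cor sd quantile rnorm rpois runif rbinom
#'   shapiro.test kruskal.test ks.test t.test aov phyper optimize
#'   qbinom rlnorm dbinom setNames
#' @importFrom utils read.csv write.csv head
#' @useDynLib spikeDTW, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SEGMENT_MS <- 2000       # each timing segment spans [0, 2000] ms
GRID_UNIT_MM <- 0.25     # electrode grid spacing, mm per grid unit
TIMINGS <- c("before", "after")

#' SpikeTrain: spike times of one neuron in one trial segment
#'
#' Ordered action-potential times (ms, within the 2 s segment) of a single
#' neuron, tagged with the neuron and electrode identity.
#'
#' @slot neuronId character(1) neuron label.
#' @slot electrodeId character(1) electrode label.
#' @slot times numeric, sorted ascending, all in [0, 2000] ms; may be empty.
#' @export
setClass("SpikeTrain",
  representation(neuronId = "character", electrodeId = "character",
                 times = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@neuronId) != 1L) msg <- c(msg, "neuronId must be length 1")
    if (length(object@electrodeId) != 1L) msg <- c(msg, "electrodeId must be length 1")
    if (is.unsorted(object@times)) msg <- c(msg, "spike times must be sorted ascending")
    if (length(object@times) && (min(object@times) < 0 || max(object@times) > SEGMENT_MS))
      msg <- c(msg, sprintf("spike times must lie in [0, %d] ms", SEGMENT_MS))
    if (length(msg)) msg else TRUE
  })

#' LFPSegment: one electrode's voltage trace in one trial segment
#'
#' Uniformly sampled local field potential (V) for one electrode.
#'
#' @slot electrodeId character(1) electrode label.
#' @slot sampleRate numeric(1) sampling rate, Hz.
#' @slot voltages numeric, >= 2 finite samples, V.
#' @export
setClass("LFPSegment",
  representation(electrodeId = "character", sampleRate = "numeric",
                 voltages = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@electrodeId) != 1L) msg <- c(msg, "electrodeId must be length 1")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a positive scalar")
    if (length(object@voltages) < 2L) msg <- c(msg, "LFP segment needs >= 2 samples")
    if (length(object@voltages) && !all(is.finite(object@voltages)))
      msg <- c(msg, "LFP voltages must be finite")
    if (length(msg)) msg else TRUE
  })

#' DTWMatrix: pairwise DTW dissimilarities over the units of one segment
#'
#' Symmetric matrix of pairwise dynamic-time-warping distances, with unit
#' labels on both dimensions, a units tag (\code{"ms"} for spike trains,
#' \code{"V"} for LFPs), the stratification metadata of the segment it came
#' from, and the exclusion log of units dropped before computation.
#'
#' @slot values numeric matrix, symmetric, zero diagonal, nonnegative, finite.
#' @slot units character(1), \code{"ms"} or \code{"V"}.
#' @slot meta list of stratification keys (study/rat/session/trial/timing/
#'   correctness), possibly empty.
#' @slot exclusions data.frame with columns \code{unit}, \code{reason} for
#'   units excluded before the matrix was formed.
#' @export
setClass("DTWMatrix",
  representation(values = "matrix", units = "character", meta = "list",
                 exclusions = "data.frame"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (is.null(rownames(v)) || is.null(colnames(v)) ||
        !identical(rownames(v), colnames(v)))
      msg <- c(msg, "matrix must carry identical row/column unit labels")
    if (!all(is.finite(v))) msg <- c(msg, "entries must be finite")
    else {
      if (any(abs(v - t(v)) > 1e-8)) msg <- c(msg, "matrix must be symmetric")
      if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
      if (any(v < 0)) msg <- c(msg, "entries must be nonnegative")
    }
    if (!object@units %in% c("ms", "V"))
      msg <- c(msg, "units must be 'ms' or 'V'")
    if (length(msg)) msg else TRUE
  })

#' ElectrodeGeometry: electrode grid coordinates and neuron placement
#'
#' Electrodes sit on an integer grid with physical spacing of 0.25 mm per
#' grid unit; each neuron is assigned to one electrode.
#'
#' @slot electrodes data.frame with columns \code{electrode_id},
#'   \code{grid_x}, \code{grid_y} (integer grid coordinates).
#' @slot neuronMap named character vector, neuron_id -> electrode_id.
#' @export
setClass("ElectrodeGeometry",
  representation(electrodes = "data.frame", neuronMap = "character"),
  validity = function(object) {
    msg <- character()
    e <- object@electrodes
    if (!all(c("electrode_id", "grid_x", "grid_y") %in% names(e)))
      msg <- c(msg, "electrodes needs columns electrode_id, grid_x, grid_y")
    else if (anyDuplicated(e$electrode_id))
      msg <- c(msg, "electrode ids must be unique")
    if (length(object@neuronMap)) {
      if (is.null(names(object@neuronMap)))
        msg <- c(msg, "neuronMap must be named by neuron_id")
      bad <- setdiff(unname(object@neuronMap), e$electrode_id)
      if (length(bad))
        msg <- c(msg, paste0("neuron mapped to unknown electrode: ",
                             paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' TrialRecording: one T-maze traversal
#'
#' Holds the correctness flag and the two timing segments (2 s before and
#' 2 s after the rat leaves the T-intersection), each with its spike trains
#' and LFP traces.
#'
#' @slot trialIndex integer(1).
#' @slot correctness logical(1), TRUE if the rat chose the rewarded arm.
#' @slot segments named list with elements \code{before} and \code{after};
#'   each a list with \code{spikes} (list of SpikeTrain) and \code{lfp}
#'   (list of LFPSegment).
#' @export
setClass("TrialRecording",
  representation(trialIndex = "integer", correctness = "logical",
                 segments = "list"),
  validity = function(object) {
    msg <- character()
    if (!identical(sort(names(object@segments)), sort(TIMINGS)))
      msg <- c(msg, "segments must be named 'before' and 'after'")
    if (length(object@correctness) != 1L) msg <- c(msg, "correctness must be length 1")
    if (length(msg)) msg else TRUE
  })

#' SessionBundle: all trials recorded for one rat on one day
#'
#' @slot studyId,ratId,sessionId character(1) labels.
#' @slot trials list of \linkS4class{TrialRecording}.
#' @slot geometry an \linkS4class{ElectrodeGeometry}.
#' @slot groundTruth list; for synthetic sessions, the cluster assignment per
#'   neuron and the injected effect sizes (empty for real data).
#' @export
setClass("SessionBundle",
  representation(studyId = "character", ratId = "character",
                 sessionId = "character", trials = "list",
                 geometry = "ElectrodeGeometry", groundTruth = "list"),
  validity = function(object) {
    msg <- character()
    for (tr in object@trials) {
      for (tm in names(tr@segments)) {
        for (st in tr@segments[[tm]]$spikes) {
          if (!st@neuronId %in% names(object@geometry@neuronMap))
            msg <- c(msg, paste0("neuron ", st@neuronId,
                                 " missing from geometry neuron map"))
        }
      }
    }
    if (length(msg)) unique(msg) else TRUE
  })

#' SyntheticDesign: parameters of the synthetic session generator
#'
#' See \code{\link{syntheticDesign}} for the constructor, defaults and the
#' meaning of each parameter.
#'
#' @slot nRats,sessionsPerRat,trialsPerSession,nElectrodes,neuronsPerElectrode,nClusters integer counts (>= 1).
#' @slot electrodeSpacing numeric(1), grid unit in mm (fixed 0.25).
#' @slot baseRate numeric(1), background firing rate, events/s.
#' @slot syncCopyProb numeric(1) in [0,1], probability a neuron copies each
#'   parent (cluster) spike.
#' @slot jitterSd numeric(1), Gaussian jitter of copied spikes, ms.
#' @slot lfpSampleRate,lfpOscFreq numeric(1), Hz.
#' @slot lfpAmplitude,lfpNoiseSd numeric(1), V.
#' @slot effectTiming,effectCorrect numeric(1), multiplicative shifts of
#'   syncCopyProb in the after segment / on correct trials.
#' @slot sessionDriftSd numeric(1), sd of the per-session log-normal
#'   perturbation of baseRate.
#' @slot pCorrect numeric(1), Bernoulli probability a trial is correct.
#' @slot seed integer(1).
#' @export
setClass("SyntheticDesign",
  representation(nRats = "integer", sessionsPerRat = "integer",
                 trialsPerSession = "integer", nElectrodes = "integer",
                 neuronsPerElectrode = "integer", nClusters = "integer",
                 electrodeSpacing = "numeric", baseRate = "numeric",
                 syncCopyProb = "numeric", jitterSd = "numeric",
                 lfpSampleRate = "numeric", lfpOscFreq = "numeric",
                 lfpAmplitude = "numeric", lfpNoiseSd = "numeric",
                 effectTiming = "numeric", effectCorrect = "numeric",
                 sessionDriftSd = "numeric", pCorrect = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    counts <- c(nRats = object@nRats, sessionsPerRat = object@sessionsPerRat,
                trialsPerSession = object@trialsPerSession,
                nElectrodes = object@nElectrodes,
                neuronsPerElectrode = object@neuronsPerElectrode,
                nClusters = object@nClusters)
    bad <- names(counts)[counts < 1L]
    if (length(bad)) msg <- c(msg, paste0("counts must be >= 1: ",
                                          paste(bad, collapse = ", ")))
    if (object@nClusters > object@nElectrodes * object@neuronsPerElectrode)
      msg <- c(msg, "nClusters cannot exceed the number of neurons")
    for (p in c("syncCopyProb", "pCorrect")) {
      v <- slot(object, p)
      if (v < 0 || v > 1) msg <- c(msg, paste0(p, " must lie in [0, 1]"))
    }
    for (p in c("baseRate", "lfpSampleRate", "lfpOscFreq", "lfpAmplitude",
                "lfpNoiseSd")) {
      if (slot(object, p) <= 0) msg <- c(msg, paste0(p, " must be > 0"))
    }
    for (p in c("jitterSd", "sessionDriftSd", "effectTiming", "effectCorrect")) {
      if (slot(object, p) < 0) msg <- c(msg, paste0(p, " must be >= 0"))
    }
    if (object@electrodeSpacing != GRID_UNIT_MM)
      msg <- c(msg, "electrodeSpacing is fixed at 0.25 mm")
    if (length(msg)) msg else TRUE
  })
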