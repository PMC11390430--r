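# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a synthetic recording design
#'
#' Parameters of the synthetic T-maze session generator. Defaults describe a
#' modest multi-electrode recording: a 2 x 2 electrode grid (0.25 mm
#' spacing) carrying 16 neurons in 2 synchrony assemblies, theta-band
#' (8 Hz) field potentials sampled at 1 kHz with ~100 uV amplitude, firing
#' at 5 events/s, 20 T-maze trials per session, and injected effects
#' (timing effect 1.0 — synchrony doubles after the decision — and
#' correctness effect 0.3, both multiplicative shifts of the synchrony
#' copy probability). See the methods vignette for the rationale behind
#' each default.
#'
#' @param nRats,sessionsPerRat,trialsPerSession hierarchy counts.
#' @param nElectrodes,neuronsPerElectrode recording geometry counts; the
#'   electrode grid is the nearest-square rectangular array.
#' @param nClusters ground-truth number of synchrony clusters (c).
#' @param baseRate background Poisson firing rate, events/s; also the rate
#'   of each cluster's parent process.
#' @param syncCopyProb probability in [0, 1] that a neuron copies each spike
#'   of its cluster parent (the synchrony knob).
#' @param jitterSd Gaussian jitter of copied spikes, ms.
#' @param lfpSampleRate,lfpOscFreq LFP sampling rate and shared oscillation
#'   frequency, Hz.
#' @param lfpAmplitude,lfpNoiseSd LFP oscillation amplitude and white-noise
#'   sd, V.
#' @param effectTiming,effectCorrect multiplicative increase of
#'   \code{syncCopyProb} in the after segment / on correct trials
#'   (0 = no effect); the effective probability is capped at 1.
#' @param sessionDriftSd sd of the log-normal per-session perturbation of
#'   \code{baseRate} (resting-state drift).
#' @param pCorrect probability a trial is correct.
#' @param seed integer seed; generation is fully deterministic given the
#'   design.
#' @return A \linkS4class{SyntheticDesign}.
#' @export
syntheticDesign <- function(nRats = 3, sessionsPerRat = 3,
                            trialsPerSession = 20, nElectrodes = 4,
                            neuronsPerElectrode = 4, nClusters = 2,
                            baseRate = 5, syncCopyProb = 0.3, jitterSd = 5,
                            lfpSampleRate = 1000, lfpOscFreq = 8,
                            lfpAmplitude = 1e-4, lfpNoiseSd = 5e-5,
                            effectTiming = 1.0, effectCorrect = 0.3,
                            sessionDriftSd = 0.1, pCorrect = 0.75,
                            seed = 1L) {
  new("SyntheticDesign", nRats = as.integer(nRats),
      sessionsPerRat = as.integer(sessionsPerRat),
      trialsPerSession = as.integer(trialsPerSession),
      nElectrodes = as.integer(nElectrodes),
      neuronsPerElectrode = as.integer(neuronsPerElectrode),
      nClusters = as.integer(nClusters), electrodeSpacing = GRID_UNIT_MM,
      baseRate = baseRate, syncCopyProb = syncCopyProb, jitterSd = jitterSd,
      lfpSampleRate = lfpSampleRate, lfpOscFreq = lfpOscFreq,
      lfpAmplitude = lfpAmplitude, lfpNoiseSd = lfpNoiseSd,
      effectTiming = effectTiming, effectCorrect = effectCorrect,
      sessionDriftSd = sessionDriftSd, pCorrect = pCorrect,
      seed = as.integer(seed))
}

# Rectangular electrode grid: rows = nearest square, electrodes filled
# row-major. Physical distance = Euclidean grid distance x 0.25 mm.
makeGeometry <- function(nElectrodes, neuronsPerElectrode) {
  ncols <- ceiling(sqrt(nElectrodes))
  idx <- seq_len(nElectrodes) - 1L
  eid <- sprintf("e%02d", seq_len(nElectrodes))
  electrodes <- data.frame(electrode_id = eid,
                           grid_x = idx %% ncols,
                           grid_y = idx %/% ncols,
                           stringsAsFactors = FALSE)
  nNeuron <- nElectrodes * neuronsPerElectrode
  nid <- sprintf("n%03d", seq_len(nNeuron))
  neuronMap <- rep(eid, each = neuronsPerElectrode)
  names(neuronMap) <- nid
  new("ElectrodeGeometry", electrodes = electrodes, neuronMap = neuronMap)
}

poissonTimes <- function(rate, spanMs = SEGMENT_MS) {
  n <- rpois(1L, rate * spanMs / 1000)
  sort(runif(n, 0, spanMs))
}

generateSegment <- function(design, geom, clusters, s, rate) {
  nid <- names(geom@neuronMap)
  # common-parent ("mother") Poisson process per cluster
  parents <- lapply(seq_len(design@nClusters), function(cl)
    poissonTimes(rate))
  spikes <- lapply(nid, function(id) {
    parent <- parents[[clusters[[id]]]]
    copied <- parent[runif(length(parent)) < s]
    if (length(copied)) {
      copied <- copied + rnorm(length(copied), 0, design@jitterSd)
      copied <- pmin(pmax(copied, 0), SEGMENT_MS)  # clip, preserving count
    }
    background <- poissonTimes(rate * (1 - s))
    new("SpikeTrain", neuronId = id, electrodeId = unname(geom@neuronMap[id]),
        times = sort(c(copied, background)))
  })
  # cluster-shared sinusoid + white noise; electrodes average the phases of
  # the clusters their neurons belong to
  nSamples <- round(design@lfpSampleRate * SEGMENT_MS / 1000)
  tSec <- (seq_len(nSamples) - 1L) / design@lfpSampleRate
  phase <- runif(design@nClusters, 0, 2 * pi)
  lfp <- lapply(geom@electrodes$electrode_id, function(eid) {
    cls <- unique(clusters[names(geom@neuronMap)[geom@neuronMap == eid]])
    osc <- rowMeans(sapply(cls, function(cl)
      sin(2 * pi * design@lfpOscFreq * tSec + phase[cl])))
    v <- design@lfpAmplitude * osc + rnorm(nSamples, 0, design@lfpNoiseSd)
    new("LFPSegment", electrodeId = eid, sampleRate = design@lfpSampleRate,
        voltages = v)
  })
  list(spikes = spikes, lfp = lfp)
}

#' Generate synthetic T-maze session bundles
#'
#' Simulates the hierarchy studies -> rats -> sessions -> trials with known
#' ground truth. Neurons are partitioned into \code{nClusters} synchrony
#' clusters (contiguously over electrodes, so neurons sharing an electrode
#' tend to share a cluster). Within a cluster, each 2 s segment draws a
#' common parent Poisson process at \code{baseRate}; every neuron copies
#' each parent spike with probability \code{syncCopyProb} (Gaussian jitter
#' \code{jitterSd} ms, clipped to the segment) and adds an independent
#' Poisson background at rate \code{(1 - syncCopyProb) * baseRate}, so each
#' neuron fires at \code{baseRate} regardless of the synchrony level and
#' the synchrony knob is orthogonal to the firing rate. LFPs are a cluster-shared sinusoid
#' at \code{lfpOscFreq} plus white noise. \code{effectTiming} scales the
#' copy probability in the after segment, \code{effectCorrect} on correct
#' trials, and \code{sessionDriftSd} perturbs the base rate per session.
#'
#' Generation is deterministic given the design (including its seed): two
#' calls with the same design return identical bundles.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @return List of \linkS4class{SessionBundle}, one per rat x session.
#' @export
generateBundles <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  validObject(design)
  geom <- makeGeometry(design@nElectrodes, design@neuronsPerElectrode)
  nid <- names(geom@neuronMap)
  clusters <- setNames(
    ceiling(seq_along(nid) * design@nClusters / length(nid)), nid)
  withSeed(design@seed, {
    bundles <- list()
    for (r in seq_len(design@nRats)) {
      ratId <- sprintf("rat%02d", r)
      for (s in seq_len(design@sessionsPerRat)) {
        sessionId <- sprintf("%s_d%02d", ratId, s)
        rate <- design@baseRate * rlnorm(1L, 0, design@sessionDriftSd)
        trialList <- lapply(seq_len(design@trialsPerSession), function(ti) {
          correct <- runif(1) < design@pCorrect
          sBase <- design@syncCopyProb *
            (1 + if (correct) design@effectCorrect else 0)
          segs <- lapply(TIMINGS, function(tm) {
            sEff <- min(1, sBase *
                          (1 + if (tm == "after") design@effectTiming else 0))
            generateSegment(design, geom, clusters, sEff, rate)
          })
          names(segs) <- TIMINGS
          new("TrialRecording", trialIndex = as.integer(ti),
              correctness = correct, segments = segs)
        })
        bundles[[length(bundles) + 1L]] <-
          new("SessionBundle", studyId = "synthetic", ratId = ratId,
              sessionId = sessionId, trials = trialList, geometry = geom,
              groundTruth = list(clusters = clusters,
                                 effectTiming = design@effectTiming,
                                 effectCorrect = design@effectCorrect,
                                 sessionRate = rate, seed = design@seed))
      }
    }
    bundles
  })
}
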