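#' Write session bundles to a plain-text directory
#'
#' Serializes bundles into five files under \code{path}:
#' \code{trials.csv} (study_id, rat_id, session_id, trial_index,
#' correctness), \code{spikes.csv} (session_id, trial_index, timing,
#' neuron_id, electrode_id, time_ms), \code{lfp.csv} (session_id,
#' trial_index, timing, electrode_id, sample_index, voltage_v),
#' \code{geometry.csv} (electrode_id, grid_x, grid_y) and
#' \code{ground_truth.json} (cluster map, effect sizes, seed, LFP sample
#' rate). All CSVs carry a header row, UTF-8, '.' decimal separator.
#'
#' @param bundles a \linkS4class{SessionBundle} or list of them (sharing one
#'   electrode geometry).
#' @param path output directory (created if absent).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readBundle}}
#' @export
writeBundle <- function(bundles, path) {
  if (is(bundles, "SessionBundle")) bundles <- list(bundles)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  trialsRows <- list(); spikeRows <- list(); lfpRows <- list()
  for (b in bundles) {
    for (tr in b@trials) {
      trialsRows[[length(trialsRows) + 1L]] <- data.frame(
        study_id = b@studyId, rat_id = b@ratId, session_id = b@sessionId,
        trial_index = tr@trialIndex, correctness = tr@correctness)
      for (tm in TIMINGS) {
        seg <- tr@segments[[tm]]
        for (st in seg$spikes) {
          if (!length(st@times)) next
          spikeRows[[length(spikeRows) + 1L]] <- data.frame(
            session_id = b@sessionId, trial_index = tr@trialIndex,
            timing = tm, neuron_id = st@neuronId,
            electrode_id = st@electrodeId, time_ms = st@times)
        }
        for (lf in seg$lfp) {
          lfpRows[[length(lfpRows) + 1L]] <- data.frame(
            session_id = b@sessionId, trial_index = tr@trialIndex,
            timing = tm, electrode_id = lf@electrodeId,
            sample_index = seq_along(lf@voltages) - 1L,
            voltage_v = lf@voltages)
        }
      }
    }
  }
  geom <- bundles[[1L]]@geometry
  write.csv(do.call(rbind, trialsRows), file.path(path, "trials.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, spikeRows), file.path(path, "spikes.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, lfpRows), file.path(path, "lfp.csv"),
            row.names = FALSE)
  write.csv(geom@electrodes, file.path(path, "geometry.csv"),
            row.names = FALSE)
  gt <- bundles[[1L]]@groundTruth
  gt$neuron_map <- as.list(geom@neuronMap)
  gt$lfp_sample_rate <- if (length(bundles[[1L]]@trials) &&
                            length(bundles[[1L]]@trials[[1L]]@segments$before$lfp))
    bundles[[1L]]@trials[[1L]]@segments$before$lfp[[1L]]@sampleRate else NA
  jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

formatError <- function(file, rows, what) {
  stop(sprintf("%s: %s (line %s)", file, what,
               paste(rows + 1L, collapse = ", ")), call. = FALSE)
}

#' Read session bundles from a plain-text directory
#'
#' Inverse of \code{\link{writeBundle}}: reads the directory format and
#' validates it. Spike times outside the 2 s segment and neurons mapped to
#' electrodes absent from \code{geometry.csv} are rejected with the file
#' name and offending line in the error message. Round trip is exact up to
#' floating-point formatting; neurons that fired no spike anywhere in a
#' session are recovered from the ground-truth neuron map.
#'
#' @param path directory written by \code{\link{writeBundle}}.
#' @return List of \linkS4class{SessionBundle}.
#' @export
readBundle <- function(path) {
  readf <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing file: ", fp, call. = FALSE)
    read.csv(fp, stringsAsFactors = FALSE)
  }
  trialsDf <- readf("trials.csv")
  spikesDf <- readf("spikes.csv")
  lfpDf <- readf("lfp.csv")
  geomDf <- readf("geometry.csv")
  gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                            simplifyVector = TRUE)

  bad <- which(spikesDf$time_ms < 0 | spikesDf$time_ms > SEGMENT_MS)
  if (length(bad))
    formatError("spikes.csv", bad, sprintf(
      "spike time outside [0, %d] ms segment", SEGMENT_MS))
  bad <- which(!spikesDf$electrode_id %in% geomDf$electrode_id)
  if (length(bad))
    formatError("spikes.csv", bad, paste0(
      "neuron ", paste(unique(spikesDf$neuron_id[bad]), collapse = ", "),
      " references electrode missing from geometry.csv"))
  bad <- which(!lfpDf$electrode_id %in% geomDf$electrode_id)
  if (length(bad))
    formatError("lfp.csv", bad, "electrode missing from geometry.csv")

  neuronMap <- unlist(gt$neuron_map)
  fromSpikes <- setNames(spikesDf$electrode_id, spikesDf$neuron_id)
  fromSpikes <- fromSpikes[!duplicated(names(fromSpikes))]
  if (is.null(neuronMap)) neuronMap <- fromSpikes
  geom <- new("ElectrodeGeometry", electrodes = geomDf, neuronMap = neuronMap)
  sampleRate <- gt$lfp_sample_rate
  if (is.null(sampleRate) || is.na(sampleRate)) sampleRate <- 1000

  gtList <- gt[setdiff(names(gt), c("neuron_map", "lfp_sample_rate"))]
  if (!is.null(gtList$clusters)) gtList$clusters <- unlist(gtList$clusters)

  bundles <- list()
  for (sid in unique(trialsDf$session_id)) {
    tdf <- trialsDf[trialsDf$session_id == sid, ]
    sdf <- spikesDf[spikesDf$session_id == sid, ]
    ldf <- lfpDf[lfpDf$session_id == sid, ]
    trialList <- lapply(seq_len(nrow(tdf)), function(i) {
      ti <- tdf$trial_index[i]
      segs <- lapply(TIMINGS, function(tm) {
        ss <- sdf[sdf$trial_index == ti & sdf$timing == tm, ]
        spikes <- lapply(names(neuronMap), function(nidOne) {
          new("SpikeTrain", neuronId = nidOne,
              electrodeId = unname(neuronMap[nidOne]),
              times = sort(ss$time_ms[ss$neuron_id == nidOne]))
        })
        ls <- ldf[ldf$trial_index == ti & ldf$timing == tm, ]
        lfp <- lapply(unique(ls$electrode_id), function(eid) {
          one <- ls[ls$electrode_id == eid, ]
          new("LFPSegment", electrodeId = eid, sampleRate = sampleRate,
              voltages = one$voltage_v[order(one$sample_index)])
        })
        list(spikes = spikes, lfp = lfp)
      })
      names(segs) <- TIMINGS
      new("TrialRecording", trialIndex = as.integer(ti),
          correctness = as.logical(tdf$correctness[i]), segments = segs)
    })
    bundles[[length(bundles) + 1L]] <-
      new("SessionBundle", studyId = tdf$study_id[1L], ratId = tdf$rat_id[1L],
          sessionId = sid, trials = trialList, geometry = geom,
          groundTruth = gtList)
  }
  bundles
}
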