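# Off-diagonal entries of a DTW matrix annotated with the physical distance
# (in 0.25 mm grid multiples) between the electrodes of each unit pair.
# Spike-train units map to electrodes through the geometry's neuron map;
# LFP units are electrodes themselves, so zero distance cannot occur.
pairEntries <- function(mat, geom) {
  labs <- unitLabels(mat)
  eid <- if (dtwUnits(mat) == "ms") {
    missing <- setdiff(labs, names(geom@neuronMap))
    if (length(missing))
      stop("units missing from geometry neuron map: ",
           paste(missing, collapse = ", "))
    unname(geom@neuronMap[labs])
  } else labs
  coords <- geom@electrodes
  ix <- match(eid, coords$electrode_id)
  gx <- coords$grid_x[ix]; gy <- coords$grid_y[ix]
  n <- length(labs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  data.frame(unit_i = labs[i], unit_j = labs[j],
             value = dtwValues(mat)[pairs],
             grid_distance = sqrt((gx[i] - gx[j])^2 + (gy[i] - gy[j])^2),
             same_electrode = eid[i] == eid[j],
             session_id = if (!is.null(dtwMeta(mat)$session_id))
               dtwMeta(mat)$session_id else NA_character_,
             stringsAsFactors = FALSE)
}

poolEntries <- function(matrices, geometry) {
  if (is(matrices, "DTWMatrix")) matrices <- list(matrices)
  do.call(rbind, lapply(matrices, pairEntries, geom = geometry))
}

#' Same- versus different-electrode distribution tests
#'
#' Pools the off-diagonal DTW matrix entries, labels each unit pair as
#' same-electrode or different-electrode via the geometry, and compares the
#' two pooled distributions with Welch's unequal-variance t-test and the
#' two-sample Kolmogorov-Smirnov test. With \code{bySession = TRUE} the
#' comparison is repeated per session; sessions where one group is empty
#' (e.g. every electrode carries a single neuron) are skipped with a
#' reason.
#'
#' @param matrices a \linkS4class{DTWMatrix} or list of them.
#' @param geometry the \linkS4class{ElectrodeGeometry}.
#' @param bySession stratify by session (default FALSE: single pooled
#'   comparison).
#' @return data.frame with one row per comparison (n_same, n_diff,
#'   t_statistic, t_p, ks_statistic, ks_p) plus attribute \code{"skipped"}.
#' @export
electrodeDistributionTests <- function(matrices, geometry,
                                       bySession = FALSE) {
  entries <- poolEntries(matrices, geometry)
  groups <- if (bySession) split(entries, entries$session_id)
            else list(pooled = entries)
  rows <- list(); skip <- list()
  for (k in names(groups)) {
    g <- groups[[k]]
    same <- g$value[g$same_electrode]
    diff <- g$value[!g$same_electrode]
    if (length(same) < 2L || length(diff) < 2L) {
      skip[[k]] <- data.frame(group = k, n_same = length(same),
                              n_diff = length(diff),
                              reason = "a group is empty or singleton")
      next
    }
    tt <- t.test(same, diff, var.equal = FALSE)
    ks <- suppressWarnings(ks.test(same, diff))
    rows[[k]] <- data.frame(group = k, n_same = length(same),
                            n_diff = length(diff),
                            t_statistic = unname(tt$statistic),
                            t_p = tt$p.value,
                            ks_statistic = unname(ks$statistic),
                            ks_p = ks$p.value, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "skipped") <- if (length(skip)) do.call(rbind, skip) else
    data.frame()
  out
}

#' ROC curve for DTW distance as a same-electrode classifier
#'
#' Treats the DTW distance of a unit pair, thresholded at a cutoff, as a
#' classifier of whether the pair was recorded on the same electrode
#' (smaller distance predicting same). Returns the full ROC curve over all
#' cutoffs and its AUC; an AUC near 0.5 means the distance carries no
#' spatial information.
#'
#' @param values numeric DTW distances per unit pair.
#' @param sameElectrode logical, TRUE for same-electrode pairs.
#' @return list with \code{curve} (data.frame threshold, tpr, fpr) and
#'   \code{auc}.
#' @export
electrodeROC <- function(values, sameElectrode) {
  stopifnot(length(values) == length(sameElectrode))
  if (length(unique(sameElectrode)) < 2L)
    stop("AUC undefined: both classes must be present")
  r <- pROC::roc(response = factor(sameElectrode, levels = c(FALSE, TRUE)),
                 predictor = values, direction = ">", quiet = TRUE)
  list(curve = data.frame(threshold = r$thresholds,
                          tpr = r$sensitivities,
                          fpr = 1 - r$specificities),
       auc = as.numeric(r$auc))
}

#' Median DTW distance stratified by electrode distance
#'
#' Groups the pooled off-diagonal entries by the physical distance of their
#' electrodes (multiples of 0.25 mm; same-electrode spike-train pairs fall
#' in the zero-distance bin, which cannot occur for LFPs) and reports the
#' median per bin with a 95% percentile-bootstrap confidence interval.
#'
#' @param matrices a \linkS4class{DTWMatrix} or list of them.
#' @param geometry the \linkS4class{ElectrodeGeometry}.
#' @param nBoot bootstrap resamples (default 1000, minimum 100).
#' @param seed optional integer; results are deterministic given the seed.
#' @return data.frame: distance (grid multiples), distance_mm, n_pairs,
#'   median, ci_lower, ci_upper.
#' @export
distanceStratifiedMedians <- function(matrices, geometry, nBoot = 1000L,
                                      seed = NULL) {
  if (nBoot < 100L) stop("nBoot must be >= 100")
  entries <- poolEntries(matrices, geometry)
  bins <- split(entries$value, round(entries$grid_distance, 6))
  withSeed(seed, {
    rows <- lapply(names(bins), function(d) {
      v <- bins[[d]]
      boot <- vapply(seq_len(nBoot), function(i)
        median(sample(v, length(v), replace = TRUE)), numeric(1))
      ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
      data.frame(distance = as.numeric(d),
                 distance_mm = as.numeric(d) * GRID_UNIT_MM,
                 n_pairs = length(v), median = median(v),
                 ci_lower = ci[1L], ci_upper = ci[2L])
    })
    out <- do.call(rbind, rows)
    out[order(out$distance), ]
  })
}
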