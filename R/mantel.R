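#' Mantel permutation test between two DTW matrices
#'
#' Pearson correlation of the vectorized upper triangles of two distance
#' matrices over the same units, with significance from joint row/column
#' permutations of the second matrix. The p-value is two-sided on |r| with
#' the add-one correction \eqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) /
#' (n_{perm} + 1)}, so it can never be exactly zero.
#'
#' @param D1,D2 \linkS4class{DTWMatrix} objects (or plain matrices) with
#'   identical unit labels in identical order and >= 3 units.
#' @param nPerm number of permutations (default 999).
#' @param seed optional integer; the permutation stream is deterministic
#'   given the seed.
#' @return An \code{"htest"} with estimate r, p.value and the permutation
#'   count in \code{parameter}.
#' @export
mantelTest <- function(D1, D2, nPerm = 999L, seed = NULL) {
  v1 <- if (is(D1, "DTWMatrix")) dtwValues(D1) else D1
  v2 <- if (is(D2, "DTWMatrix")) dtwValues(D2) else D2
  if (is.null(rownames(v1)) || is.null(rownames(v2)) ||
      !identical(rownames(v1), rownames(v2)))
    stop("matrices must share identical unit labels in identical order")
  n <- nrow(v1)
  if (n < 3L) stop("Mantel test needs >= 3 units")
  ut <- upper.tri(v1)
  rObs <- cor(v1[ut], v2[ut])
  withSeed(seed, {
    exceed <- 0L
    for (b in seq_len(nPerm)) {
      p <- sample.int(n)
      rPerm <- cor(v1[ut], v2[p, p][ut])
      if (abs(rPerm) >= abs(rObs)) exceed <- exceed + 1L
    }
    pval <- (1 + exceed) / (nPerm + 1)
  })
  structure(list(estimate = c(r = rObs), p.value = pval,
                 parameter = c(n_perm = nPerm),
                 statistic = c(r = rObs),
                 alternative = "two.sided (on |r|)",
                 method = "Mantel permutation test",
                 data.name = "upper triangles of D1, D2"),
            class = "htest")
}

# Per-trial before/after DTW matrices of one session, restricted to the
# units retained in every matrix; NULL with a reason if < 3 common units.
sessionMatrixPairs <- function(bundle, minSpikes = 1L,
                               modality = c("spike", "lfp")) {
  modality <- match.arg(modality)
  mats <- lapply(bundle@trials, function(tr) {
    bef <- segmentMatrices(bundle, tr, "before", minSpikes, modality)
    aft <- segmentMatrices(bundle, tr, "after", minSpikes, modality)
    list(before = bef[[modality]], after = aft[[modality]])
  })
  failed <- vapply(mats, function(m)
    is.character(m$before) || is.character(m$after), logical(1))
  mats <- mats[!failed]
  if (length(mats) < 2L)
    return(structure(NULL, reason = "fewer than 2 trials with both segments"))
  labelSets <- lapply(mats, function(m)
    list(unitLabels(m$before), unitLabels(m$after)))
  common <- Reduce(intersect, unlist(labelSets, recursive = FALSE))
  if (length(common) < 3L)
    return(structure(NULL, reason = sprintf(
      "only %d units common to all matrices (need >= 3)", length(common))))
  lapply(mats, function(m) list(
    before = dtwValues(m$before)[common, common],
    after = dtwValues(m$after)[common, common],
    correctness = dtwMeta(m$before)$correctness,
    trial_index = dtwMeta(m$before)$trial_index))
}

#' Before-versus-after Mantel procedure for one session
#'
#' Asks whether the correspondence between a trial's pre-decision and
#' post-decision DTW matrices is specific to the trial: Mantel tests are
#' run for every (trial i before, trial j after) pair over the session's
#' common unit set, and the resulting Pearson r (and Mantel p)
#' distributions of the same-trial pairs (i = j) are compared with those of
#' the different-trial pairs (i != j) by Kruskal-Wallis and two-sample
#' Kolmogorov-Smirnov tests. Trials whose matrices cannot be formed are
#' dropped; the session is skipped (with a reason) when fewer than 2 trials
#' or fewer than 3 common units remain.
#'
#' @param bundle a \linkS4class{SessionBundle}.
#' @param nPerm Mantel permutations per pair (default 199 — the procedure
#'   runs O(trials^2) Mantel tests).
#' @param seed optional integer for the permutation streams.
#' @param minSpikes spike-count threshold passed to \code{\link{pairwiseDTW}}.
#' @param modality \code{"spike"} (default) or \code{"lfp"}.
#' @param correctnessSubset optional logical: restrict to trials with this
#'   correctness value (stratified variant).
#' @return list with \code{pairs} (data.frame trial_i, trial_j, same_trial,
#'   r, p) and \code{tests} (r_kruskal_p, r_ks_p, p_kruskal_p, p_ks_p), or
#'   a skip record \code{list(skipped = TRUE, reason = ...)}.
#' @export
beforeAfterProcedure <- function(bundle, nPerm = 199L, seed = NULL,
                                 minSpikes = 1L, modality = "spike",
                                 correctnessSubset = NULL) {
  if (!is.null(correctnessSubset)) {
    keep <- vapply(bundle@trials, function(tr)
      identical(tr@correctness, correctnessSubset), logical(1))
    bundle@trials <- bundle@trials[keep]
  }
  if (length(bundle@trials) < 2L)
    return(list(skipped = TRUE, reason = "fewer than 2 trials"))
  mats <- sessionMatrixPairs(bundle, minSpikes, modality)
  if (is.null(mats))
    return(list(skipped = TRUE, reason = attr(mats, "reason")))
  nT <- length(mats)
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nT)) {
      for (j in seq_len(nT)) {
        mt <- mantelTest(mats[[i]]$before, mats[[j]]$after, nPerm = nPerm)
        rows[[length(rows) + 1L]] <- data.frame(
          trial_i = mats[[i]]$trial_index, trial_j = mats[[j]]$trial_index,
          same_trial = i == j, r = unname(mt$estimate), p = mt$p.value)
      }
    }
    pairs <- do.call(rbind, rows)
    cmp <- function(v) {
      same <- v[pairs$same_trial]; diff <- v[!pairs$same_trial]
      kw <- kruskal.test(list(same, diff))
      ks <- suppressWarnings(ks.test(same, diff))
      c(kruskal_p = kw$p.value, ks_p = ks$p.value)
    }
    rTests <- cmp(pairs$r)
    pTests <- cmp(pairs$p)
    list(pairs = pairs,
         tests = list(r_kruskal_p = unname(rTests["kruskal_p"]),
                      r_ks_p = unname(rTests["ks_p"]),
                      p_kruskal_p = unname(pTests["kruskal_p"]),
                      p_ks_p = unname(pTests["ks_p"])),
         n_trials = nT)
  })
}
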