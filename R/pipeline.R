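# All DTW matrices of a bundle list, one per (session, trial, timing,
# modality), plus the skip log for segments that could not be formed.
collectMatrices <- function(bundles, minSpikes, modalities) {
  mats <- list(); skipped <- list()
  for (b in bundles) {
    for (tr in b@trials) {
      for (tm in TIMINGS) {
        res <- segmentMatrices(b, tr, tm, minSpikes, modalities)
        for (mod in names(res)) {
          key <- sprintf("%s|%d|%s|%s", b@sessionId, tr@trialIndex, tm, mod)
          if (is.character(res[[mod]]))
            skipped[[key]] <- data.frame(
              session_id = b@sessionId, trial_index = tr@trialIndex,
              timing = tm, modality = mod, reason = res[[mod]])
          else mats[[key]] <- res[[mod]]
        }
      }
    }
  }
  list(matrices = mats,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame())
}

dcritFromMatrices <- function(mats) {
  rows <- lapply(mats, function(m) {
    meta <- dtwMeta(m)
    dc <- dCrit(m)
    data.frame(study_id = meta$study_id, rat_id = meta$rat_id,
               session_id = meta$session_id, trial_index = meta$trial_index,
               timing = meta$timing, correctness = meta$correctness,
               modality = if (dtwUnits(m) == "ms") "spike" else "lfp",
               d_crit = dc, log10_d_crit = log10(dc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synchrony analysis pipeline
#'
#' Sequences simulate (or read) -> pairwise DTW -> d_crit -> statistical
#' battery -> experiment-design table into one reproducible run: a tidy
#' d_crit table, per-screen CSVs, electrode-distance analyses, the
#' before/after Mantel procedure per session, a JSON report with every
#' summary quantity, and a manifest whose per-stage counts reconcile
#' (analyzed + skipped = total). Deterministic given \code{seed}.
#'
#' @param design a \linkS4class{SyntheticDesign} (input generated), or NULL
#'   when \code{inputPath} is given.
#' @param inputPath directory in the \code{\link{writeBundle}} format.
#' @param outputDir output directory (created).
#' @param alpha significance level for all screens (default 0.05).
#' @param nPerm Mantel permutations (default 199).
#' @param nBoot bootstrap resamples for distance-stratified medians
#'   (default 1000).
#' @param minSpikes spike-count threshold for DTW inclusion (default 1).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param modalities subset of \code{c("spike", "lfp")}.
#' @return Invisibly, the report list.
#' @export
runPipeline <- function(design = NULL, inputPath = NULL, outputDir,
                        alpha = 0.05, nPerm = 199L, nBoot = 1000L,
                        minSpikes = 1L, seed = 1L,
                        modalities = c("spike", "lfp")) {
  if (is.null(design) == is.null(inputPath))
    stop("supply exactly one of design, inputPath")
  modalities <- match.arg(modalities, several.ok = TRUE)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  bundles <- if (!is.null(design)) generateBundles(design) else
    readBundle(inputPath)

  coll <- collectMatrices(bundles, minSpikes, modalities)
  records <- dcritFromMatrices(coll$matrices)
  write.csv(records, file.path(outputDir, "dcrit.csv"), row.names = FALSE)

  report <- list(alpha = alpha, seed = seed)
  screens <- list()
  screens$normality <- normalityScreen(records, alpha = alpha)
  for (m in c("kruskal_wallis", "anova"))
    screens[[paste0("session_", m)]] <-
      varianceScreen(records, "session", m, alpha = alpha)
  if (length(unique(records$session_id)) > 1L)
    screens$rat_kruskal_wallis <-
      varianceScreen(records, "rat", alpha = alpha)
  if (length(unique(records$rat_id)) > 1L)
    screens$study_kruskal_wallis <-
      varianceScreen(records, "study", alpha = alpha)
  for (nm in names(screens)) {
    write.csv(screens[[nm]]$results,
              file.path(outputDir, paste0("screen_", nm, ".csv")),
              row.names = FALSE)
    report$screens[[nm]] <- list(
      proportion_significant = as.list(screens[[nm]]$proportion),
      n_tested = nrow(screens[[nm]]$results),
      n_skipped = nrow(screens[[nm]]$skipped))
  }

  # proportion comparisons mirroring the screen battery
  splitScreen <- function(s, mod) {
    r <- s$results[s$results$modality == mod, ]
    c(sum(r$significant), nrow(r))
  }
  if (all(c("spike", "lfp") %in% records$modality)) {
    tab <- proportionTable(splitScreen(screens$normality, "spike"),
                           splitScreen(screens$normality, "lfp"),
                           labels = c("spike", "lfp"))
    report$boschloo$normality_spike_vs_lfp <-
      list(table = tab, p_value = boschlooTest(tab)$p.value)
  }
  for (mod in unique(records$modality)) {
    tab <- proportionTable(
      splitScreen(screens$session_kruskal_wallis, mod),
      splitScreen(screens$session_anova, mod),
      labels = c("kruskal_wallis", "anova"))
    report$boschloo[[paste0("kw_vs_anova_", mod)]] <-
      list(table = tab, p_value = boschlooTest(tab)$p.value)
  }

  geom <- bundles[[1L]]@geometry
  if ("spike" %in% modalities) {
    spikeMats <- Filter(function(m) dtwUnits(m) == "ms", coll$matrices)
    et <- electrodeDistributionTests(spikeMats, geom)
    write.csv(et, file.path(outputDir, "electrode_tests.csv"),
              row.names = FALSE)
    entries <- poolEntries(spikeMats, geom)
    if (length(unique(entries$same_electrode)) == 2L) {
      roc <- electrodeROC(entries$value, entries$same_electrode)
      report$electrode <- list(auc = roc$auc,
                               t_p = et$t_p[1L], ks_p = et$ks_p[1L])
    }
    med <- distanceStratifiedMedians(spikeMats, geom, nBoot = nBoot,
                                     seed = seed + 1L)
    write.csv(med, file.path(outputDir, "distance_medians.csv"),
              row.names = FALSE)
    report$distance_medians <- med
  }

  if ("spike" %in% modalities) {
    mantelRows <- list(); mantelSkips <- list()
    for (i in seq_along(bundles)) {
      ba <- beforeAfterProcedure(bundles[[i]], nPerm = nPerm,
                                 seed = seed + 100L + i,
                                 minSpikes = minSpikes)
      sid <- bundles[[i]]@sessionId
      if (isTRUE(ba$skipped))
        mantelSkips[[sid]] <- data.frame(session_id = sid,
                                         reason = ba$reason)
      else
        mantelRows[[sid]] <- cbind(session_id = sid, ba$pairs,
                                   r_ks_p = ba$tests$r_ks_p,
                                   r_kruskal_p = ba$tests$r_kruskal_p)
    }
    if (length(mantelRows)) {
      mp <- do.call(rbind, mantelRows)
      write.csv(mp, file.path(outputDir, "mantel_pairs.csv"),
                row.names = FALSE)
      perSession <- unique(mp[c("session_id", "r_ks_p", "r_kruskal_p")])
      report$mantel <- list(
        n_sessions = nrow(perSession),
        n_skipped = length(mantelSkips),
        prop_r_ks_significant = mean(perSession$r_ks_p < alpha))
    }
  }

  nNeurons <- length(geom@neuronMap)
  designTab <- do.call(rbind, lapply(1:25, couponDesign))
  write.csv(designTab, file.path(outputDir, "coupon_design.csv"),
            row.names = FALSE)
  report$design <- list(
    n_neurons = nNeurons,
    clusters_discernible = clustersDiscernible(nNeurons),
    mpfc_estimate = estimateMpfcNeurons()$reported)

  nTotal <- 2L * length(modalities) * sum(vapply(bundles, function(b)
    length(b@trials), integer(1)))
  manifest <- list(
    version = as.character(utils::packageVersion("spikeDTW")),
    config = list(alpha = alpha, n_perm = nPerm, n_boot = nBoot,
                  min_spikes = minSpikes, seed = seed,
                  modalities = modalities,
                  input = if (is.null(inputPath)) "synthetic design"
                          else inputPath),
    counts = list(sessions = length(bundles),
                  trials = sum(vapply(bundles, function(b)
                    length(b@trials), integer(1))),
                  segments_total = nTotal,
                  segments_analyzed = length(coll$matrices),
                  segments_skipped = nrow(coll$skipped)))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
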