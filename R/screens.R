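strataColumns <- function(stratify = c("none", "correctness", "timing",
                                       "both")) {
  stratify <- match.arg(stratify)
  switch(stratify, none = character(), correctness = "correctness",
         timing = "timing", both = c("correctness", "timing"))
}

groupKey <- function(df, cols) {
  if (!length(cols)) return(rep("all", nrow(df)))
  do.call(paste, c(unname(df[cols]), list(sep = "|")))
}

newScreen <- function(results, skipped, alpha, test) {
  results$significant <- results$p_value < alpha
  prop <- tapply(results$significant, results$modality, mean)
  structure(list(results = results, skipped = skipped,
                 proportion = prop, alpha = alpha, test = test),
            class = "dtwScreen")
}

#' @export
print.dtwScreen <- function(x, ...) {
  cat(sprintf("%s screen: %d tests, %d skipped, alpha = %g\n", x$test,
              nrow(x$results), nrow(x$skipped), x$alpha))
  for (m in names(x$proportion))
    cat(sprintf("  %s: %.1f%% significant (%d of %d)\n", m,
                100 * x$proportion[[m]],
                sum(x$results$significant[x$results$modality == m]),
                sum(x$results$modality == m)))
  invisible(x)
}

#' Shapiro-Wilk normality screen of per-session d_crit samples
#'
#' Tests, session by session (and modality by modality), whether the d_crit
#' values of a session are compatible with a normal distribution. Sessions
#' with fewer than 3 values, or with zero variance, cannot be tested and
#' are skipped with a reason (they do not enter the denominator of the
#' reported proportion). A high proportion of rejections argues for
#' non-parametric tests downstream.
#'
#' @param records d_crit table from \code{\link{dcritTable}}.
#' @param alpha significance level (default 0.05).
#' @param stratify one of \code{"none"}, \code{"correctness"},
#'   \code{"timing"}, \code{"both"}: test each stratum separately.
#' @return A \code{dtwScreen}: per-group results (statistic, p_value, n),
#'   skipped groups with reasons, and the proportion of non-normal groups
#'   per modality.
#' @export
normalityScreen <- function(records, alpha = 0.05, stratify = "none") {
  cols <- c("modality", "study_id", "rat_id", "session_id",
            strataColumns(stratify))
  key <- groupKey(records, cols)
  rows <- list(); skip <- list()
  for (k in unique(key)) {
    g <- records[key == k, ]
    info <- data.frame(group = k, modality = g$modality[1L],
                       session_id = g$session_id[1L],
                       n_observations = nrow(g), stringsAsFactors = FALSE)
    if (nrow(g) < 3L) {
      skip[[k]] <- cbind(info, reason = "fewer than 3 observations")
    } else if (sd(g$d_crit) == 0) {
      skip[[k]] <- cbind(info, reason = "zero variance")
    } else {
      sw <- shapiro.test(g$d_crit)
      rows[[k]] <- cbind(info, statistic = unname(sw$statistic),
                         p_value = sw$p.value)
    }
  }
  if (!length(rows)) stop("normality screen: no testable group")
  newScreen(do.call(rbind, rows),
            if (length(skip)) do.call(rbind, skip) else data.frame(),
            alpha, "Shapiro-Wilk normality")
}

levelKeys <- list(
  session = list(unit = c("modality", "study_id", "rat_id", "session_id"),
                 group = "trial_index"),
  rat = list(unit = c("modality", "study_id", "rat_id"),
             group = "session_id"),
  study = list(unit = c("modality", "study_id"), group = "rat_id"))

#' Omnibus variance screen of d_crit across the recording hierarchy
#'
#' At \code{level = "session"} tests trial-to-trial variation of d_crit
#' within each session (groups = trials, observations = the before/after
#' segment values of each trial); at \code{"rat"}, day-to-day variation
#' across a rat's sessions; at \code{"study"}, rat-to-rat variation within
#' a study. \code{groups} can override the grouping variable (e.g.
#' \code{"timing"} to test the before-vs-after effect within sessions).
#' Units with a single group (e.g. a rat recorded on a single day) have no
#' degrees of freedom for the test and are excluded with reason
#' \code{"dof = 0"}.
#'
#' @param records d_crit table from \code{\link{dcritTable}}.
#' @param level \code{"session"}, \code{"rat"} or \code{"study"}.
#' @param method \code{"kruskal_wallis"} (default) or \code{"anova"}.
#' @param alpha significance level.
#' @param stratify as in \code{\link{normalityScreen}}; strata are tested
#'   separately.
#' @param groups optional grouping column overriding the level default
#'   (one of \code{"trial_index"}, \code{"timing"}, \code{"correctness"},
#'   \code{"session_id"}, \code{"rat_id"}).
#' @return A \code{dtwScreen} (see \code{\link{normalityScreen}}).
#' @export
varianceScreen <- function(records, level = c("session", "rat", "study"),
                           method = c("kruskal_wallis", "anova"),
                           alpha = 0.05, stratify = "none", groups = NULL) {
  level <- match.arg(level)
  method <- match.arg(method)
  specLevel <- levelKeys[[level]]
  groupCol <- if (is.null(groups)) specLevel$group else groups
  cols <- unique(c(specLevel$unit, strataColumns(stratify)))
  key <- groupKey(records, cols)
  rows <- list(); skip <- list()
  for (k in unique(key)) {
    g <- records[key == k, ]
    fac <- factor(g[[groupCol]])
    info <- data.frame(group = k, modality = g$modality[1L],
                       n_observations = nrow(g),
                       n_groups = nlevels(droplevels(fac)),
                       stringsAsFactors = FALSE)
    if (nlevels(droplevels(fac)) < 2L) {
      skip[[k]] <- cbind(info, reason = "dof = 0")
    } else if (sd(g$d_crit) == 0) {
      skip[[k]] <- cbind(info, reason = "zero variance")
    } else if (method == "kruskal_wallis") {
      kw <- kruskal.test(g$d_crit, droplevels(fac))
      rows[[k]] <- cbind(info, statistic = unname(kw$statistic),
                         p_value = kw$p.value)
    } else {
      fit <- aov(d_crit ~ fac, data = cbind(g, fac = droplevels(fac)))
      sm <- summary(fit)[[1L]]
      rows[[k]] <- cbind(info, statistic = sm[["F value"]][1L],
                         p_value = sm[["Pr(>F)"]][1L])
    }
  }
  if (!length(rows)) stop("variance screen: no testable group")
  newScreen(do.call(rbind, rows),
            if (length(skip)) do.call(rbind, skip) else data.frame(),
            alpha,
            paste0(if (method == "kruskal_wallis") "Kruskal-Wallis"
                   else "ANOVA", " variance (", level, ")"))
}

#' Assemble a 2x2 contingency table from two screens
#'
#' Rows are the two screens, columns (significant, not significant) — the
#' table handed to \code{\link{boschlooTest}} when comparing, e.g., the
#' proportion of significant sessions between spike trains and LFPs or
#' between two test procedures.
#'
#' @param screenA,screenB \code{dtwScreen} objects, or integer vectors
#'   \code{c(significant, total)}.
#' @param labels row labels.
#' @return 2x2 integer matrix.
#' @export
proportionTable <- function(screenA, screenB,
                            labels = c("screenA", "screenB")) {
  count <- function(s) {
    if (inherits(s, "dtwScreen"))
      c(sum(s$results$significant), nrow(s$results))
    else c(s[1L], s[2L])
  }
  a <- count(screenA)
  b <- count(screenB)
  if (a[2L] == 0L || b[2L] == 0L)
    warning("degenerate proportion table: a screen has no tested group")
  m <- matrix(c(a[1L], a[2L] - a[1L], b[1L], b[2L] - b[1L]), 2L, 2L,
              byrow = TRUE,
              dimnames = list(labels, c("significant", "not_significant")))
  m
}
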