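offDiagonal <- function(v) v[upper.tri(v)]

# Depth-first search connectivity of the <=t threshold graph of a distance
# matrix. Iterative stack DFS; adjacency taken directly from the matrix.
thresholdConnected <- function(values, t) {
  n <- nrow(values)
  adj <- values <= t
  diag(adj) <- FALSE
  visited <- logical(n)
  stack <- 1L
  visited[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(adj[v, ] & !visited)
    visited[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(visited)
}

#' Critical connectivity threshold of a DTW matrix
#'
#' The graph over units with an edge (i, j) whenever \eqn{D_{ij} \le t} is
#' disconnected for small t and complete for large t. \code{dCrit} returns
#' the smallest threshold t at which that graph is connected — the point of
#' the connectivity transition. It is located by binary search over the
#' sorted unique off-diagonal weights, testing connectivity with a
#' depth-first search at each probe; the result is always an attained edge
#' weight, and equals the bottleneck (maximum edge) of a minimum spanning
#' tree of the complete weighted graph.
#'
#' @param D a \linkS4class{DTWMatrix}, or a plain symmetric numeric matrix
#'   with >= 2 rows.
#' @return The critical threshold, in the units of \code{D}.
#' @examples
#' m <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' dCrit(m)  # 2: edges {1, 2} already span the three nodes
#' @export
dCrit <- function(D) {
  values <- if (is(D, "DTWMatrix")) D@values else D
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("D must be a square matrix or DTWMatrix")
  if (nrow(values) < 2L) stop("dCrit needs at least 2 nodes")
  w <- sort(unique(offDiagonal(values)))
  lo <- 1L
  hi <- length(w)
  # invariant: graph at w[hi] connected (complete graph), w[lo-1] unknown
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (thresholdConnected(values, w[mid])) hi <- mid else lo <- mid + 1L
  }
  w[lo]
}

#' Threshold graph of a DTW matrix
#'
#' Undirected, unweighted graph retaining exactly the edges with
#' \eqn{D_{ij} \le t}, returned as a logical adjacency matrix (no self
#' loops).
#'
#' @param D a \linkS4class{DTWMatrix} or square symmetric matrix.
#' @param t finite threshold, in the units of \code{D}.
#' @return Logical adjacency matrix with the unit labels of \code{D}.
#' @export
thresholdGraph <- function(D, t) {
  values <- if (is(D, "DTWMatrix")) D@values else D
  stopifnot(is.finite(t))
  adj <- values <= t
  diag(adj) <- FALSE
  adj
}

segmentMatrices <- function(bundle, trial, timing, minSpikes, modalities) {
  seg <- trial@segments[[timing]]
  meta <- list(study_id = bundle@studyId, rat_id = bundle@ratId,
               session_id = bundle@sessionId, trial_index = trial@trialIndex,
               timing = timing, correctness = trial@correctness)
  out <- list()
  if ("spike" %in% modalities)
    out$spike <- tryCatch(
      pairwiseDTW(seg$spikes, minSpikes = minSpikes, meta = meta),
      error = function(e) conditionMessage(e))
  if ("lfp" %in% modalities)
    out$lfp <- tryCatch(
      pairwiseDTW(seg$lfp, meta = meta),
      error = function(e) conditionMessage(e))
  out
}

#' Tidy d_crit table over session bundles
#'
#' Computes one d_crit value per (session, trial, timing segment, modality):
#' pairwise DTW over the segment's spike trains (ms) and LFP traces (V),
#' then the critical connectivity threshold of each matrix. Records carry
#' all stratification keys (study, rat, session, trial, timing,
#' correctness). Segments whose matrix cannot be formed (fewer than two
#' retained units) are skipped and logged in the \code{"skipped"} attribute.
#'
#' @param bundles a \linkS4class{SessionBundle} or list of them.
#' @param minSpikes minimum spike count for a spike train to enter the DTW
#'   matrix (default 1).
#' @param modalities character subset of \code{c("spike", "lfp")}.
#' @return data.frame with columns study_id, rat_id, session_id,
#'   trial_index, timing, correctness, modality, d_crit, log10_d_crit, and
#'   attribute \code{"skipped"} (data.frame of skipped segments with
#'   reasons). log10_d_crit is provided for reporting and plotting; the
#'   statistic itself is linear-scale.
#' @export
dcritTable <- function(bundles, minSpikes = 1L,
                       modalities = c("spike", "lfp")) {
  if (is(bundles, "SessionBundle")) bundles <- list(bundles)
  modalities <- match.arg(modalities, several.ok = TRUE)
  rows <- list()
  skipped <- list()
  for (b in bundles) {
    for (tr in b@trials) {
      for (tm in TIMINGS) {
        mats <- segmentMatrices(b, tr, tm, minSpikes, modalities)
        for (mod in names(mats)) {
          key <- data.frame(study_id = b@studyId, rat_id = b@ratId,
                            session_id = b@sessionId,
                            trial_index = tr@trialIndex, timing = tm,
                            correctness = tr@correctness, modality = mod,
                            stringsAsFactors = FALSE)
          if (is.character(mats[[mod]])) {
            skipped[[length(skipped) + 1L]] <-
              cbind(key, reason = mats[[mod]])
          } else {
            dc <- dCrit(mats[[mod]])
            rows[[length(rows) + 1L]] <-
              cbind(key, d_crit = dc, log10_d_crit = log10(dc))
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(study_id = character(), rat_id = character(),
               session_id = character(), trial_index = integer(),
               timing = character(), correctness = logical(),
               modality = character(), d_crit = numeric(),
               log10_d_crit = numeric())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame()
  out
}
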