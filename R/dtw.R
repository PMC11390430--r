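#' Dynamic time warping distance between two sequences
#'
#' Traditional, parameter-free DTW: the minimal accumulated cost over all
#' monotone, boundary-anchored warping paths with per-step cost
#' \eqn{|x_i - y_j|} and steps \{(-1,0), (0,-1), (-1,-1)\}. The total
#' (unnormalized) cost is returned, so the result carries the units of the
#' inputs: milliseconds when aligning spike-time sequences, volts when
#' aligning LFP sample sequences. No window constraint, smoothing or path
#' normalization is applied. DTW is a dissimilarity, not a metric: the
#' triangle inequality need not hold.
#'
#' @param x,y non-empty numeric sequences.
#' @return Nonnegative scalar DTW dissimilarity, symmetric in its arguments.
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 3))  # 0
#' dtwDistance(c(0, 10), c(0, 5, 10))   # 5
#' @export
dtwDistance <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("dtwDistance is undefined for empty sequences; ",
         "filter sparse units first (see pairwiseDTW min_spikes)")
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y))
    stop("dtwDistance requires numeric, NA-free sequences")
  .dtw_cost(as.numeric(x), as.numeric(y))
}

newDTWMatrix <- function(values, units, meta = list(),
                         exclusions = data.frame(unit = character(),
                                                 reason = character())) {
  new("DTWMatrix", values = values, units = units, meta = meta,
      exclusions = exclusions)
}

#' Pairwise DTW dissimilarity matrix over the units of one trial segment
#'
#' Computes all pairwise DTW distances among a set of spike trains (on their
#' spike-time sequences, units ms) or LFP segments (on their voltage-sample
#' sequences, units V). Spike trains with fewer than \code{minSpikes} spikes
#' are excluded before computation and recorded in the exclusion log —
#' DTW is undefined on empty sequences and near-empty trains carry no
#' alignment signal.
#'
#' @param units list of \linkS4class{SpikeTrain} or of
#'   \linkS4class{LFPSegment} (not mixed).
#' @param minSpikes minimum spike count for a spike train to be retained
#'   (default 1). Ignored for LFPs.
#' @param meta named list of stratification keys attached to the result.
#' @return A \linkS4class{DTWMatrix} over the retained units.
#' @seealso \code{\link{dtwDistance}}, \code{\link{dCrit}}
#' @export
pairwiseDTW <- function(units, minSpikes = 1L, meta = list()) {
  if (!length(units)) stop("no units supplied")
  isSpike <- vapply(units, is, logical(1), class2 = "SpikeTrain")
  isLfp <- vapply(units, is, logical(1), class2 = "LFPSegment")
  if (all(isSpike)) {
    labels <- vapply(units, function(u) u@neuronId, character(1))
    seqs <- lapply(units, function(u) u@times)
    unitsTag <- "ms"
    keep <- lengths(seqs) >= minSpikes
    reason <- sprintf("spike count %d < min_spikes %d",
                      lengths(seqs)[!keep], as.integer(minSpikes))
  } else if (all(isLfp)) {
    labels <- vapply(units, function(u) u@electrodeId, character(1))
    seqs <- lapply(units, function(u) u@voltages)
    unitsTag <- "V"
    keep <- rep(TRUE, length(seqs))
    reason <- character()
  } else {
    stop("units must be all SpikeTrain or all LFPSegment")
  }
  if (anyDuplicated(labels)) stop("duplicated unit labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  exclusions <- data.frame(unit = labels[!keep], reason = reason,
                           stringsAsFactors = FALSE)
  labels <- labels[keep]
  seqs <- seqs[keep]
  n <- length(seqs)
  if (n < 2L)
    stop("fewer than 2 units retained after exclusion (",
         nrow(exclusions), " excluded)")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- .dtw_cost(seqs[[i]], seqs[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  newDTWMatrix(m, unitsTag, meta = meta, exclusions = exclusions)
}
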