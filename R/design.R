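harmonic <- function(n) if (n == 0) 0 else sum(1 / seq_len(n))

#' Expected draws to collect every cluster (coupon collector)
#'
#' Expected number of i.i.d. uniform draws from \code{c} equally likely
#' clusters until all \code{c} have been seen: \eqn{S = c \cdot H_c} with
#' \eqn{H_c} the c-th harmonic number. Asymptotically \eqn{S \sim c \log c}.
#'
#' @param c cluster count (>= 1).
#' @return Expected sample count.
#' @examples
#' expectedSamplesFull(2)  # 3
#' @export
expectedSamplesFull <- function(c) {
  if (length(c) != 1L || c < 1 || c != round(c))
    stop("c must be a single integer >= 1")
  c * harmonic(c)
}

#' Expected draws to collect k of c clusters
#'
#' Partial-coverage coupon collector: expected number of uniform draws
#' until \code{k} distinct of the \code{c} clusters have been seen,
#' \eqn{S_k = c (H_c - H_{c-k}) = c \sum_{i=0}^{k-1} 1/(c-i)}. At
#' \code{k = c} this reduces to \code{\link{expectedSamplesFull}}.
#'
#' @param c cluster count (>= 1).
#' @param k required distinct clusters, 1 <= k <= c.
#' @return Expected sample count.
#' @export
expectedSamplesPartial <- function(c, k) {
  if (length(c) != 1L || c < 1 || c != round(c))
    stop("c must be a single integer >= 1")
  if (length(k) != 1L || k < 1 || k > c || k != round(k))
    stop("k must be a single integer with 1 <= k <= c")
  c * (harmonic(c) - harmonic(c - k))
}

#' Coupon-collector design summary
#'
#' @param c cluster count.
#' @param k required distinct clusters (default \code{c}: full coverage).
#' @return data.frame with c, k, H_c, H_{c-k} and the expected sample count.
#' @export
couponDesign <- function(c, k = c) {
  data.frame(c = c, k = k, H_c = harmonic(c), H_c_minus_k = harmonic(c - k),
             expected_samples = expectedSamplesPartial(c, k))
}

#' Largest discernible cluster count for a given electrode size
#'
#' The largest number of clusters \code{c} whose expected coupon-collector
#' sample count does not exceed the number of neurons recorded — i.e. how
#' many synchrony clusters an electrode of that size can, in expectation,
#' sample at least once (fully, or \code{k} of them when \code{coverage}
#' is given). Found by monotone search, since the expected count is
#' strictly increasing in \code{c}.
#'
#' @param nNeurons number of neurons recorded (>= 1).
#' @param coverage NULL for full coverage, or a function \code{f(c)}
#'   returning the required k for a given c (e.g.
#'   \code{function(c) ceiling(c / 2)}).
#' @return Largest feasible integer c (>= 1).
#' @examples
#' clustersDiscernible(3)  # 2: S(2) = 3 <= 3 < S(3) = 5.5
#' @export
clustersDiscernible <- function(nNeurons, coverage = NULL) {
  if (nNeurons < 1) stop("nNeurons must be >= 1")
  need <- function(c) if (is.null(coverage)) expectedSamplesFull(c)
         else expectedSamplesPartial(c, coverage(c))
  c <- 1L
  while (need(c + 1L) <= nNeurons) c <- c + 1L
  c
}

#' Scaling estimate of the neuron count in the rat mPFC
#'
#' Volume-proportional estimate: assuming a uniform neuron density,
#' \eqn{N_{mPFC} = N_{brain} \times V_{mPFC} / V_{brain}}. Defaults are the
#' standard literature values for the rat: 2.1e7 neurons in a 2,500 mm^3
#' brain, with a 20 mm^3 medial prefrontal cortex.
#'
#' @param nBrain total neuron count of the brain.
#' @param vBrain brain volume, mm^3.
#' @param vMpfc mPFC volume, mm^3 (same units as \code{vBrain}).
#' @return list with the exact estimate (\code{n_mpfc}) and a
#'   two-significant-figure \code{reported} value.
#' @examples
#' estimateMpfcNeurons()$reported  # 1.7e5
#' @export
estimateMpfcNeurons <- function(nBrain = 2.1e7, vBrain = 2500, vMpfc = 20) {
  if (nBrain <= 0 || vBrain <= 0 || vMpfc <= 0)
    stop("all inputs must be positive")
  exact <- nBrain * vMpfc / vBrain
  list(n_brain = nBrain, v_brain = vBrain, v_mpfc = vMpfc,
       n_mpfc = exact, reported = signif(exact, 2))
}

#' Monte-Carlo coupon collector
#'
#' Simulates i.i.d. uniform draws from \code{c} equally likely clusters
#' until \code{k} distinct clusters are seen, \code{nRuns} times, and
#' returns the mean draw count — the simulation oracle for
#' \code{\link{expectedSamplesPartial}}.
#'
#' @param c cluster count.
#' @param k required distinct clusters (default \code{c}).
#' @param nRuns replicates (>= 1).
#' @param seed optional integer; deterministic given the seed.
#' @return list with \code{mean} draws and the vector of per-run
#'   \code{draws}.
#' @export
simulateCoupon <- function(c, k = c, nRuns = 10000L, seed = NULL) {
  draws <- withSeed(seed, .coupon_draws(as.integer(c), as.integer(k),
                                        as.integer(nRuns)))
  list(mean = mean(draws), draws = draws)
}
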