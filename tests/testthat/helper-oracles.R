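# Independent oracles and fixture builders, kept free of the code paths
# they check.

# Exhaustive enumeration of all monotone, boundary-anchored warping paths
# (steps down/right/diagonal); minimum accumulated |x_i - y_j| cost.
# Exponential — for sequences of length <= 6 only.
bruteDtw <- function(x, y) {
  n <- length(x); m <- length(y)
  rec <- function(i, j) {
    cost <- abs(x[i] - y[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(n, m)
}

# MST bottleneck via igraph (standard algorithm, independent of dCrit).
mstBottleneck <- function(values) {
  g <- igraph::graph_from_adjacency_matrix(values, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  max(igraph::E(mst)$weight)
}

# Exhaustive spanning-subset bottleneck: minimum over all (n-1)-edge
# spanning subsets of the maximum edge weight. n <= 6 only.
exhaustiveBottleneck <- function(values) {
  n <- nrow(values)
  pairs <- which(upper.tri(values), arr.ind = TRUE)
  w <- values[upper.tri(values)]
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    g <- igraph::make_graph(t(pairs[sel, , drop = FALSE]), n = n,
                            directed = FALSE)
    if (igraph::components(g)$no == 1L)
      best <- min(best, max(w[sel]))
  }
  best
}

# Random symmetric distance matrix with distinct positive weights.
randDistMatrix <- function(n) {
  v <- matrix(0, n, n)
  w <- sample(seq(1, 1000), n * (n - 1) / 2)
  v[upper.tri(v)] <- w
  v <- v + t(v)
  dimnames(v) <- list(paste0("u", 1:n), paste0("u", 1:n))
  v
}

# DTWMatrix wrapper around a raw values matrix (for stats-layer tests that
# do not need real DTW input).
wrapMatrix <- function(values, units = "ms", meta = list()) {
  new("DTWMatrix", values = values, units = units, meta = meta,
      exclusions = data.frame(unit = character(), reason = character()))
}

# Geometry with nE electrodes on a line, nPer neurons each.
lineGeometry <- function(nE, nPer) {
  eid <- sprintf("e%02d", seq_len(nE))
  nm <- rep(eid, each = nPer)
  names(nm) <- sprintf("n%03d", seq_len(nE * nPer))
  new("ElectrodeGeometry",
      electrodes = data.frame(electrode_id = eid,
                              grid_x = seq_len(nE) - 1L, grid_y = 0L),
      neuronMap = nm)
}

# Synthetic d_crit record table with groups drawn from a supplied sampler.
fakeRecords <- function(nSessions, trialsPer, sampler,
                        modality = "spike") {
  rows <- lapply(seq_len(nSessions), function(s) {
    d <- sampler(trialsPer * 2)
    data.frame(study_id = "st", rat_id = "r1",
               session_id = sprintf("s%03d", s),
               trial_index = rep(seq_len(trialsPer), each = 2),
               timing = rep(c("before", "after"), trialsPer),
               correctness = TRUE, modality = modality,
               d_crit = d, log10_d_crit = log10(pmax(d, 1e-12)))
  })
  do.call(rbind, rows)
}

spikeTrainOf <- function(times, id = "n1", eid = "e1")
  new("SpikeTrain", neuronId = id, electrodeId = eid, times = times)

tinyDesign <- function(...) {
  args <- list(nRats = 1, sessionsPerRat = 1, trialsPerSession = 4,
               nElectrodes = 2, neuronsPerElectrode = 3, nClusters = 2,
               lfpSampleRate = 100, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(syntheticDesign, args)
}
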