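test_that("dCrit solves small instances by hand", {
  m2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(dCrit(m2), 7)
  m3 <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(dCrit(m3), 2)  # edges {1, 2} already span the triangle
  expect_error(dCrit(matrix(0, 1, 1)), "2 nodes")
})

test_that("dCrit equals the MST bottleneck on random matrices", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    v <- randDistMatrix(n)
    expect_equal(dCrit(v), mstBottleneck(v))
  }
})

test_that("dCrit equals exhaustive spanning-subset bottleneck at small n", {
  skip_if_not_installed("igraph")
  set.seed(6)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    v <- randDistMatrix(n)
    expect_equal(dCrit(v), exhaustiveBottleneck(v))
  }
})

test_that("dCrit is equivariant under shift and positive scaling", {
  set.seed(8)
  v <- randDistMatrix(9)
  d0 <- dCrit(v)
  shifted <- v + 13.5
  diag(shifted) <- 0
  expect_equal(dCrit(shifted), d0 + 13.5)
  expect_equal(dCrit(v * 2.5), d0 * 2.5)
})

test_that("the threshold graph flips connectivity exactly at dCrit", {
  set.seed(9)
  for (rep in 1:20) {
    v <- randDistMatrix(sample(3:8, 1))
    dc <- dCrit(v)
    w <- sort(unique(v[upper.tri(v)]))
    connected <- function(adj) {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      igraph::components(g)$no == 1L
    }
    expect_true(connected(thresholdGraph(v, dc)))
    below <- w[w < dc]
    if (length(below))
      expect_false(connected(thresholdGraph(v, max(below))))
    expect_equal(sum(thresholdGraph(v, min(w) - 1)), 0)
    adjFull <- thresholdGraph(v, max(w))
    expect_true(all(adjFull[upper.tri(adjFull)]))
  }
})

test_that("dcritTable yields one record per segment and modality with full
           stratification keys", {
  d <- tinyDesign(trialsPerSession = 2)
  b <- generateBundles(d)
  rec <- dcritTable(b)
  expect_equal(nrow(rec), 2 * 2 * 2)  # trials x timings x modalities
  expect_setequal(unique(rec$modality), c("spike", "lfp"))
  expect_setequal(unique(rec$timing), c("before", "after"))
  expect_true(all(c("study_id", "rat_id", "session_id", "trial_index",
                    "correctness", "d_crit", "log10_d_crit") %in%
                    names(rec)))
  expect_equal(rec$log10_d_crit, log10(rec$d_crit))
})

test_that("segments without two active units are skipped and logged", {
  d <- tinyDesign(trialsPerSession = 2, neuronsPerElectrode = 1,
                  nElectrodes = 2, nClusters = 1, baseRate = 0.6)
  b <- generateBundles(d)
  # force one segment down to a single active neuron
  seg <- b[[1]]@trials[[1]]@segments$before
  seg$spikes[[2]]@times <- numeric()
  b[[1]]@trials[[1]]@segments$before <- seg
  rec <- dcritTable(b, minSpikes = 1, modalities = "spike")
  skipped <- attr(rec, "skipped")
  expect_equal(nrow(rec) + nrow(skipped), 4)
  expect_gte(nrow(skipped), 1)
  expect_match(skipped$reason[1], "fewer than 2 units")
})

test_that("injected timing effects depress post-decision d_crit", {
  shifts <- vapply(1:15, function(seed) {
    d <- syntheticDesign(nRats = 1, sessionsPerRat = 1,
                         trialsPerSession = 6, nElectrodes = 2,
                         neuronsPerElectrode = 4, nClusters = 2,
                         lfpSampleRate = 100, seed = seed)
    rec <- dcritTable(generateBundles(d), modalities = "spike")
    mean(rec$d_crit[rec$timing == "after"]) -
      mean(rec$d_crit[rec$timing == "before"])
  }, numeric(1))
  expect_lt(mean(shifts), 0)
})
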