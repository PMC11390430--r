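test_that("generation is bit-identical under a fixed seed", {
  d <- tinyDesign()
  expect_identical(generateBundles(d), generateBundles(d))
  d2 <- tinyDesign(seed = 8L)
  expect_false(identical(generateBundles(d), generateBundles(d2)))
})

test_that("design invariants are enforced", {
  expect_error(tinyDesign(syncCopyProb = 1.2), "syncCopyProb")
  expect_error(tinyDesign(baseRate = 0), "baseRate")
  expect_error(tinyDesign(nRats = 0), "counts")
  expect_error(tinyDesign(nClusters = 99), "exceed")
})

test_that("with no shared parent, per-segment spike counts are Poisson at
           the base rate", {
  d <- syntheticDesign(nRats = 1, sessionsPerRat = 1, trialsPerSession = 25,
                       nElectrodes = 2, neuronsPerElectrode = 10,
                       nClusters = 2, baseRate = 10, syncCopyProb = 0,
                       effectTiming = 0, effectCorrect = 0,
                       sessionDriftSd = 1e-9, lfpSampleRate = 100,
                       seed = 31L)
  b <- generateBundles(d)[[1]]
  counts <- unlist(lapply(trials(b), function(tr)
    lapply(tr@segments, function(seg)
      vapply(seg$spikes, function(st) length(spikeTimes(st)), numeric(1)))))
  expect_length(counts, 25 * 2 * 20)
  lambda <- 20  # 10 events/s x 2 s
  expect_equal(mean(counts), lambda, tolerance = 0.02)
  # chi-square goodness of fit against the Poisson pmf, pooled tails
  brk <- qpois(c(0.001, seq(0.05, 0.95, by = 0.1), 0.999), lambda)
  brk <- unique(c(-1, brk, Inf))
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(brk, lambda))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("mean pairwise DTW decreases as cluster synchrony rises", {
  meanD <- function(s, seed) {
    d <- syntheticDesign(nRats = 1, sessionsPerRat = 1, trialsPerSession = 2,
                         nElectrodes = 1, neuronsPerElectrode = 6,
                         nClusters = 1, syncCopyProb = s, effectTiming = 0,
                         effectCorrect = 0, lfpSampleRate = 100, seed = seed)
    b <- generateBundles(d)[[1]]
    mean(vapply(trials(b), function(tr) {
      v <- dtwValues(pairwiseDTW(tr@segments$before$spikes))
      mean(v[upper.tri(v)])
    }, numeric(1)))
  }
  means <- vapply(c(0, 0.5, 1), function(s)
    mean(vapply(1:20, function(seed) meanD(s, seed), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("bundles survive a disk round trip", {
  d <- tinyDesign(trialsPerSession = 2, baseRate = 8)
  b <- generateBundles(d)
  dir <- withr::local_tempdir()
  writeBundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trials.csv", "spikes.csv", "lfp.csv", "geometry.csv",
      "ground_truth.json")))))
  b2 <- readBundle(dir)
  expect_equal(length(b2), length(b))
  expect_equal(b2[[1]]@sessionId, b[[1]]@sessionId)
  expect_equal(names(geometry(b2[[1]])@neuronMap),
               names(geometry(b[[1]])@neuronMap))
  for (i in seq_along(b[[1]]@trials)) {
    for (tm in c("before", "after")) {
      s1 <- b[[1]]@trials[[i]]@segments[[tm]]$spikes
      s2 <- b2[[1]]@trials[[i]]@segments[[tm]]$spikes
      expect_equal(lapply(s2, spikeTimes), lapply(s1, spikeTimes),
                   tolerance = 1e-12)
      l1 <- b[[1]]@trials[[i]]@segments[[tm]]$lfp
      l2 <- b2[[1]]@trials[[i]]@segments[[tm]]$lfp
      expect_equal(lapply(l2, voltages), lapply(l1, voltages),
                   tolerance = 1e-12)
    }
  }
  # and the derived statistics agree exactly enough to be interchangeable
  expect_equal(dcritTable(b2, modalities = "spike")$d_crit,
               dcritTable(b, modalities = "spike")$d_crit,
               tolerance = 1e-10)
})

test_that("malformed bundle files are rejected with file and line", {
  d <- tinyDesign(trialsPerSession = 1)
  dir <- withr::local_tempdir()
  writeBundle(generateBundles(d), dir)

  spikes <- read.csv(file.path(dir, "spikes.csv"))
  spikes$time_ms[3] <- 2500
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  expect_error(readBundle(dir), "spikes\\.csv.*line 4")

  writeBundle(generateBundles(d), dir)
  spikes <- read.csv(file.path(dir, "spikes.csv"))
  spikes$electrode_id[1] <- "e99"
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  err <- tryCatch(readBundle(dir), error = conditionMessage)
  expect_match(err, "spikes\\.csv")
  expect_match(err, spikes$neuron_id[1])
})
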