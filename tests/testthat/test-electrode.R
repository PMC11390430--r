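# Build a DTWMatrix over neurons of a line geometry with entries drawn by
# group: sameFn for same-electrode pairs, diffFn otherwise.
groupedMatrix <- function(geom, sameFn, diffFn, session = "s1") {
  nid <- names(geom@neuronMap)
  n <- length(nid)
  v <- matrix(0, n, n, dimnames = list(nid, nid))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- geom@neuronMap[nid[i]] == geom@neuronMap[nid[j]]
    v[i, j] <- v[j, i] <- if (same) sameFn(1) else diffFn(1)
  }
  wrapMatrix(v, meta = list(session_id = session))
}

test_that("same/diff electrode tests are calibrated under the null", {
  set.seed(51)
  geom <- lineGeometry(4, 4)
  ps <- t(vapply(1:200, function(i) {
    m <- groupedMatrix(geom, function(n) rnorm(n, 100, 10),
                       function(n) rnorm(n, 100, 10))
    r <- electrodeDistributionTests(m, geom)
    c(r$t_p, r$ks_p)
  }, numeric(2)))
  # both p-value streams uniform on (0,1)
  expect_gt(ks.test(ps[, 1], "punif")$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(ps[, 2], "punif"))$p.value, 0.01)
})

test_that("a two-sd separation is detected by both tests", {
  set.seed(52)
  geom <- lineGeometry(4, 4)
  m <- groupedMatrix(geom, function(n) rnorm(n, 100, 5),
                     function(n) rnorm(n, 110, 5))
  r <- electrodeDistributionTests(m, geom)
  expect_lt(r$t_p, 0.001)
  expect_lt(r$ks_p, 0.001)
})

test_that("sessions with an empty same-electrode group are skipped", {
  set.seed(53)
  geom <- lineGeometry(4, 1)  # one neuron per electrode
  m <- groupedMatrix(geom, function(n) rnorm(n, 10), function(n) rnorm(n, 10))
  r <- electrodeDistributionTests(m, geom)
  expect_equal(nrow(r), 0)
  expect_match(attr(r, "skipped")$reason, "empty")
})

test_that("ROC behaves as a proper ranking statistic", {
  set.seed(54)
  sep <- electrodeROC(c(rnorm(50, 0), rnorm(50, 100)),
                      rep(c(TRUE, FALSE), each = 50))
  expect_equal(sep$auc, 1.0)

  vals <- runif(10000); labs <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  a <- electrodeROC(vals, labs)$auc
  expect_equal(a, 0.5, tolerance = 0.02)

  # score symmetry and monotone-transform invariance
  v <- rnorm(400); l <- rep(c(TRUE, FALSE), 200)
  expect_equal(electrodeROC(v, l)$auc, 1 - electrodeROC(-v, l)$auc,
               tolerance = 1e-10)
  expect_equal(electrodeROC(exp(v), l)$auc, electrodeROC(v, l)$auc)

  expect_error(electrodeROC(1:5, rep(TRUE, 5)), "both classes")
})

test_that("distance-stratified medians: exact constants and no LFP zero
           bin", {
  geom <- lineGeometry(3, 2)
  nid <- names(geom@neuronMap)
  v <- matrix(7, 6, 6, dimnames = list(nid, nid)); diag(v) <- 0
  m <- wrapMatrix(v)
  med <- distanceStratifiedMedians(m, geom, nBoot = 100, seed = 1)
  expect_true(0 %in% med$distance)       # same-electrode spike pairs
  expect_true(all(med$median == 7))
  expect_true(all(med$ci_lower == 7 & med$ci_upper == 7))
  expect_equal(med$distance_mm, med$distance * 0.25)

  eids <- geom@electrodes$electrode_id
  lv <- matrix(3, 3, 3, dimnames = list(eids, eids)); diag(lv) <- 0
  lm <- wrapMatrix(lv, units = "V")
  lmed <- distanceStratifiedMedians(lm, geom, nBoot = 100, seed = 1)
  expect_false(0 %in% lmed$distance)     # LFPs are per-electrode

  expect_identical(distanceStratifiedMedians(m, geom, 150, seed = 9),
                   distanceStratifiedMedians(m, geom, 150, seed = 9))
})

test_that("bootstrap CIs cover the true median at the nominal rate", {
  set.seed(56)
  geom <- lineGeometry(2, 3)
  trueMed <- qexp(0.5, rate = 0.1)
  hits <- vapply(1:200, function(i) {
    m <- groupedMatrix(geom, function(n) rexp(n, 0.1),
                       function(n) rexp(n, 0.1))
    med <- distanceStratifiedMedians(m, geom, nBoot = 199)
    row <- med[med$distance == 1, ]
    row$ci_lower <= trueMed && trueMed <= row$ci_upper
  }, logical(1))
  # nominal 95%; percentile bootstrap on n = 9 pairs undercovers a little
  expect_gt(mean(hits), 0.85)
})
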