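test_that("mantelTest recovers exact and affine correspondence", {
  v <- randDistMatrix(6)
  r1 <- mantelTest(v, v, nPerm = 99, seed = 1)
  expect_equal(unname(r1$estimate), 1)
  expect_lte(r1$p.value, 0.05)
  w <- 3 * v + 11
  diag(w) <- 0
  expect_equal(unname(mantelTest(v, w, nPerm = 99, seed = 1)$estimate), 1)

  other <- randDistMatrix(6)
  rownames(other) <- colnames(other) <- paste0("x", 1:6)
  expect_error(mantelTest(v, other), "identical unit labels")
  expect_error(mantelTest(v[1:2, 1:2], v[1:2, 1:2]), ">= 3")
})

test_that("mantel r agrees with vegan and p is seed-stable, never zero", {
  skip_if_not_installed("vegan")
  set.seed(61)
  for (rep in 1:5) {
    a <- randDistMatrix(8); b <- randDistMatrix(8)
    mt <- mantelTest(a, b, nPerm = 199, seed = rep)
    vg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 0)
    expect_equal(unname(mt$estimate), unname(vg$statistic),
                 tolerance = 1e-10)
    expect_gt(mt$p.value, 0)
    expect_identical(mt$p.value,
                     mantelTest(a, b, nPerm = 199, seed = rep)$p.value)
  }
})

test_that("mantel p-values are uniform under independence", {
  set.seed(62)
  ps <- vapply(1:300, function(i)
    mantelTest(randDistMatrix(8), randDistMatrix(8), nPerm = 99)$p.value,
    numeric(1))
  rate <- mean(ps <= 0.05)
  ci <- qbinom(c(0.005, 0.995), 300, 0.05) / 300
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("before/after procedure flags trial-specific correspondence and
           stays quiet under the null", {
  set.seed(63)
  runOnce <- function(coupled) {
    nT <- 5; n <- 8
    labs <- paste0("u", 1:n)
    mk <- function() {
      v <- randDistMatrix(n); dimnames(v) <- list(labs, labs); v
    }
    before <- replicate(nT, mk(), simplify = FALSE)
    after <- lapply(before, function(b) {
      if (!coupled) return(mk())
      noise <- matrix(rnorm(n * n, 0, 0.05 * sd(b)), n, n)
      noise <- noise + t(noise); diag(noise) <- 0
      v <- abs(b + noise); dimnames(v) <- dimnames(b); v
    })
    rows <- list()
    for (i in 1:nT) for (j in 1:nT) {
      mt <- mantelTest(before[[i]], after[[j]], nPerm = 99)
      rows[[length(rows) + 1]] <- data.frame(same = i == j,
                                             r = unname(mt$estimate))
    }
    d <- do.call(rbind, rows)
    suppressWarnings(ks.test(d$r[d$same], d$r[!d$same]))$p.value
  }
  powerP <- vapply(1:25, function(i) runOnce(TRUE), numeric(1))
  expect_gt(mean(powerP < 0.05), 0.8)
  nullP <- vapply(1:40, function(i) runOnce(FALSE), numeric(1))
  expect_lt(mean(nullP < 0.05), 0.25)
})

test_that("beforeAfterProcedure runs end to end on synthetic sessions and
           skips degenerate ones", {
  d <- tinyDesign(trialsPerSession = 3, neuronsPerElectrode = 4)
  b <- generateBundles(d)[[1]]
  res <- beforeAfterProcedure(b, nPerm = 49, seed = 5)
  expect_false(isTRUE(res$skipped))
  expect_equal(nrow(res$pairs), 9)
  expect_equal(sum(res$pairs$same_trial), 3)
  expect_true(all(res$pairs$p > 0 & res$pairs$p <= 1))
  expect_true(all(abs(res$pairs$r) <= 1))
  expect_named(res$tests,
               c("r_kruskal_p", "r_ks_p", "p_kruskal_p", "p_ks_p"))

  one <- b
  one@trials <- one@trials[1]
  skip1 <- beforeAfterProcedure(one, nPerm = 49)
  expect_true(skip1$skipped)
  expect_match(skip1$reason, "fewer than 2 trials")
})
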