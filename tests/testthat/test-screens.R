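test_that("normality screen keeps its type-I error near alpha on normal
           d_crit samples", {
  set.seed(41)
  rec <- fakeRecords(200, 10, function(n) rnorm(n, 100, 10))
  sc <- normalityScreen(rec, alpha = 0.05)
  expect_equal(nrow(sc$results), 200)
  rate <- unname(sc$proportion["spike"])
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
})

test_that("normality screen rejects heavy-tailed sessions", {
  set.seed(42)
  rec <- fakeRecords(100, 10, function(n) rlnorm(n, 0, 1))
  sc <- normalityScreen(rec)
  expect_gt(unname(sc$proportion["spike"]), 0.5)
})

test_that("undersized sessions are skipped, not counted", {
  set.seed(43)
  rec <- rbind(fakeRecords(5, 5, rnorm),
               fakeRecords(1, 1, rnorm)[1:2, ])  # 2 observations only
  rec$session_id[11:12] <- "tiny"
  sc <- normalityScreen(rec)
  expect_equal(nrow(sc$results), 5)
  expect_match(sc$skipped$reason, "fewer than 3")
})

test_that("variance screens hold their null rejection rate for both
           methods", {
  set.seed(44)
  rec <- fakeRecords(200, 10, function(n) rnorm(n, 50, 5))
  ci <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  for (m in c("kruskal_wallis", "anova")) {
    # two balanced groups of 10: the asymptotic null holds for both tests
    sc <- varianceScreen(rec, "session", m, groups = "timing")
    rate <- unname(sc$proportion["spike"])
    expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
  }
  # with trials as groups each trial contributes only its two segments;
  # the rank test's chi-square approximation is then strongly
  # conservative — it must never become anticonservative
  for (m in c("kruskal_wallis", "anova"))
    expect_lte(unname(
      varianceScreen(rec, "session", m)$proportion["spike"]), 0.09)
})

test_that("variance screens detect strong between-group shifts", {
  set.seed(45)
  rec <- fakeRecords(40, 8, function(n) rnorm(n, 50, 1))
  rec$d_crit <- rec$d_crit + 10 * rec$trial_index  # large location trend
  for (m in c("kruskal_wallis", "anova")) {
    sc <- varianceScreen(rec, "session", m)
    expect_gt(unname(sc$proportion["spike"]), 0.95)
  }
})

test_that("units with a single group are excluded with the dof reason", {
  set.seed(46)
  rec <- fakeRecords(3, 6, rnorm)
  single <- fakeRecords(1, 6, rnorm)
  single$session_id <- "only_day"
  rec2 <- rbind(rec, single)
  # rat level: rats group over sessions; a second rat with one session
  single$rat_id <- "r2"
  ratRec <- rbind(rec, single)
  sc <- varianceScreen(ratRec, "rat")
  expect_true("dof = 0" %in% sc$skipped$reason)
  expect_equal(nrow(sc$results), 1)  # r1 has 4 sessions, r2 excluded
})

test_that("timing can serve as the grouping variable", {
  set.seed(47)
  rec <- fakeRecords(30, 10, function(n) rnorm(n, 100, 5))
  shift <- rec$timing == "after"
  rec$d_crit[shift] <- rec$d_crit[shift] - 20
  sc <- varianceScreen(rec, "session", groups = "timing")
  expect_gt(unname(sc$proportion["spike"]), 0.9)
})

test_that("proportionTable assembles published-style contingency tables", {
  tab <- proportionTable(c(5, 14), c(1, 14),
                         labels = c("ks_mantel", "dcrit"))
  expect_equal(unname(tab), matrix(c(5, 9, 1, 13), 2, 2, byrow = TRUE))
  expect_equal(rownames(tab), c("ks_mantel", "dcrit"))
  # transposed under row swap
  tab2 <- proportionTable(c(1, 14), c(5, 14))
  expect_equal(unname(tab2), unname(tab[2:1, ]))
  expect_warning(proportionTable(c(0, 0), c(1, 4)), "degenerate")
})

test_that("screens integrate with dtwScreen printing", {
  set.seed(48)
  rec <- fakeRecords(5, 6, rnorm)
  expect_output(print(normalityScreen(rec)), "Shapiro-Wilk")
})
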