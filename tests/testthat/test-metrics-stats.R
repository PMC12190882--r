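test_that("accuracy counts corrections and excludes timeouts", {
  ev <- data.frame(correct = c(rep(TRUE, 10)), timed_out = FALSE)
  expect_equal(accuracy(ev), 100)
  ev <- data.frame(correct = c(TRUE, TRUE, TRUE, FALSE),
                   timed_out = FALSE)
  expect_equal(accuracy(ev), 75)
  ev$timed_out <- c(FALSE, FALSE, FALSE, TRUE)
  ev$correct <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(accuracy(ev), 100)
  expect_error(accuracy(data.frame(correct = logical(0),
                                   timed_out = logical(0))),
               "undefined")
})

test_that("Wolpaw bits match the closed form and its limits", {
  expect_equal(wolpaw_bits(1, 4), 2)
  expect_equal(wolpaw_bits(0.25, 4), 0)
  expect_equal(wolpaw_bits(0.5, 4), 0.2075, tolerance = 1e-4)
  # nondecreasing on [1/N, 1], anchored at chance and perfection
  grid <- seq(0.25, 1, by = 0.01)
  b <- wolpaw_bits(grid, 4)
  expect_true(all(diff(b) >= 0))
  expect_equal(b[1], 0)
  expect_equal(b[length(b)], log2(4))
  expect_error(wolpaw_bits(0.5, 1), "N")
})

test_that("ITR scales with selections per active minute", {
  expect_equal(itr_bits_per_min(1, 4, selections = 30, active_seconds = 60), 60)
  base <- itr_bits_per_min(0.9, 4, 20, 45)
  expect_equal(itr_bits_per_min(0.9, 4, 20, 90), base / 2)
  expect_error(itr_bits_per_min(0.9, 4, 20, 0), "positive")
})

test_that("a simulated run's ITR recomputes from its event log", {
  fx <- trained_fixture()
  res <- with_seed(23L, run_copy_spelling(fx$subject, "BCI", fx$filters,
                                          codes2))
  ev <- res$events
  n_sel <- sum(!ev$timed_out)
  p <- sum(ev$correct) / n_sel
  expect_equal(res$itr,
               wolpaw_bits(p, 4) * n_sel * 60 / sum(ev$latency),
               tolerance = 1e-9)
  expect_equal(res$accuracy, 100 * p, tolerance = 1e-9)
})

test_that("the packaged subject table parses with the published missingness", {
  tab <- load_study_table()
  expect_s3_class(tab, "study_table")
  expect_equal(nrow(tab), 38 * 3)
  present <- tapply(!is.na(tab$accuracy), tab$condition, sum)
  expect_equal(as.vector(present[c("baseline16", "reduced6_noretrain",
                                   "reduced6_retrained")]),
               c(38L, 18L, 23L))
})

test_that("malformed study tables are rejected with a line number", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,accuracy_baseline16,accuracy_reduced6_noretrain,accuracy_reduced6_retrained,itr_baseline16,itr_reduced6_noretrain,itr_reduced6_retrained",
               "1,95.0,90.0,91.0,50.0,40.0,41.0",
               "2,oops,90.0,91.0,50.0,40.0,41.0"), bad)
  expect_error(load_study_table(bad), "line 3")
  worse <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,foo", "1,2"), worse)
  expect_error(load_study_table(worse), "header")
})

test_that("condition summaries reproduce the published means", {
  tab <- load_study_table()
  expect_equal(condition_summary(tab, "baseline16", "accuracy")[["mean"]],
               95.62, tolerance = 5e-3)
  expect_equal(condition_summary(tab, "baseline16", "itr")[["mean"]],
               49.33, tolerance = 5e-3)
  expect_equal(condition_summary(tab, "reduced6_retrained", "accuracy")[["mean"]],
               98.01, tolerance = 5e-3)
  expect_equal(condition_summary(tab, "reduced6_retrained", "itr")[["mean"]],
               48.39, tolerance = 5e-3)
  # a constant column has zero SD
  toy <- data.frame(subject = 1:3, condition = "baseline16",
                    accuracy = c(90, 90, 90), itr = c(50, 50, 50))
  class(toy) <- c("study_table", "data.frame")
  expect_equal(condition_summary(toy, "baseline16", "accuracy")[["sd"]], 0)
  expect_error(condition_summary(tab, "reduced6_noretrain", "nope"))
})

test_that("functionality transitions match the published counts", {
  f <- functionality_and_transitions(load_study_table())
  expect_equal(unname(f$functional), c(38, 18, 23))
  expect_equal(f$regained, 7)
  expect_equal(f$lost, 2)
  expect_equal(f$remained_failed, 13)
  expect_equal(round(unname(f$failure_rate), 1), c(0, 52.6, 39.5))
  # an all-functional table has zero failure everywhere
  toy <- data.frame(subject = rep(1:3, 3),
                    condition = rep(cvepsim:::study_conditions, each = 3),
                    accuracy = 95, itr = 50)
  class(toy) <- c("study_table", "data.frame")
  expect_true(all(functionality_and_transitions(toy)$failure_rate == 0))
})

test_that("the McNemar statistic matches its discordant-count form", {
  expect_equal(mcnemar_chi2(20, 0), 20)
  expect_equal(mcnemar_chi2(15, 0), 15)
  expect_equal(mcnemar_chi2(7, 7), 0)
  expect_equal(mcnemar_chi2(7, 2, corrected = TRUE), 16 / 9)
  expect_error(mcnemar_chi2(0, 0), "undefined")
  # independent oracle: stats::mcnemar.test without continuity correction
  for (bc in list(c(5, 2), c(9, 4), c(3, 3))) {
    tbl <- matrix(c(10, bc[1], bc[2], 12), 2)
    ref <- unname(stats::mcnemar.test(tbl, correct = FALSE)$statistic)
    expect_equal(mcnemar_chi2(bc[1], bc[2]), ref)
  }
})

test_that("Cochran's Q matches independent oracles and degenerates sanely", {
  # the binary-data identity with the Friedman statistic
  set.seed(30)
  for (i in 1:5) {
    mat <- matrix(rbinom(5 * 3, 1, 0.5), 5, 3)
    if (all(apply(mat, 1, function(r) length(unique(r)) == 1))) next
    q <- cochran_q(mat)
    ref <- unname(suppressWarnings(
      stats::friedman.test(mat))$statistic)
    expect_equal(q$Q, ref, tolerance = 1e-9)
    expect_equal(q$df, 2)
  }
  # k = 2 reduces to the uncorrected McNemar statistic
  set.seed(31)
  for (i in 1:5) {
    mat <- matrix(rbinom(10 * 2, 1, 0.5), 10, 2)
    b <- sum(mat[, 1] == 1 & mat[, 2] == 0)
    cc <- sum(mat[, 1] == 0 & mat[, 2] == 1)
    if (b + cc == 0 || all(rowSums(mat) %in% c(0, 2))) next
    expect_equal(cochran_q(mat)$Q, mcnemar_chi2(b, cc), tolerance = 1e-9)
  }
  # identical columns force every row constant: the formula degenerates
  expect_error(cochran_q(matrix(c(1, 0, 1, 0), 2, 2)), "degenerate")
  expect_error(cochran_q(matrix(1, 3, 1)), "two conditions")
  # the fixture's functionality matrix (pattern fixed by the subject table)
  q <- cochran_q(functionality_matrix(load_study_table()))
  expect_equal(q$Q, 29.55, tolerance = 5e-3)
})

test_that("paired effect sizes match manual arithmetic", {
  x <- c(12, 15, 11, 19, 14)
  y <- c(10, 11, 12, 16, 9)
  diff <- x - y
  manual <- mean(diff) / sd(diff)
  res <- cohens_d_paired(x, y, n_boot = 500, seed = 5)
  expect_equal(res$d, manual, tolerance = 1e-12)
  expect_lte(res$ci[1], res$d)
  expect_gte(res$ci[2], res$d)
  expect_equal(cohens_d_paired(x, x, n_boot = 50, seed = 1)$d, 0)
  expect_error(cohens_d_paired(x, x - 3, n_boot = 50, seed = 1),
               "zero variance")
  expect_error(cohens_d_paired(1:2, 2:3), "length")
})

test_that("correlation helpers reduce to Pearson correlation", {
  x <- c(1.5, 2.2, 3.9, 4.1, 5.7)
  expect_equal(stats::cor(x, 2 * x), 1)
  g <- c(0, 1, 0, 1, 1)
  expect_equal(point_biserial(x, g), stats::cor(x, g))
  expect_equal(point_biserial(x, g == 1), stats::cor(x, g))
})

test_that("the fixture report reproduces every determined summary", {
  rep <- reproduce_fixture_report()
  expect_equal(rep$functional$baseline16, 38)
  expect_equal(rep$functional$reduced6_noretrain, 18)
  expect_equal(rep$functional$reduced6_retrained, 23)
  expect_equal(rep$mcnemar$baseline_vs_noretrain$chi2, 20)
  expect_equal(rep$mcnemar$baseline_vs_retrained$chi2, 15)
  expect_equal(rep$regained, 7)
  expect_equal(rep$lost, 2)
  expect_equal(rep$remained_failed, 13)
})
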