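test_that("confusion metrics match the direct formulas", {
  truth <- rep(c(TRUE, FALSE), c(100, 100))
  pred <- rep(c(TRUE, FALSE, FALSE, TRUE), c(90, 10, 80, 20))
  cm <- confusion_metrics(truth, pred)
  expect_identical(c(cm$tp, cm$fn, cm$tn, cm$fp), c(90L, 10L, 80L, 20L))
  expect_equal(cm$sensitivity, 90)
  expect_equal(cm$specificity, 80)
  expect_equal(cm$balanced_accuracy, 85)
  expect_equal(round_half_up(cm$ppv, 1), 81.8)
  expect_equal(round_half_up(cm$npv, 1), 88.9)
  expect_length(cm$undefined, 0)
})

test_that("perfect predictions score 100 on all five metrics", {
  truth <- rep(c(TRUE, FALSE), 10)
  cm <- confusion_metrics(truth, truth)
  for (f in c("sensitivity", "specificity", "balanced_accuracy",
              "ppv", "npv"))
    expect_equal(cm[[f]], 100)
})

test_that("zero denominators are flagged, never silently zero", {
  cm <- confusion_metrics(rep(FALSE, 5), rep(FALSE, 5))
  expect_equal(cm$specificity, 100)
  expect_true(is.na(cm$sensitivity))
  expect_true(all(c("sensitivity", "balanced_accuracy", "ppv") %in%
                    cm$undefined))
  expect_error(confusion_metrics(logical(0), logical(0)), "empty")
  expect_error(confusion_metrics(c(TRUE), c(TRUE, FALSE)), "differ")
})

test_that("balanced accuracy is exactly the sensitivity/specificity mean", {
  set.seed(31)
  for (k in 1:20) {
    n <- 50
    truth <- runif(n) < 0.6
    pred <- xor(truth, runif(n) < 0.2)
    if (!any(truth) || all(truth)) next
    cm <- confusion_metrics(truth, pred)
    expect_identical(cm$balanced_accuracy,
                     (cm$sensitivity + cm$specificity) / 2)
    # permutation invariance
    o <- sample(n)
    cm2 <- confusion_metrics(truth[o], pred[o])
    expect_identical(unclass(cm)[1:9], unclass(cm2)[1:9])
  }
})

test_that("grade accuracy is exact-match percent over the 7-letter domain", {
  expect_equal(grade_accuracy(c("A", "B", "C"), c("A", "B", "C")), 100)
  expect_equal(grade_accuracy(rep("A", 10), c(rep("A", 9), "B")), 90)
  set.seed(5)
  for (k in 1:10) {
    a <- sample(c("A", "B", "C", "D", "E", "U", "F"), 30, replace = TRUE)
    b <- sample(c("A", "B", "C", "D", "E", "U", "F"), 30, replace = TRUE)
    expect_equal(grade_accuracy(a, b), 100 * sum(a == b) / 30)
  }
  expect_error(grade_accuracy(c("A", "Z"), c("A", "A")), "invalid grade")
  expect_error(grade_accuracy(c("A"), c("A", "B")), "length")
})

test_that("proportion comparison matches the textbook chi-squared", {
  tr <- monthly_quality_comparison(data.frame(
    label = c("g1", "g2"), num = c(50, 50), den = c(100, 100)))
  expect_equal(tr$chi2, 0)
  expect_equal(tr$p_value, 1)

  tr2 <- monthly_quality_comparison(data.frame(
    label = c("g1", "g2"), num = c(10, 19), den = c(20, 20)))
  # hand-computed Pearson statistic without continuity correction
  o <- matrix(c(10, 10, 19, 1), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi2_hand <- sum((o - e)^2 / e)
  expect_equal(tr2$chi2, chi2_hand, tolerance = 1e-12)
  expect_equal(tr2$p_value, stats::pchisq(chi2_hand, 1, lower.tail = FALSE))

  expect_error(monthly_quality_comparison(data.frame(
    label = "g1", num = 1, den = 2)), "at least 2")
  expect_error(monthly_quality_comparison(data.frame(
    label = c("a", "b"), num = c(1, 1), den = c(0, 2))), "denominator")
})

test_that("run_batch writes reports and skips corrupt files", {
  d <- withr::local_tempdir()
  paths <- character()
  for (i in 1:3) {
    g <- generate_session(list(maneuver_spec(seed = i),
                               maneuver_spec(seed = i + 10),
                               maneuver_spec(seed = i + 20)),
                          sprintf("s%d", i))
    p <- file.path(d, sprintf("s%d.json", i))
    write_session(g$session, p)
    paths <- c(paths, p)
  }
  bad <- file.path(d, "bad.json")
  writeLines("{broken", bad)
  out <- suppressMessages(
    run_batch(c(paths, bad), report_dir = file.path(d, "rep")))
  expect_identical(out$n_ok, 3L)
  expect_identical(out$n_skipped, 1L)
  expect_true(file.exists(file.path(d, "rep", "s1_qc.json")))
  expect_true(file.exists(file.path(d, "rep", "maneuvers.csv")))
  expect_identical(nrow(out$table), 9L)
  # clean sessions carry no warnings
  expect_true(all(out$table$fev1_acceptable))
})

test_that("batch evaluation against truth reaches high balanced accuracy", {
  d <- withr::local_tempdir()
  co <- generate_cohort(40, quality_profile = 0.45, seed = 17)
  paths <- vapply(co$sessions, function(s) {
    p <- file.path(d, paste0(s$session_id, ".json"))
    write_session(s, p)
    p
  }, character(1))
  tp <- file.path(d, "truth.json")
  write_truth(co$truth, tp)
  out <- suppressWarnings(
    run_batch(paths, truth_path = tp, report_dir = file.path(d, "rep")))
  expect_true(file.exists(file.path(d, "rep", "evaluation.json")))
  for (fl in names(out$metrics)) {
    ba <- out$metrics[[fl]]$balanced_accuracy
    expect_false(is.na(ba))
    expect_gte(ba, 90)
  }
  expect_gte(min(out$grade_accuracy), 90)
})
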