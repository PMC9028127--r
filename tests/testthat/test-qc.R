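test_that("a clean maneuver passes every criterion", {
  m <- exp_maneuver()
  ind <- compute_indices(m)
  q <- assess_maneuver(ind, scan_artifacts(m, ind))
  expect_true(q$fev1_acceptable && q$fev1_usable &&
                q$fvc_acceptable && q$fvc_usable)
  expect_true(all(q$reasons$passed))
})

test_that("a first-second cough fails FEV1 but leaves FVC intact", {
  q <- assess_maneuver(fake_indices(), finding_row("cough", 0.5, 0.8))
  expect_false(q$fev1_usable)
  expect_false(q$fev1_acceptable)
  expect_true(q$fvc_usable)
  expect_true(q$fvc_acceptable)
  expect_false(q$reasons$passed[q$reasons$criterion == "cough_first_second"])
})

test_that("late glottic closure fails FVC acceptability only", {
  ind <- fake_indices(plateau = FALSE, eofe = FALSE, fet = 2.5)
  q <- assess_maneuver(ind, finding_row("glottic_closure", 2.4, 2.9))
  expect_true(q$fev1_usable && q$fev1_acceptable)
  expect_false(q$fvc_acceptable)
  expect_true(q$fvc_usable)
})

test_that("an extra breath corrupts FVC and, early, FEV1 acceptability", {
  q <- assess_maneuver(fake_indices(), finding_row("extra_breath", 0.6, 0.9))
  expect_false(q$fev1_acceptable)
  expect_true(q$fev1_usable)
  expect_false(q$fvc_usable)
  q2 <- assess_maneuver(fake_indices(), finding_row("extra_breath", 3.0, 3.4))
  expect_true(q2$fev1_acceptable)
  expect_false(q2$fvc_usable)
})

test_that("the session-level repeatability branch rescues EOFE", {
  ind <- fake_indices(plateau = FALSE, eofe = FALSE, fet = 4)
  q1 <- assess_maneuver(ind, no_findings)
  expect_false(q1$fvc_acceptable)
  q2 <- assess_maneuver(ind, no_findings, best_fvc_delta = 0.05)
  expect_true(q2$fvc_acceptable)
})

test_that("findings outside the recorded span are rejected", {
  expect_error(assess_maneuver(fake_indices(t_last = 3),
                               finding_row("cough", 2.5, 3.6)),
               "outside the maneuver")
})

test_that("acceptable implies usable on randomized inputs", {
  set.seed(42)
  kinds <- c("cough", "glottic_closure", "flutter_obstruction",
             "early_termination", "extra_breath")
  for (k in 1:40) {
    n <- sample(0:3, 1)
    f <- if (n == 0) no_findings else {
      do.call(rbind, lapply(seq_len(n), function(i) {
        a <- runif(1, 0, 5)
        finding_row(sample(kinds, 1), a, a + runif(1, 0.1, 1))
      }))
    }
    ind <- fake_indices(bev = runif(1, 0, 0.3),
                        plateau = sample(c(TRUE, FALSE), 1),
                        fet = runif(1, 2, 8), t_last = 7)
    ind$eofe_met <- ind$plateau
    q <- assess_maneuver(ind, f)
    expect_true(!q$fev1_acceptable || q$fev1_usable)
    expect_true(!q$fvc_acceptable || q$fvc_usable)
  }
})

test_that("session grades follow the rating decision table", {
  mk <- function(n_acc, n_use, nm = 3) {
    lapply(seq_len(max(nm, n_use)), function(i)
      qc_stub(i <= n_acc, i <= n_use, i <= n_acc, i <= n_use))
  }
  vals <- function(n, delta) {
    v <- rep(4.0 - delta - 0.3, n)
    if (n >= 1) v[1] <- 4.0
    if (n >= 2) v[2] <- 4.0 - delta
    v
  }
  g <- grade_session(mk(3, 3), vals(3, 0.05), vals(3, 0.05))
  expect_identical(g$fev1_grade, "A")
  g <- grade_session(mk(2, 3), c(3.30, 3.12, NA), c(3.30, 3.12, NA))
  expect_identical(g$fev1_grade, "C")
  g <- grade_session(mk(0, 2), rep(NA_real_, 3), rep(NA_real_, 3))
  expect_identical(g$fev1_grade, "U")
  g <- grade_session(mk(0, 0), rep(NA_real_, 3), rep(NA_real_, 3))
  expect_identical(g$fev1_grade, "F")
  expect_error(grade_session(list(), numeric(0), numeric(0)), "no maneuver")
})

test_that("grade_session agrees with the enumeration oracle", {
  for (n_man in 3:4) {
    for (n_acc in 0:n_man) {
      for (n_use in n_acc:n_man) {
        for (delta in c(0.05, 0.16, 0.21, 0.26)) {
          qcs <- lapply(seq_len(n_man), function(i)
            qc_stub(i <= n_acc, i <= n_use, i <= n_acc, i <= n_use))
          v <- rep(3.0, n_man)
          if (n_acc >= 1) v[1] <- 4.0
          if (n_acc >= 2) v[2] <- 4.0 - delta
          g <- grade_session(qcs, v, v)
          want <- oracle_grade(n_acc, n_use,
                               if (n_acc >= 2) delta else 0)
          expect_identical(g$fev1_grade, want)
          expect_identical(g$fvc_grade, want)
          # pediatric tiers
          gp <- grade_session(qcs, v, v, subject_age = 5)
          expect_identical(gp$fev1_grade,
                           oracle_grade(n_acc, n_use,
                                        if (n_acc >= 2) delta else 0,
                                        pediatric = TRUE))
        }
      }
    }
  }
})

test_that("improving one maneuver never worsens the grade when values repeat", {
  # monotonicity holds whenever the newly admitted value does not widen the
  # top-two repeatability gap, i.e. for values within one tier of each other
  rank <- function(g) match(g, c("A", "B", "C", "D", "E", "U", "F"))
  set.seed(11)
  for (k in 1:30) {
    acc <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    use <- acc | sample(c(TRUE, FALSE), 3, replace = TRUE)
    v <- round(runif(3, 3.80, 3.90), 2)
    qcs <- lapply(1:3, function(i) qc_stub(acc[i], use[i], acc[i], use[i]))
    g0 <- grade_session(qcs, v, v)
    i <- which(!acc)[1]
    if (is.na(i)) next
    qcs2 <- qcs
    qcs2[[i]] <- qc_stub(TRUE, TRUE, TRUE, TRUE)
    g1 <- grade_session(qcs2, v, v)
    expect_lte(rank(g1$fev1_grade), rank(g0$fev1_grade))
  }
})

test_that("messages deduplicate by criterion and prompt on low grades", {
  m <- exp_maneuver()
  ind <- compute_indices(m)
  clean_q <- assess_maneuver(ind, no_findings)
  g <- grade_session(list(clean_q, clean_q, clean_q),
                     rep(3.67, 3), rep(4.0, 3))
  msg <- generate_messages(list(clean_q, clean_q, clean_q), g)
  expect_length(msg$messages, 0)
  expect_length(msg$guidance, 0)

  coughed <- assess_maneuver(fake_indices(), finding_row("cough", 0.5, 0.8))
  g2 <- grade_session(list(coughed, coughed, clean_q),
                      c(NA, NA, 3.67), rep(4.0, 3))
  msg2 <- generate_messages(list(coughed, coughed, clean_q), g2)
  cat_tab <- qc_criteria()
  cough_msg <- cat_tab$operator_message[cat_tab$criterion == "cough_first_second"]
  expect_identical(sum(msg2$messages == cough_msg), 1L)

  # grade below C prompts a repeat, messages independent of maneuver order
  expect_true(any(grepl("additional maneuver", msg2$messages)))
  msg2r <- generate_messages(list(clean_q, coughed, coughed), g2)
  expect_identical(msg2$messages, msg2r$messages)
})

test_that("assess_session runs the full two-pass pipeline", {
  tt <- seq(0, 8, by = 0.01)
  mk <- function(id, fvc) maneuver(id, volume = fvc * (1 - exp(-tt / 0.45)),
                                   flow = fvc / 0.45 * exp(-tt / 0.45))
  rep <- assess_session(session("s1", list(mk("m1", 4.00), mk("m2", 3.96),
                                           mk("m3", 4.03))))
  expect_identical(rep$grade$fev1_grade, "A")
  expect_identical(rep$grade$fvc_grade, "A")
  expect_length(rep$grade$messages, 0)

  g <- generate_session(list(
    maneuver_spec(seed = 1),
    maneuver_spec(seed = 2),
    maneuver_spec(seed = 3, artifacts = list(
      artifact_spec("cough", onset = 0.5, magnitude = 0.45)))), "s2")
  rep2 <- assess_session(g$session)
  expect_identical(rep2$grade$n_fev1_acceptable, 2L)
  expect_identical(rep2$grade$n_fvc_acceptable, 3L)
})

test_that("QC reports serialize to JSON and a flat audit table", {
  g <- generate_session(list(maneuver_spec(seed = 1), maneuver_spec(seed = 2),
                             maneuver_spec(seed = 3)), "s1")
  rep <- assess_session(g$session)
  p <- withr::local_tempfile(fileext = ".json")
  write_qc_report(rep, p)
  doc <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_identical(doc$session_id, "s1")
  expect_length(doc$maneuvers, 3)
  tab <- qc_report_table(rep)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$fev1_acceptable))
})
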