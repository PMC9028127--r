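test_that("clean maneuvers produce no findings", {
  m <- exp_maneuver()
  expect_identical(nrow(scan_artifacts(m, compute_indices(m))), 0L)
  for (seed in c(3, 11)) {
    g <- generate_maneuver(maneuver_spec(seed = seed), "m")
    expect_identical(
      nrow(scan_artifacts(g$maneuver, compute_indices(g$maneuver))), 0L)
  }
})

test_that("an injected cough is found at its onset", {
  g <- inject1("cough", onset = 0.6, magnitude = 0.4)
  f <- detect_cough(g$maneuver, compute_indices(g$maneuver))
  expect_identical(nrow(f), 1L)
  expect_lte(f$t_start, 0.6)
  expect_gte(f$t_end, 0.6)
  expect_true(f$score > 0 && f$score <= 1)
})

test_that("two coughs yield two disjoint findings in time order", {
  sp <- maneuver_spec(fvc_true = 4.4, pef_true = 5, tau = 0.88,
                      rise_time = 0.05, noise_sd = 0,
                      artifacts = list(
                        artifact_spec("cough", onset = 0.5, magnitude = 0.4),
                        artifact_spec("cough", onset = 2.0, magnitude = 0.4)))
  g <- generate_maneuver(sp, "m")
  f <- detect_cough(g$maneuver, compute_indices(g$maneuver))
  expect_identical(nrow(f), 2L)
  expect_lt(f$t_end[1], f$t_start[2])
  expect_true(f$t_start[1] <= 0.5 && 0.5 <= f$t_end[1])
  expect_true(f$t_start[2] <= 2.0 && 2.0 <= f$t_end[2])
})

test_that("cough amplitude monotonicity: stronger coughs never vanish", {
  for (mag in seq(0.35, 0.6, by = 0.05)) {
    g <- inject1("cough", onset = 0.6, magnitude = mag, seed = 5)
    f <- detect_cough(g$maneuver, compute_indices(g$maneuver))
    expect_gte(nrow(f), 1L)
  }
})

test_that("glottic closure is localized at the cessation", {
  m <- exp_maneuver()
  expect_identical(nrow(detect_glottic_closure(m, compute_indices(m))), 0L)

  # sharp stop on a slow-decay 4-L maneuver while flow is still high
  g <- inject1("glottic_closure", onset = 1.8, fvc = 4, pef = 4.5,
               tau = 0.8, rise = 0, noise = 0)
  f <- detect_glottic_closure(g$maneuver, compute_indices(g$maneuver))
  expect_identical(nrow(f), 1L)
  expect_lt(abs(f$t_start - 1.8), 0.05)

  # closure inside the first second drives FEV1 non-usability downstream
  g <- inject1("glottic_closure", onset = 0.7)
  f <- detect_glottic_closure(g$maneuver, compute_indices(g$maneuver))
  expect_identical(nrow(f), 1L)
  expect_lt(f$t_start, 1.0)
})

test_that("flutter is found over its injected window, not below threshold", {
  g <- inject1("flutter_obstruction", onset = 1.0, magnitude = 0.25,
               duration = 1.0, fvc = 4.4, pef = 5, tau = 0.88, noise = 0)
  ind <- compute_indices(g$maneuver)
  f <- detect_flutter(g$maneuver, ind)
  expect_identical(nrow(f), 1L)
  covered <- min(f$t_end, 2.0) - max(f$t_start, 1.0)
  expect_gte(covered, 0.8)

  g5 <- inject1("flutter_obstruction", onset = 1.0, magnitude = 0.05,
                duration = 1.0, fvc = 4.4, pef = 5, tau = 0.88, noise = 0)
  expect_identical(
    nrow(detect_flutter(g5$maneuver, compute_indices(g5$maneuver))), 0L)
})

test_that("early termination fires only when EOFE has no other route", {
  # truncated ramp: neither plateau nor long FET
  m <- ramp_maneuver(slope = 2, t_end = 1)
  ind <- compute_indices(m)
  f <- detect_early_termination(m, ind)
  expect_identical(nrow(f), 1L)
  expect_equal(f$t_start, max(0, ind$fet - 1) + ind$t0, tolerance = 0.02)
  expect_equal(f$t_end, ind$t0 + ind$fet, tolerance = 0.02)

  # a full exponential reaches its plateau
  m <- exp_maneuver()
  expect_identical(nrow(detect_early_termination(m, compute_indices(m))), 0L)

  # a 15.5-s slow blow without plateau satisfies EOFE via long FET
  m <- ramp_maneuver(slope = 0.2, t_end = 15.5)
  ind <- compute_indices(m)
  expect_false(ind$plateau)
  expect_identical(nrow(detect_early_termination(m, ind)), 0L)
})

test_that("an extra breath needs resumed expiration to count", {
  m <- exp_maneuver()
  expect_identical(nrow(detect_extra_breath(m)), 0L)

  g <- inject1("extra_breath", onset = 3.0, magnitude = 0.2, noise = 0)
  f <- detect_extra_breath(g$maneuver)
  expect_identical(nrow(f), 1L)
  expect_true(f$t_start <= 3.0 + 0.4 && 3.0 <= f$t_end + 0.1)

  # terminal inspiration with no resumed expiration: recording just ends
  tt <- seq(0, 3, by = 0.01)
  fl <- 4 * exp(-tt / 0.4)
  fl[tt > 2.6] <- -0.3
  vol <- cumsum(c(0, (fl[-1] + fl[-length(fl)]) / 2 * 0.01))
  m <- suppressWarnings(maneuver("ti", volume = vol, flow = fl))
  expect_identical(nrow(detect_extra_breath(m)), 0L)
})

test_that("start-quality findings follow the BEV and tPEF thresholds", {
  expect_identical(nrow(detect_start_quality(fake_indices(bev = 0, tpef = 0))),
                   0L)
  f <- detect_start_quality(fake_indices(bev = 0.25, fvc = 4.0))
  expect_identical(f$kind, "hesitant_start")
  expect_identical(
    nrow(detect_start_quality(fake_indices(bev = 0.15, fvc = 4.0,
                                           tpef = 0.05))), 0L)
  f <- detect_start_quality(fake_indices(bev = 0.05, fvc = 4.0, tpef = 0.30))
  expect_identical(f$kind, "variable_flow")
})

test_that("the combined scan orders and disambiguates findings", {
  sp <- maneuver_spec(fvc_true = 4.5, pef_true = 3.4, tau = 1.3,
                      rise_time = 0.05, noise_sd = 0.02,
                      artifacts = list(
                        artifact_spec("cough", onset = 0.6, magnitude = 0.45),
                        artifact_spec("glottic_closure", onset = 2.5)),
                      seed = 9)
  g <- generate_maneuver(sp, "m")
  f <- scan_artifacts(g$maneuver, compute_indices(g$maneuver))
  expect_true(all(c("cough", "glottic_closure") %in% f$kind))
  expect_lt(f$t_start[match("cough", f$kind)],
            f$t_start[match("glottic_closure", f$kind)])
  expect_true(!is.unsorted(f$t_start))
  # intervals lie within the recording
  expect_true(all(f$t_start >= 0) &&
                all(f$t_end <= max(g$maneuver$t) + 1e-9))
})

test_that("detector output is deterministic and translation-equivariant", {
  g <- inject1("cough", onset = 0.6, magnitude = 0.4, seed = 3)
  m <- g$maneuver
  ind <- compute_indices(m)
  expect_identical(scan_artifacts(m, ind), scan_artifacts(m, ind))

  shift <- 20L
  m2 <- maneuver("sh", volume = c(rep(0, shift), m$volume),
                 flow = c(rep(0, shift), m$flow),
                 sample_interval = m$sample_interval)
  f1 <- scan_artifacts(m, ind)
  f2 <- scan_artifacts(m2, compute_indices(m2))
  expect_identical(f1$kind, f2$kind)
  expect_equal(f2$t_start, f1$t_start + 0.2, tolerance = 0.06)
  expect_equal(f2$t_end, f1$t_end + 0.2, tolerance = 0.06)
})
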