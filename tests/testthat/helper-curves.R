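# Builders used across the suite. All curves are constructed from closed
# forms so tests can compare against analytic values.

# Single-exponential forced expiration: V(t) = fvc (1 - exp(-t/tau)),
# flow supplied analytically so PEF is exact.
exp_maneuver <- function(fvc = 4, tau = 0.4, t_end = 12, dt = 0.01,
                         id = "exp") {
  tt <- seq(0, t_end, by = dt)
  maneuver(id, volume = fvc * (1 - exp(-tt / tau)),
           flow = fvc / tau * exp(-tt / tau), sample_interval = dt)
}

# Linear ramp V(t) = slope * t, truncated at t_end.
ramp_maneuver <- function(slope = 2, t_end = 1, dt = 0.01, id = "ramp") {
  tt <- seq(0, t_end, by = dt)
  maneuver(id, volume = slope * tt, sample_interval = dt)
}

# One maneuver with a single injected artifact at strong strength.
inject1 <- function(kind, ..., fvc = 4, pef = 8, tau = 0.5, rise = 0.05,
                    noise = 0.02, seed = 42, id = "m") {
  sp <- maneuver_spec(fvc_true = fvc, pef_true = pef, tau = tau,
                      rise_time = rise, noise_sd = noise,
                      artifacts = list(artifact_spec(kind, ...)),
                      seed = seed)
  generate_maneuver(sp, maneuver_id = id)
}

# Fake indices object for decision-table tests that need no real curve.
fake_indices <- function(t0 = 0, bev = 0.02, fev1 = 3.5, fvc = 4.0,
                         pef = 8, tpef = 0.05, fet = 6, plateau = TRUE,
                         eofe = plateau, t_last = 8) {
  structure(
    list(maneuver_id = "fake", t0 = t0, bev = bev, fev1 = fev1, fvc = fvc,
         pef = pef, tpef = tpef, fet = fet, plateau = plateau,
         plateau_onset = if (plateau) 3 else NA_real_, eofe_met = eofe,
         t_end_record = t_last, t_end_expiration = min(t0 + fet, t_last),
         t_last = t_last, sample_interval = 0.01),
    class = "spiro_indices")
}

# Hand-made findings row(s) compatible with assess_maneuver().
finding_row <- function(kind, t_start, t_end, v = 1, score = 0.8) {
  data.frame(kind = kind, t_start = t_start, t_end = t_end,
             v_at_onset = v, score = score, stringsAsFactors = FALSE)
}

no_findings <- finding_row("cough", 1, 2)[0, ]

# Independently transcribed session-rating decision table: grade from the
# number of acceptable/usable maneuvers and the repeatability delta.
# Deliberately written as a flat rule list, separate from grade_session().
oracle_grade <- function(n_acc, n_usable, delta, pediatric = FALSE) {
  tiers <- if (pediatric) c(0.100, 0.150, 0.200) else c(0.150, 0.200, 0.250)
  if (n_acc >= 3 && delta <= tiers[1]) return("A")
  if (n_acc == 2 && delta <= tiers[1]) return("B")
  if (n_acc >= 2 && delta <= tiers[2]) return("C")
  if (n_acc >= 2 && delta <= tiers[3]) return("D")
  if (n_acc >= 2) return("E")
  if (n_acc == 1) return("E")
  if (n_usable >= 1) return("U")
  "F"
}

# Build a list of maneuver-QC stubs with given per-index flags.
qc_stub <- function(fev1_acc, fev1_use, fvc_acc, fvc_use) {
  structure(list(maneuver_id = "stub",
                 fev1_acceptable = fev1_acc, fev1_usable = fev1_use,
                 fvc_acceptable = fvc_acc, fvc_usable = fvc_use,
                 reasons = data.frame(criterion = character(),
                                      index = character(),
                                      effect = character(),
                                      passed = logical(),
                                      detail = character())),
            class = "spiro_maneuver_qc")
}
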