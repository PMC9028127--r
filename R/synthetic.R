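# Synthetic forced-expiration maneuvers with ground-truth labels.
#
# Physiology template: flow rises linearly to PEF over `rise_time`, then
# decays as dV/dt = (fvc_true - V)/tau, scaled so flow is continuous at
# the junction. The scaled tail is exponential with effective constant
# tau_eff = (fvc_true - V_rise)/pef_true, which gives closed forms for
# volume, FEV1 and FVC that the index layer can be checked against.
# Artifacts are injected by kind-specific transforms of the flow series;
# Gaussian flow noise is added last and volume is the exact trapezoidal
# integral of the final flow, so flow-volume consistency holds by
# construction.

SYNTH_KINDS <- c("cough", "glottic_closure", "flutter_obstruction",
                 "early_termination", "extra_breath", "hesitant_start")

# Documented "strong regime" injector defaults per kind: magnitudes and
# onsets in these ranges are reliably visible to the detectors and
# reliably violate the QC rule they target.
SYNTH_DEFAULTS <- list(
  cough = list(magnitude = 0.4, duration = 0.25),
  glottic_closure = list(magnitude = NA_real_, duration = NA_real_),
  flutter_obstruction = list(magnitude = 0.25, duration = 1.0),
  early_termination = list(magnitude = NA_real_, duration = NA_real_),
  extra_breath = list(magnitude = 0.2, duration = 0.4),
  hesitant_start = list(magnitude = 0.3, duration = NA_real_)
)

#' Specify an artifact to inject
#'
#' @param kind one of \code{cough}, \code{glottic_closure},
#'   \code{flutter_obstruction}, \code{early_termination},
#'   \code{extra_breath}, \code{hesitant_start}.
#' @param onset seconds on the template axis (the start of the forced
#'   blast; a hesitant-start prefix shifts recorded times). Ignored for
#'   \code{hesitant_start}, which always sits at the start.
#' @param magnitude kind-dependent: fractional flow drop for \code{cough}
#'   (strong regime 0.35-0.6), fractional oscillation amplitude for
#'   \code{flutter_obstruction} (0.2-0.35), liters re-inhaled for
#'   \code{extra_breath} (0.15-0.3), liters exhaled slowly before the
#'   blast for \code{hesitant_start} (0.25-0.4). Unused for
#'   \code{glottic_closure} and \code{early_termination}.
#' @param duration seconds, where applicable.
#' @return A list of class \code{"artifact_spec"}.
#' @export
artifact_spec <- function(kind, onset = 0, magnitude = NULL,
                          duration = NULL) {
  kind <- match.arg(kind, SYNTH_KINDS)
  d <- SYNTH_DEFAULTS[[kind]]
  if (is.null(magnitude)) magnitude <- d$magnitude
  if (is.null(duration)) duration <- d$duration
  if (!is.numeric(onset) || length(onset) != 1L || onset < 0)
    stop("artifact onset must be a single non-negative number", call. = FALSE)
  if (!is.na(magnitude) && magnitude <= 0)
    stop("artifact magnitude must be positive", call. = FALSE)
  if (!is.na(duration) && duration <= 0)
    stop("artifact duration must be positive", call. = FALSE)
  structure(list(kind = kind, onset = onset, magnitude = magnitude,
                 duration = duration),
            class = "artifact_spec")
}

#' Specify a synthetic maneuver
#'
#' @param fvc_true total exhalable volume of the template, liters.
#' @param pef_true peak expiratory flow of the template, L/s.
#' @param tau nominal decay constant of the volume ODE, seconds (the
#'   continuity scaling makes the realized tail constant
#'   \code{(fvc_true - V_rise)/pef_true}).
#' @param rise_time seconds of linear flow rise to PEF.
#' @param noise_sd Gaussian flow noise, L/s.
#' @param artifacts list of [artifact_spec()] objects.
#' @param seed integer seed for the maneuver's noise stream.
#' @return A list of class \code{"maneuver_spec"}.
#' @export
maneuver_spec <- function(fvc_true = 4.0, pef_true = 8.0, tau = 0.5,
                          rise_time = 0.05, noise_sd = 0.02,
                          artifacts = list(), seed = 1L) {
  stopifnot(fvc_true > 0, pef_true > 0, tau > 0, rise_time >= 0,
            noise_sd >= 0)
  if (!is.list(artifacts) ||
      (length(artifacts) &&
       !all(vapply(artifacts, inherits, logical(1), "artifact_spec"))))
    stop("artifacts must be a list of artifact_spec objects", call. = FALSE)
  v_rise <- 0.5 * pef_true * rise_time
  if (v_rise >= fvc_true)
    stop("rise phase alone exceeds fvc_true", call. = FALSE)
  structure(list(fvc_true = fvc_true, pef_true = pef_true, tau = tau,
                 rise_time = rise_time, noise_sd = noise_sd,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "maneuver_spec")
}

# Template closed forms (template axis s = time since blast start).
# `f0` is the flow level at s = 0: zero normally, the hesitant-start
# prefix flow when a prefix precedes the blast (keeps flow continuous).
template_funs <- function(spec, f0 = 0) {
  tr <- spec$rise_time
  pef <- spec$pef_true
  v_rise <- 0.5 * (f0 + pef) * tr
  tau_eff <- (spec$fvc_true - v_rise) / pef
  flow <- function(s) {
    ifelse(s < 0, f0,
           ifelse(s <= tr & tr > 0, f0 + (pef - f0) * s / max(tr, 1e-12),
                  pef * exp(-(pmax(s, tr) - tr) / tau_eff)))
  }
  vol <- function(s) {
    ifelse(s < 0, 0,
           ifelse(s <= tr & tr > 0,
                  f0 * s + 0.5 * (pef - f0) * s^2 / max(tr, 1e-12),
                  spec$fvc_true -
                    (spec$fvc_true - v_rise) *
                    exp(-(pmax(s, tr) - tr) / tau_eff)))
  }
  # record until the trailing 1-s volume change falls well below the
  # plateau threshold, so clean maneuvers plateau robustly under noise
  dv_target <- 0.01
  t_nat <- tr + tau_eff *
    log(spec$pef_true * tau_eff * (exp(1 / tau_eff) - 1) / dv_target)
  list(flow = flow, vol = vol, tau_eff = tau_eff, v_rise = v_rise,
       t_nat = max(t_nat, tr + 1.2) + 0.3)
}

#' Generate one synthetic maneuver with its ground truth
#'
#' Builds the two-phase template, applies the requested artifact
#' transforms in onset order (cough: multiplicative dip-and-rebound;
#' glottic closure: flow ramped to zero at onset, record kept 0.5 s
#' beyond; flutter: additive band-limited sinusoid at 10 Hz; extra breath:
#' inspiratory half-sine re-inhaling \code{magnitude} liters followed by a
#' compensating expiratory bump; hesitant start: constant 0.5 L/s prefix
#' exhaling \code{magnitude} liters before the blast; early termination:
#' truncation at onset), adds seeded Gaussian flow noise, and integrates
#' flow to volume.
#'
#' @param spec a [maneuver_spec()].
#' @param maneuver_id id for the generated maneuver.
#' @param config a [spiro_config()] list.
#' @return A list with elements \code{maneuver} (a [maneuver()]) and
#'   \code{truth}: injected artifact table (onsets on the recording's time
#'   axis), the template's intended \code{t0}, \code{fev1}, \code{fvc},
#'   whether a plateau is expected, and the expected per-maneuver QC flags
#'   (the FVC-acceptability flag still needs the session-level
#'   repeatability resolution done by [generate_session()]).
#' @examples
#' g <- generate_maneuver(maneuver_spec(fvc_true = 4, pef_true = 10,
#'                                      tau = 0.4, rise_time = 0,
#'                                      noise_sd = 0), "m1")
#' max(abs(g$maneuver$volume - 4 * (1 - exp(-g$maneuver$t / 0.4))))
#' @export
generate_maneuver <- function(spec, maneuver_id = "m1", config = NULL) {
  cfg <- as_config(config)
  if (!inherits(spec, "maneuver_spec")) stop("not a maneuver_spec", call. = FALSE)
  dt <- cfg$sample_interval
  arts <- spec$artifacts
  kinds <- vapply(arts, `[[`, character(1), "kind")
  uniq <- c("glottic_closure", "early_termination", "hesitant_start")
  if (anyDuplicated(kinds[kinds %in% uniq]))
    stop("at most one glottic_closure / early_termination / hesitant_start ",
         "per maneuver", call. = FALSE)

  # hesitant-start prefix shifts the template axis; the blast then rises
  # from the prefix flow so the series has no artificial discontinuity
  d_p <- 0
  hes <- Find(function(a) a$kind == "hesitant_start", arts)
  if (!is.null(hes)) d_p <- round(hes$magnitude / 0.5 / dt) * dt
  tf <- template_funs(spec, f0 = if (d_p > 0) 0.5 else 0)
  bad <- vapply(arts, function(a)
    a$kind != "hesitant_start" && a$onset >= tf$t_nat, logical(1))
  if (any(bad))
    stop("artifact onset beyond the end of the curve", call. = FALSE)

  rec_end <- tf$t_nat
  et <- Find(function(a) a$kind == "early_termination", arts)
  gc_a <- Find(function(a) a$kind == "glottic_closure", arts)
  eb <- Find(function(a) a$kind == "extra_breath", arts)
  eb_resume <- 0.6
  if (!is.null(eb))
    rec_end <- max(rec_end, eb$onset + eb$duration + eb_resume + 0.3)
  if (!is.null(et)) rec_end <- min(rec_end, et$onset)
  if (!is.null(gc_a)) rec_end <- min(rec_end, gc_a$onset + 0.5)

  t <- seq(0, d_p + rec_end, by = dt)
  s <- t - d_p
  flow <- tf$flow(s)
  vol_corr <- 0  # net volume change caused by multiplicative artifacts

  for (cg in Filter(function(a) a$kind == "cough", arts)) {
    d1 <- 0.6 * cg$duration; d2 <- 0.4 * cg$duration
    in_dip <- s >= cg$onset & s < cg$onset + d1
    in_reb <- s >= cg$onset + d1 & s < cg$onset + d1 + d2
    mult <- rep(1, length(s))
    mult[in_dip] <- 1 - cg$magnitude * sin(pi * (s[in_dip] - cg$onset) / d1)
    mult[in_reb] <- 1 + 0.5 * cg$magnitude *
      sin(pi * (s[in_reb] - cg$onset - d1) / d2)
    vol_corr <- vol_corr + sum((mult - 1) * flow) * dt
    flow <- flow * mult
  }
  for (fl_a in Filter(function(a) a$kind == "flutter_obstruction", arts)) {
    win <- s >= fl_a$onset & s <= fl_a$onset + fl_a$duration
    flow[win] <- flow[win] +
      fl_a$magnitude * tf$flow(s[win]) * sin(2 * pi * 10 * (s[win] - fl_a$onset))
  }
  if (!is.null(eb)) {
    amp_in <- pi * eb$magnitude / (2 * eb$duration)
    amp_out <- pi * eb$magnitude / (2 * eb_resume)
    w1 <- s >= eb$onset & s < eb$onset + eb$duration
    w2 <- s >= eb$onset + eb$duration &
      s < eb$onset + eb$duration + eb_resume
    flow[w1] <- flow[w1] - amp_in * sin(pi * (s[w1] - eb$onset) / eb$duration)
    flow[w2] <- flow[w2] +
      amp_out * sin(pi * (s[w2] - eb$onset - eb$duration) / eb_resume)
  }
  if (!is.null(gc_a))
    flow <- flow * pmax(0, pmin(1, 1 - (s - gc_a$onset) / 0.03))

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(spec$seed)
    flow <- flow + stats::rnorm(length(flow), 0, spec$noise_sd)
  }
  volume <- cum_trapz(flow, dt)
  m <- suppressWarnings(
    maneuver(maneuver_id, volume = volume, flow = flow,
             sample_interval = dt, config = cfg))

  truth <- synth_truth(spec, arts, tf, d_p, rec_end, vol_corr, maneuver_id,
                       cfg)
  list(maneuver = m, truth = truth)
}

# Expected indices and QC flags implied by the spec alone (no detectors).
synth_truth <- function(spec, arts, tf, d_p, rec_end, vol_corr,
                        maneuver_id, cfg) {
  tr <- spec$rise_time
  hes <- Find(function(a) a$kind == "hesitant_start", arts)
  h <- if (is.null(hes)) 0 else hes$magnitude
  # tangent at peak slope (pef) through the end of the rise phase
  t0 <- d_p + tr - (h + tf$v_rise) / spec$pef_true
  t0 <- max(t0, 0)
  vol_abs <- function(tt) h * pmin(1, ifelse(d_p > 0, tt / d_p, 1)) +
    tf$vol(tt - d_p)
  bev <- vol_abs(t0)
  et <- Find(function(a) a$kind == "early_termination", arts)
  gc_a <- Find(function(a) a$kind == "glottic_closure", arts)
  eb <- Find(function(a) a$kind == "extra_breath", arts)
  cgs <- Filter(function(a) a$kind == "cough", arts)
  fls <- Filter(function(a) a$kind == "flutter_obstruction", arts)
  # FVC intent: exhaled volume up to the end of the expiratory record
  exp_end <- d_p + rec_end
  if (!is.null(eb)) exp_end <- d_p + eb$onset
  fvc <- vol_abs(exp_end) + vol_corr - bev
  fev1 <- if (exp_end >= t0 + 1 || d_p + rec_end >= t0 + 1)
    vol_abs(t0 + 1) - bev else NA_real_
  plateau <- is.null(et) && is.null(gc_a) &&
    (is.null(eb) || eb$onset >= tf$t_nat - 0.05)
  bev_lim <- max(cfg$bev_abs, cfg$bev_frac * fvc)
  bev_ok <- bev <= bev_lim
  in_first <- function(a)
    !is.null(a) && d_p + a$onset < t0 + 1
  any_first <- function(as)
    any(vapply(as, in_first, logical(1)), FALSE)
  fev1_measurable <- !is.na(fev1) &&
    (is.null(gc_a) || d_p + gc_a$onset + 0.5 >= t0 + 1) &&
    (is.null(et) || d_p + et$onset >= t0 + 1)
  fev1_usable <- bev_ok && fev1_measurable && !any_first(cgs) &&
    !in_first(gc_a) && !any_first(fls)
  fev1_acceptable <- fev1_usable && !in_first(eb)
  fvc_usable <- bev_ok && is.null(eb) && !length(fls)
  # acceptability up to the session-level repeatability branch:
  fvc_acceptable_base <- fvc_usable && is.null(gc_a)
  onsets <- vapply(arts, function(a)
    if (a$kind == "hesitant_start") 0 else d_p + a$onset, numeric(1))
  list(
    maneuver_id = maneuver_id,
    artifacts = data.frame(
      kind = vapply(arts, `[[`, character(1), "kind"),
      onset = onsets,
      magnitude = vapply(arts, `[[`, numeric(1), "magnitude"),
      duration = vapply(arts, `[[`, numeric(1), "duration"),
      stringsAsFactors = FALSE),
    t0 = t0, bev = bev, fev1 = fev1, fvc = fvc, plateau = plateau,
    fev1_acceptable = fev1_acceptable, fev1_usable = fev1_usable,
    fvc_acceptable_base = fvc_acceptable_base, fvc_usable = fvc_usable
  )
}

#' Generate a synthetic session with its ground truth
#'
#' Generates one maneuver per spec, resolves the session-level
#' end-of-forced-expiration repeatability branch on the intended FVC
#' values, and computes the expected session grades with the same rating
#' tiers the QC layer uses.
#'
#' @param specs list of [maneuver_spec()] objects (>= 1).
#' @param session_id session id; maneuver ids are \code{m1, m2, ...}.
#' @param subject_age optional years.
#' @param seed optional integer; when given, each maneuver's noise stream
#'   is seeded by a stable hash of (seed, session id, maneuver id), so the
#'   result does not depend on generation order.
#' @param config a [spiro_config()] list.
#' @return A list with \code{session} (a [session()]) and \code{truth}
#'   (per-maneuver truths plus expected \code{fev1_grade} and
#'   \code{fvc_grade}).
#' @export
generate_session <- function(specs, session_id = "s1", subject_age = NULL,
                             seed = NULL, config = NULL) {
  cfg <- as_config(config)
  if (!is.list(specs) || !length(specs))
    stop("specs must be a non-empty list of maneuver_spec", call. = FALSE)
  gens <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    mid <- paste0("m", i)
    if (!is.null(seed))
      sp$seed <- stable_hash(paste(seed, session_id, mid, sep = "/"))
    generate_maneuver(sp, maneuver_id = mid, config = cfg)
  })
  mans <- lapply(gens, `[[`, "maneuver")
  truths <- lapply(gens, `[[`, "truth")
  # session-level EOFE repeatability on intended values
  fvcs <- vapply(truths, `[[`, numeric(1), "fvc")
  usable <- vapply(truths, `[[`, logical(1), "fvc_usable")
  best <- if (any(usable)) max(fvcs[usable]) else NA_real_
  truths <- lapply(truths, function(tr) {
    eofe <- tr$plateau ||
      (!is.na(best) && (best - tr$fvc) <= cfg$repeat_tol)
    tr$fvc_acceptable <- tr$fvc_acceptable_base && eofe
    tr
  })
  tiers <- if (!is.null(subject_age) && subject_age <= cfg$pediatric_age)
    cfg$repeat_tiers_pediatric else cfg$repeat_tiers
  grade_of <- function(acc, use, vals) {
    v <- vals[acc & !is.na(vals)]
    grade_one(sum(acc), sum(use), if (length(v)) repeatability_delta(v) else 0,
              tiers)
  }
  fev1s <- vapply(truths, `[[`, numeric(1), "fev1")
  truth <- list(
    maneuvers = truths,
    fev1_grade = grade_of(
      vapply(truths, `[[`, logical(1), "fev1_acceptable"),
      vapply(truths, `[[`, logical(1), "fev1_usable"), fev1s),
    fvc_grade = grade_of(
      vapply(truths, `[[`, logical(1), "fvc_acceptable"), usable, fvcs)
  )
  list(session = session(session_id, mans, subject_age = subject_age),
       truth = truth)
}

# Draw one subject's template parameters and (optionally) one artifact in
# the documented strong regime. Internal; assumes RNG already seeded.
draw_specs <- function(n_man, kind = NULL) {
  fvc <- stats::runif(1, 3.0, 4.5)
  pef <- fvc * stats::runif(1, 1.8, 2.3)
  tau <- stats::runif(1, 0.35, 0.6)
  rise <- stats::runif(1, 0.03, 0.08)
  tau_eff <- (fvc - 0.5 * pef * rise) / pef
  target <- if (is.null(kind)) 0L else sample.int(n_man, 1)
  lapply(seq_len(n_man), function(i) {
    arts <- list()
    if (i == target) {
      arts <- list(switch(
        kind,
        cough = artifact_spec(
          "cough",
          onset = rise + stats::runif(1, 0.3, 1.3) * tau_eff,
          magnitude = stats::runif(1, 0.35, 0.55)),
        glottic_closure = artifact_spec(
          "glottic_closure",
          onset = rise + stats::runif(1, 0.5, 1.5) * tau_eff),
        flutter_obstruction = artifact_spec(
          "flutter_obstruction",
          onset = stats::runif(1, 0.3, 0.9),
          magnitude = stats::runif(1, 0.22, 0.35)),
        early_termination = artifact_spec(
          "early_termination",
          onset = rise + stats::runif(1, 1.05, 1.35)),
        extra_breath = artifact_spec(
          "extra_breath",
          onset = rise + stats::runif(1, 3.2, 4.2) * tau_eff,
          magnitude = stats::runif(1, 0.16, 0.28)),
        hesitant_start = artifact_spec(
          "hesitant_start",
          magnitude = stats::runif(1, 0.28, 0.4))
      ))
    }
    maneuver_spec(
      fvc_true = fvc + stats::rnorm(1, 0, 0.02),
      pef_true = pef * stats::runif(1, 0.97, 1.03),
      tau = tau, rise_time = rise, noise_sd = 0.02, artifacts = arts)
  })
}

#' Generate a labeled synthetic cohort of sessions
#'
#' Draws \code{n_sessions} three-maneuver sessions. Each session is
#' violation-free with probability \code{quality_profile}; otherwise one
#' maneuver receives one artifact drawn from \code{artifact_mix} at a
#' strong-regime magnitude. All randomness fans out from \code{seed}
#' through stable per-session and per-maneuver substreams, so the dataset
#' is reproducible and independent of generation order.
#'
#' @param n_sessions number of sessions (>= 1).
#' @param artifact_mix named probability vector over the six injectable
#'   kinds; default uniform. Must sum to 1.
#' @param quality_profile target fraction of violation-free sessions.
#' @param seed integer master seed.
#' @param config a [spiro_config()] list.
#' @return A list of class \code{"spiro_dataset"}: \code{sessions} (list of
#'   [session()] objects) and \code{truth} (list of per-session truths as
#'   returned by [generate_session()]).
#' @export
generate_cohort <- function(n_sessions, artifact_mix = NULL,
                            quality_profile = 0.7, seed = 1,
                            config = NULL) {
  cfg <- as_config(config)
  stopifnot(n_sessions >= 1, quality_profile >= 0, quality_profile <= 1)
  if (is.null(artifact_mix))
    artifact_mix <- stats::setNames(rep(1 / 6, 6), SYNTH_KINDS)
  if (is.null(names(artifact_mix)) ||
      !all(names(artifact_mix) %in% SYNTH_KINDS) ||
      any(artifact_mix < 0) || abs(sum(artifact_mix) - 1) > 1e-8)
    stop("artifact_mix must be a probability vector over the six injectable kinds",
         call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  sessions <- vector("list", n_sessions)
  truth <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    sid <- sprintf("s%04d", i)
    set.seed(stable_hash(paste(seed, sid, sep = "/")))
    flawed <- stats::runif(1) > quality_profile
    kind <- if (flawed)
      sample(names(artifact_mix), 1, prob = artifact_mix) else NULL
    specs <- draw_specs(3L, kind)
    g <- generate_session(specs, session_id = sid, seed = seed,
                          config = cfg)
    sessions[[i]] <- g$session
    truth[[i]] <- c(list(session_id = sid), g$truth)
  }
  structure(list(sessions = sessions, truth = truth),
            class = "spiro_dataset")
}

#' @export
print.spiro_dataset <- function(x, ...) {
  cat(sprintf("<spiro_dataset: %d session(s)>\n", length(x$sessions)))
  invisible(x)
}

#' Generate the seeded single-artifact benchmark
#'
#' Builds \code{n} artifact-bearing maneuvers (one artifact each, cycling
#' through the six injectable kinds at strong-regime strengths) plus one
#' clean mate per maneuver from the same subject draw, with per-maneuver
#' seed substreams. This is the repository's desk-scale benchmark for
#' detector recall and clean-curve false-positive rate.
#'
#' @param n number of artifact maneuvers.
#' @param seed integer master seed.
#' @param config a [spiro_config()] list.
#' @return A list with \code{maneuvers} (artifact-bearing), \code{clean}
#'   (their clean mates), and \code{truth} (per-maneuver truths).
#' @export
generate_benchmark <- function(n = 200, seed = 1, config = NULL) {
  cfg <- as_config(config)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  kinds <- rep(SYNTH_KINDS, length.out = n)
  mans <- vector("list", n); clean <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    mid <- sprintf("b%04d", i)
    set.seed(stable_hash(paste(seed, "bench", mid, sep = "/")))
    sp <- draw_specs(1L, kinds[i])[[1]]
    sp$seed <- stable_hash(paste(seed, mid, "art", sep = "/"))
    sp_clean <- sp
    sp_clean$artifacts <- list()
    sp_clean$seed <- stable_hash(paste(seed, mid, "clean", sep = "/"))
    g <- generate_maneuver(sp, maneuver_id = mid, config = cfg)
    mans[[i]] <- g$maneuver
    truth[[i]] <- g$truth
    clean[[i]] <- generate_maneuver(sp_clean,
                                    maneuver_id = paste0(mid, "c"),
                                    config = cfg)$maneuver
  }
  list(maneuvers = mans, clean = clean, truth = truth)
}

#' Write / read a cohort truth sidecar
#'
#' Serializes the truth component of a [generate_cohort()] dataset to JSON
#' so that batch evaluation can run from files alone.
#'
#' @param truth the \code{truth} element of a \code{spiro_dataset}.
#' @param path file path.
#' @return \code{write_truth}: invisibly, \code{path}; \code{read_truth}:
#'   the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
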