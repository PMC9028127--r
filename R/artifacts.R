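# Deterministic signal-domain artifact detectors.
#
# Each detector classifies and localizes one anomaly class on the numeric
# flow/volume series and returns a findings table (possibly empty):
# one row per finding with columns
#   kind       one of cough, glottic_closure, flutter_obstruction,
#              early_termination, extra_breath, hesitant_start,
#              variable_flow
#   t_start,   the localized interval on the recording's time axis
#   t_end
#   v_at_onset cumulative exhaled volume at t_start (locates the finding
#              on the flow-volume representation as well)
#   score      surrogate confidence in [0, 1]: the observed transient
#              amplitude relative to its detection threshold, mapped by
#              min(1, ratio / 2)
#
# Fractional thresholds are taken relative to the local flow envelope (a
# running median of smoothed flow), which makes them scale-free across
# subjects. All detectors are pure functions of their inputs.

ARTIFACT_KINDS <- c("cough", "glottic_closure", "flutter_obstruction",
                    "early_termination", "extra_breath", "hesitant_start",
                    "variable_flow")

findings_table <- function(kind = character(), t_start = numeric(),
                           t_end = numeric(), v_at_onset = numeric(),
                           score = numeric()) {
  stopifnot(all(kind %in% ARTIFACT_KINDS), all(score >= 0), all(score <= 1))
  data.frame(kind = kind, t_start = t_start, t_end = t_end,
             v_at_onset = v_at_onset, score = score,
             stringsAsFactors = FALSE)
}

score_from_ratio <- function(ratio) pmin(1, pmax(ratio, 0) / 2)

flow_envelope <- function(m, cfg) {
  running_median(moving_average(m$flow, cfg$smooth_window),
                 cfg$envelope_window, m$sample_interval)
}

#' Detect cough transients
#'
#' A cough shows as an up-and-down flow spike during expiration: from a
#' local minimum of smoothed flow, the drop from the preceding maximum
#' (looked up over 0.3 x \code{cough_window}) must reach
#' \code{cough_drop_frac} (default 0.25) of the local flow envelope -- and
#' at least \code{cough_min_drop} absolute, so noise at near-zero flow
#' cannot qualify -- and flow must rebound by \code{cough_recover_frac}
#' (default 0.15) of the envelope within \code{cough_window} (default
#' 0.5 s). The rebound requirement rejects monotone decay, however steep.
#' The reported interval covers the dip and its rebound. Three or more
#' qualifying dips within twice the cough window are sustained periodicity
#' and are left to the flutter detector.
#'
#' @param maneuver a [maneuver()] object.
#' @param indices the matching [compute_indices()] result.
#' @param config a [spiro_config()] list.
#' @return A findings table (zero rows when the curve is clean), ordered by
#'   \code{t_start}.
#' @seealso [scan_artifacts()] for the combined, disambiguated scan.
#' @export
detect_cough <- function(maneuver, indices, config = NULL) {
  cfg <- as_config(config)
  m <- maneuver
  b <- expiration_bounds(m, cfg)
  fl <- b$flow_smooth
  dt <- m$sample_interval
  i0 <- which(m$t >= indices$t0)[1]
  i1 <- b$i_fet
  if (is.na(i0) || i1 - i0 < 3L) return(findings_table())
  env <- flow_envelope(m, cfg)
  w <- as.integer(round(cfg$cough_window / dt))
  wpre <- as.integer(round(0.3 * cfg$cough_window / dt))
  inner <- seq(max(i0 + 1L, 2L), max(min(i1 - 1L, length(fl) - 1L), 2L))
  mins <- inner[fl[inner] <= fl[inner - 1L] & fl[inner] <= fl[inner + 1L]]
  cand <- NULL
  dip_times <- numeric()  # every dip-and-rebound, however shallow
  for (i in mins) {
    pre <- seq(max(i0, i - wpre), i)
    post <- seq(i, min(i1, i + w))
    jpre <- pre[which.max(fl[pre])]
    jpost <- post[which.max(fl[post])]
    level <- max(env[jpre], 2 * cfg$zero_flow_floor)
    drop <- fl[jpre] - fl[i]
    recov <- fl[jpost] - fl[i]
    if (drop >= 0.6 * cfg$cough_drop_frac * level &&
        recov >= 0.6 * cfg$cough_recover_frac * level)
      dip_times <- c(dip_times, m$t[i])
    if (drop >= max(cfg$cough_drop_frac * level, cfg$cough_min_drop) &&
        recov >= cfg$cough_recover_frac * level)
      cand <- rbind(cand, c(i, jpre, jpost,
                            drop / (cfg$cough_drop_frac * level)))
  }
  if (is.null(cand)) return(findings_table())
  # sustained periodic dipping is flutter, not cough: suppress candidates
  # surrounded by 3+ dips (counted without the absolute-depth floor, so a
  # fading oscillation still reads as periodic)
  keep <- vapply(seq_len(nrow(cand)), function(k)
    sum(abs(dip_times - m$t[cand[k, 1]]) <= 2 * cfg$cough_window) < 3L,
    logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(findings_table())
  out <- findings_table(
    kind = rep("cough", nrow(cand)),
    t_start = pmax(m$t[pmax(cand[, 2] - cfg$smooth_window, 1L)], m$t[i0]),
    t_end = m$t[pmin(cand[, 3] + cfg$smooth_window, length(fl))],
    v_at_onset = m$volume[cand[, 2]],
    score = score_from_ratio(cand[, 4]))
  # merge overlapping candidates (one physical cough can seed several
  # local minima)
  out <- out[order(out$t_start), , drop = FALSE]
  merged <- out[1, , drop = FALSE]
  for (k in seq_len(nrow(out))[-1]) {
    last <- nrow(merged)
    if (out$t_start[k] <= merged$t_end[last]) {
      merged$t_end[last] <- max(merged$t_end[last], out$t_end[k])
      merged$score[last] <- max(merged$score[last], out$score[k])
    } else {
      merged <- rbind(merged, out[k, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Detect glottic closure
#'
#' Glottic closure shows as a sharp flow cessation before the natural end
#' of expiration: smoothed flow falls from above \code{gc_high_frac * PEF}
#' (default 0.10) to below the zero-flow floor within \code{gc_drop_window}
#' (default 0.1 s) and stays below it for at least \code{gc_hold} (default
#' 0.25 s) or to the end of the record, with no volume plateau in the
#' second preceding the stop. At most one finding is reported, at the
#' cessation point.
#'
#' @inheritParams detect_cough
#' @return A findings table with zero or one row.
#' @export
detect_glottic_closure <- function(maneuver, indices, config = NULL) {
  cfg <- as_config(config)
  m <- maneuver
  b <- expiration_bounds(m, cfg)
  fl <- b$flow_smooth
  dt <- m$sample_interval
  i0 <- which(m$t >= indices$t0)[1]
  i1 <- b$i_rec
  if (is.na(i0) || i1 <= i0) return(findings_table())
  rng <- i0:i1
  below <- fill_short_gaps(fl[rng] <= cfg$zero_flow_floor,
                           as.integer(round(0.05 / dt)))
  if (!any(below)) return(findings_table())
  runs <- true_runs(below)
  w <- as.integer(round(cfg$gc_drop_window / dt))
  high <- cfg$gc_high_frac * indices$pef
  for (r in seq_len(nrow(runs))) {
    j <- rng[runs[r, "start"]]
    j_end <- rng[runs[r, "end"]]
    held <- (m$t[j_end] - m$t[j]) >= cfg$gc_hold || j_end == i1
    if (!held) next
    pre_rng <- seq(max(i0, j - w), max(i0, j - 1L))
    if (max(fl[pre_rng]) < high) next
    # a genuine plateau immediately before the stop means the maneuver
    # simply finished; not a closure
    t_stop <- m$t[j]
    lo <- max(m$t[1], t_stop - cfg$plateau_window)
    dv <- interp_at(m$t, m$volume, t_stop) - interp_at(m$t, m$volume, lo)
    if ((t_stop - lo) >= cfg$plateau_window && dv <= cfg$plateau_dv) next
    jpre <- pre_rng[max(which(fl[pre_rng] >= high))]
    drop_rate <- (fl[jpre] - fl[j]) / max(m$t[j] - m$t[jpre], dt)
    return(findings_table(
      kind = "glottic_closure", t_start = m$t[jpre], t_end = m$t[j_end],
      v_at_onset = m$volume[jpre],
      score = score_from_ratio(fl[jpre] / high)))
  }
  findings_table()
}

#' Detect flutter (obstructed mouthpiece or spirometer)
#'
#' Flutter shows as a sustained band-limited oscillation of flow: after
#' band-pass filtering (default 5-15 Hz, 2nd-order Butterworth applied
#' forward-backward), segments where the oscillation amplitude reaches
#' \code{flutter_frac} (default 0.15) of the local flow envelope for at
#' least \code{flutter_min_dur} (default 0.3 s) are reported. Segments are
#' only evaluated where the envelope is at least \code{flutter_min_flow}
#' (default 0.25 L/s); relative thresholds are meaningless near zero flow.
#'
#' @inheritParams detect_cough
#' @return A findings table, ordered by \code{t_start}.
#' @export
detect_flutter <- function(maneuver, indices, config = NULL) {
  cfg <- as_config(config)
  m <- maneuver
  b <- expiration_bounds(m, cfg)
  dt <- m$sample_interval
  fs <- 1 / dt
  i0 <- which(m$t >= indices$t0)[1]
  i1 <- b$i_rec
  if (is.na(i0) || (i1 - i0) * dt < 2 * cfg$flutter_min_dur)
    return(findings_table())
  x <- m$flow[i0:i1]
  bf <- signal::butter(2, cfg$flutter_band / (fs / 2), type = "pass")
  bp <- tryCatch(signal::filtfilt(bf, x - mean(x)),
                 error = function(e) rep(0, length(x)))
  # oscillation amplitude: rolling max of |band-passed flow| over one
  # period of the low band edge
  half <- as.integer(round(1 / cfg$flutter_band[1] / dt / 2))
  n <- length(bp)
  amp <- vapply(seq_len(n), function(i)
    max(abs(bp[max(1L, i - half):min(n, i + half)])), numeric(1))
  env <- flow_envelope(m, cfg)[i0:i1]
  mask <- env >= cfg$flutter_min_flow & amp >= cfg$flutter_frac * env
  if (!any(mask)) return(findings_table())
  runs <- true_runs(mask)
  keep <- (runs[, "end"] - runs[, "start"]) * dt >= cfg$flutter_min_dur
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(findings_table())
  out <- lapply(seq_len(nrow(runs)), function(r) {
    a <- runs[r, "start"]; z <- runs[r, "end"]
    ratio <- stats::median(amp[a:z] / (cfg$flutter_frac * env[a:z]))
    findings_table(
      kind = "flutter_obstruction",
      t_start = m$t[i0 + a - 1L], t_end = m$t[i0 + z - 1L],
      v_at_onset = m$volume[i0 + a - 1L],
      score = score_from_ratio(ratio))
  })
  do.call(rbind, out)
}

#' Detect early termination of the forced expiration
#'
#' Reports a single end-of-record finding when the maneuver ends without
#' meeting the end-of-forced-expiration requirement through a plateau or a
#' long forced expiratory time, and no glottic-closure finding explains the
#' stop (the session-level FVC-repeatability branch is resolved by the QC
#' layer, not here). The interval is the final second of expiration.
#'
#' @inheritParams detect_cough
#' @return A findings table with zero or one row.
#' @export
detect_early_termination <- function(maneuver, indices, config = NULL) {
  cfg <- as_config(config)
  if (isTRUE(indices$plateau) || indices$fet >= cfg$fet_long)
    return(findings_table())
  if (nrow(detect_glottic_closure(maneuver, indices, config = cfg)))
    return(findings_table())
  t_end <- indices$t_end_expiration
  t_start <- max(indices$t0, t_end - 1)
  findings_table(kind = "early_termination", t_start = t_start,
                 t_end = t_end,
                 v_at_onset = interp_at(maneuver$t, maneuver$volume, t_start),
                 score = 1)
}

#' Detect an extra breath within the maneuver
#'
#' An extra breath shows as an inspiratory excursion followed by resumed
#' expiration: smoothed flow below \code{-eb_flow} (default 0.05 L/s) for
#' at least \code{eb_dur} (default 0.15 s), with expiratory flow rising
#' above twice the zero-flow floor afterwards. A terminal inspiration with
#' no resumed expiration is the recording simply ending, not an artifact.
#'
#' @inheritParams detect_cough
#' @param maneuver a [maneuver()] object.
#' @return A findings table, one row per inspiratory excursion.
#' @export
detect_extra_breath <- function(maneuver, config = NULL) {
  cfg <- as_config(config)
  m <- maneuver
  fl <- moving_average(m$flow, cfg$smooth_window)
  dt <- m$sample_interval
  neg <- fl < -cfg$eb_flow
  if (!any(neg)) return(findings_table())
  runs <- true_runs(neg)
  keep <- (runs[, "end"] - runs[, "start"] + 1L) * dt >= cfg$eb_dur
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(findings_table())
  out <- lapply(seq_len(nrow(runs)), function(r) {
    a <- runs[r, "start"]; z <- runs[r, "end"]
    after <- fl[seq(min(z + 1L, length(fl)), length(fl))]
    if (!any(after > 2 * cfg$zero_flow_floor)) return(NULL)
    depth <- -min(fl[a:z])
    findings_table(kind = "extra_breath", t_start = m$t[a], t_end = m$t[z],
                   v_at_onset = m$volume[a],
                   score = score_from_ratio(depth / cfg$eb_flow))
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(findings_table())
  do.call(rbind, out)
}

#' Detect start-of-test problems from the computed indices
#'
#' Flags a hesitant start when the back-extrapolated volume exceeds
#' \code{max(bev_abs, bev_frac * FVC)} (defaults 0.100 L, 5% of FVC), and
#' variable flow when the time to peak flow exceeds \code{tpef_max}
#' (default 0.15 s) without a hesitant start. Both findings span
#' \code{[t0, t0 + tPEF]} (at least one sample interval wide).
#'
#' @param indices a [compute_indices()] result.
#' @param config a [spiro_config()] list.
#' @return A findings table with zero or one row.
#' @export
detect_start_quality <- function(indices, config = NULL) {
  cfg <- as_config(config)
  dt <- if (is.null(indices$sample_interval)) 0.01 else indices$sample_interval
  t_end <- indices$t0 + max(indices$tpef, dt)
  bev_lim <- max(cfg$bev_abs, cfg$bev_frac * indices$fvc)
  if (indices$bev > bev_lim) {
    return(findings_table(kind = "hesitant_start", t_start = indices$t0,
                          t_end = t_end, v_at_onset = indices$bev,
                          score = score_from_ratio(indices$bev / bev_lim)))
  }
  if (indices$tpef > cfg$tpef_max) {
    return(findings_table(kind = "variable_flow", t_start = indices$t0,
                          t_end = t_end, v_at_onset = indices$bev,
                          score = score_from_ratio(indices$tpef / cfg$tpef_max)))
  }
  findings_table()
}

#' Scan a maneuver for all artifact classes
#'
#' Runs every detector, resolves overlapping cough/flutter findings in
#' favor of the higher score (an isolated transient is a cough, sustained
#' periodicity a flutter), and returns the union sorted by onset.
#'
#' @inheritParams detect_cough
#' @return A findings table sorted by \code{t_start}.
#' @examples
#' tt <- seq(0, 6, by = 0.01)
#' m <- maneuver("clean", volume = 4 * (1 - exp(-tt / 0.5)),
#'               flow = 8 * exp(-tt / 0.5))
#' scan_artifacts(m, compute_indices(m))
#' @export
scan_artifacts <- function(maneuver, indices, config = NULL) {
  cfg <- as_config(config)
  f <- rbind(
    detect_cough(maneuver, indices, config = cfg),
    detect_glottic_closure(maneuver, indices, config = cfg),
    detect_flutter(maneuver, indices, config = cfg),
    detect_early_termination(maneuver, indices, config = cfg),
    detect_extra_breath(maneuver, config = cfg),
    detect_start_quality(indices, config = cfg)
  )
  if (!nrow(f)) return(f)
  # cough vs flutter: where intervals overlap, keep the higher score
  drop <- rep(FALSE, nrow(f))
  ic <- which(f$kind == "cough")
  fl <- which(f$kind == "flutter_obstruction")
  for (i in ic) for (j in fl) {
    if (f$t_start[i] <= f$t_end[j] && f$t_start[j] <= f$t_end[i]) {
      if (f$score[i] >= f$score[j]) drop[j] <- TRUE else drop[i] <- TRUE
    }
  }
  f <- f[!drop, , drop = FALSE]
  f <- f[order(f$t_start, f$kind), , drop = FALSE]
  rownames(f) <- NULL
  f
}
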