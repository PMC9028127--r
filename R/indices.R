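# Quantitative spirometric indices on a single maneuver.
#
# All timing indices are referenced to back-extrapolated time zero (t0),
# the standard start-of-test reference: the steepest tangent of the
# volume-time curve extended down to V = 0.

# Locate the expiratory portion of the record and the end of expiration.
# Returns indices into the maneuver's grid:
#   i_rec : last sample of the expiratory record -- everything up to (not
#           including) the first sustained inspiratory segment. Plateau
#           windows and FVC are evaluated on [1, i_rec].
#   i_fet : last sample with flow above the zero-flow floor within the
#           expiratory record -- the end of expiration used for FET, so
#           sensor drift at near-zero flow cannot inflate FET.
expiration_bounds <- function(m, cfg) {
  n <- length(m$t)
  dt <- m$sample_interval
  fl <- moving_average(m$flow, cfg$smooth_window)
  neg <- fl < -cfg$eb_flow
  i_rec <- n
  if (any(neg)) {
    runs <- true_runs(neg)
    len <- (runs[, "end"] - runs[, "start"] + 1L) * dt
    sustained <- runs[len >= cfg$eb_dur, , drop = FALSE]
    if (nrow(sustained)) i_rec <- max(1L, sustained[1, "start"] - 1L)
  }
  above <- which(fl[seq_len(i_rec)] > cfg$zero_flow_floor)
  i_fet <- if (length(above)) max(above) else 0L
  list(i_rec = i_rec, i_fet = i_fet, flow_smooth = fl)
}

#' Back-extrapolate the start of the forced expiration
#'
#' Finds back-extrapolated time zero and the back-extrapolated volume
#' (BEV): the tangent with the steepest smoothed slope of the volume-time
#' curve is extended to V = 0; its time-axis intercept is t0 (clamped to
#' the start of the recording) and the measured exhaled volume at t0 is
#' the BEV. A large BEV marks a hesitant, non-explosive start of test.
#'
#' @param maneuver a [maneuver()] object.
#' @param config a [spiro_config()] list; \code{smooth_window} controls the
#'   derivative smoothing used to pick the steepest slope.
#' @return A list with numeric fields \code{t0} (seconds) and \code{bev}
#'   (liters).
#' @examples
#' tt <- seq(0, 1, by = 0.01)
#' back_extrapolate(maneuver("ramp", volume = 2 * tt))
#' @export
back_extrapolate <- function(maneuver, config = NULL) {
  cfg <- as_config(config)
  m <- maneuver
  if (!inherits(m, "spiro_maneuver")) stop("not a spiro_maneuver", call. = FALSE)
  b <- expiration_bounds(m, cfg)
  idx <- seq_len(b$i_rec)
  if (max(m$volume[idx]) - m$volume[1] <= 1e-6 || b$i_fet < 1L)
    stop("degenerate maneuver: no measurable expiration", call. = FALSE)
  slope <- moving_average(finite_diff(m$volume[idx], m$sample_interval),
                          cfg$smooth_window)
  i_star <- which.max(slope)
  s <- slope[i_star]
  if (s <= 0) stop("degenerate maneuver: non-positive peak slope", call. = FALSE)
  t0 <- m$t[i_star] - m$volume[i_star] / s
  t0 <- max(t0, m$t[1])
  bev <- interp_at(m$t, m$volume, t0) - m$volume[1]
  list(t0 = t0, bev = max(bev, 0))
}

#' Detect the end-of-expiration volume plateau
#'
#' A maneuver reaches a plateau when the exhaled volume changes by no more
#' than \code{plateau_dv} (default 0.025 L) over the final
#' \code{plateau_window} (default 1 s) of the expiratory record. The onset
#' is the earliest time from which every trailing window is compliant,
#' reported as the end time of the first compliant window.
#'
#' @inheritParams back_extrapolate
#' @return A list with \code{plateau} (logical) and \code{onset} (seconds,
#'   \code{NA} when there is no plateau). Records shorter than the window
#'   return \code{plateau = FALSE} rather than an error.
#' @export
detect_plateau <- function(maneuver, config = NULL) {
  cfg <- as_config(config)
  m <- maneuver
  b <- expiration_bounds(m, cfg)
  idx <- seq_len(b$i_rec)
  t <- m$t[idx]; v <- m$volume[idx]
  w <- cfg$plateau_window
  if (t[length(t)] - t[1] < w)
    return(list(plateau = FALSE, onset = NA_real_))
  ends <- which(t >= t[1] + w)
  dv <- v[ends] - stats::approx(t, v, xout = t[ends] - w)$y
  compliant <- dv <= cfg$plateau_dv
  plateau <- compliant[length(compliant)]
  onset <- NA_real_
  if (plateau) {
    ok_from <- rev(cumprod(rev(compliant))) > 0
    onset <- t[ends[which(ok_from)[1]]]
  }
  list(plateau = plateau, onset = onset)
}

#' Compute the spirometric indices of one maneuver
#'
#' Derives the standard forced-expiration quantities, all referenced to
#' back-extrapolated time zero (t0): FEV1 (volume exhaled in the first
#' second after t0, linear interpolation at t0 + 1 s), FVC (maximum
#' cumulative exhaled volume above V(t0)), PEF and time to PEF, forced
#' expiratory time (t0 to the end of expiration at the zero-flow floor),
#' BEV, and the end-of-forced-expiration status.
#'
#' @inheritParams back_extrapolate
#' @param best_fvc_delta optional session-level difference (liters) between
#'   the session's best FVC and this maneuver's FVC; when supplied and
#'   within \code{repeat_tol} it satisfies the repeatability branch of the
#'   end-of-forced-expiration rule.
#' @return An object of class \code{"spiro_indices"}: \code{t0}, \code{bev},
#'   \code{fev1} (NA when the record ends before t0 + 1 s), \code{fvc},
#'   \code{pef}, \code{tpef}, \code{fet}, \code{plateau},
#'   \code{plateau_onset}, \code{eofe_met}, plus the record bookkeeping
#'   fields \code{t_end_record} and \code{t_end_expiration}.
#' @examples
#' tt <- seq(0, 12, by = 0.01)
#' m <- maneuver("exp", volume = 4 * (1 - exp(-tt / 0.4)),
#'               flow = 10 * exp(-tt / 0.4))
#' compute_indices(m)
#' @export
compute_indices <- function(maneuver, best_fvc_delta = NULL, config = NULL) {
  cfg <- as_config(config)
  m <- maneuver
  if (!inherits(m, "spiro_maneuver")) stop("not a spiro_maneuver", call. = FALSE)
  b <- expiration_bounds(m, cfg)
  if (b$i_fet < 1L)
    stop("degenerate maneuver: flow never exceeds the zero-flow floor",
         call. = FALSE)
  be <- back_extrapolate(m, config = cfg)
  t0 <- be$t0
  idx <- seq_len(b$i_rec)
  v0 <- interp_at(m$t, m$volume, t0)
  fvc <- max(m$volume[idx]) - v0
  t_end_rec <- m$t[b$i_rec]
  t_end_exp <- m$t[b$i_fet]
  fet <- t_end_exp - t0
  if (fet < m$sample_interval)
    stop("degenerate maneuver: expiration shorter than one sample interval",
         call. = FALSE)
  fev1 <- if (t_end_rec >= t0 + 1 - m$sample_interval / 2) {
    interp_at(m$t, m$volume, t0 + 1) - v0
  } else NA_real_
  after <- which(m$t[idx] >= t0)
  i_pef <- after[which.max(m$flow[after])]
  pef <- m$flow[i_pef]
  tpef <- max(m$t[i_pef] - t0, 0)
  pl <- detect_plateau(m, config = cfg)
  ind <- structure(
    list(maneuver_id = m$maneuver_id, t0 = t0, bev = be$bev,
         fev1 = fev1, fvc = fvc, pef = pef, tpef = tpef, fet = fet,
         plateau = pl$plateau, plateau_onset = pl$onset,
         eofe_met = NA, t_end_record = t_end_rec,
         t_end_expiration = t_end_exp,
         t_last = m$t[length(m$t)],
         sample_interval = m$sample_interval),
    class = "spiro_indices"
  )
  ind$eofe_met <- eofe_met(ind, best_fvc_delta, config = cfg)
  ind
}

#' @export
print.spiro_indices <- function(x, ...) {
  cat(sprintf(
    paste0("<spiro_indices %s: FEV1=%s L, FVC=%.3f L, PEF=%.2f L/s, ",
           "BEV=%.3f L, tPEF=%.2f s, FET=%.2f s, plateau=%s, EOFE=%s>\n"),
    x$maneuver_id,
    if (is.na(x$fev1)) "NA" else sprintf("%.3f", x$fev1),
    x$fvc, x$pef, x$bev, x$tpef, x$fet, x$plateau, x$eofe_met))
  invisible(x)
}

#' End-of-forced-expiration rule
#'
#' The end-of-forced-expiration requirement is met by any of three
#' indicators: a volume plateau, a forced expiratory time of at least
#' \code{fet_long} (default 15 s), or -- at session level -- an FVC within
#' the repeatability tolerance (default 0.150 L) of the session's best FVC.
#'
#' @param indices a [compute_indices()] result.
#' @param best_fvc_delta optional non-negative liters; difference between
#'   the session's best FVC and this maneuver's FVC.
#' @param config a [spiro_config()] list.
#' @return Logical scalar.
#' @export
eofe_met <- function(indices, best_fvc_delta = NULL, config = NULL) {
  cfg <- as_config(config)
  isTRUE(indices$plateau) ||
    indices$fet >= cfg$fet_long ||
    (!is.null(best_fvc_delta) && !is.na(best_fvc_delta) &&
       best_fvc_delta <= cfg$repeat_tol)
}

#' Repeatability delta of an index across maneuvers
#'
#' The difference between the two largest values, the quantity the
#' session-grading tiers compare with their repeatability tolerances.
#' A single value has, by convention, a delta of 0.
#'
#' @param values numeric vector of index values (liters), length >= 1;
#'   \code{NA}s are dropped.
#' @return Non-negative numeric scalar.
#' @examples
#' repeatability_delta(c(4.10, 3.98, 4.05))
#' @export
repeatability_delta <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values supplied", call. = FALSE)
  if (length(values) == 1L) return(0)
  s <- sort(values, decreasing = TRUE)
  s[1] - s[2]
}
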