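#' Pipeline configuration
#'
#' All tunable thresholds used by the index, artifact-detection and QC
#' layers, collected in one flat namespace so that every rule can be
#' overridden without touching code. Values follow the ATS/ERS 2019
#' technical-standard quantities where the standard states one; detector
#' thresholds are this package's own documented defaults.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Keys and defaults (units in brackets):
#' \describe{
#'   \item{sample_interval}{canonical sampling interval, 0.01 [s].}
#'   \item{flow_tol}{allowed discrepancy between a recorded flow channel
#'     and the smoothed derivative of volume, 0.05 [L/s]; exceedances are
#'     warned about, never fatal.}
#'   \item{bev_abs, bev_frac}{back-extrapolated volume limits: BEV must not
#'     exceed \code{max(bev_abs, bev_frac * FVC)}; 0.100 [L] and 0.05 [-].}
#'   \item{plateau_dv, plateau_window}{end-of-forced-expiration plateau:
#'     volume change at most \code{plateau_dv} (0.025 [L]) over the final
#'     \code{plateau_window} (1 [s]) of expiration.}
#'   \item{fet_long}{forced expiratory time that satisfies EOFE on its own,
#'     15 [s].}
#'   \item{repeat_tol}{FVC repeatability tolerance used by the session-level
#'     EOFE branch, 0.150 [L].}
#'   \item{zero_flow_floor}{flow below this is treated as zero when locating
#'     the end of expiration, 0.025 [L/s].}
#'   \item{smooth_window}{moving-average width (samples) used for the
#'     back-extrapolation slope and detector smoothing, 5.}
#'   \item{tpef_max}{time to peak flow above which rise is flagged as
#'     variable flow, 0.15 [s].}
#'   \item{cough_drop_frac, cough_recover_frac, cough_window,
#'     cough_min_drop}{cough: flow must dip by >= 0.25 of the local flow
#'     envelope and rebound by >= 0.15 of it within 0.5 [s];
#'     \code{cough_min_drop} (0.15 [L/s]) is an absolute floor on the dip
#'     depth, so sensor noise at near-zero flow cannot masquerade as a
#'     cough.}
#'   \item{gc_high_frac, gc_drop_window, gc_hold}{glottic closure: flow
#'     falls from above \code{gc_high_frac * PEF} (0.10) to below the
#'     zero-flow floor within 0.1 [s] and stays there >= 0.25 [s].}
#'   \item{flutter_band, flutter_frac, flutter_min_dur, flutter_min_flow}{
#'     flutter: band-limited (5-15 [Hz]) oscillation with amplitude >= 0.15
#'     of the local flow for >= 0.3 [s], evaluated only where local flow
#'     >= 0.25 [L/s].}
#'   \item{eb_flow, eb_dur}{extra breath: flow below \code{-eb_flow}
#'     (0.05 [L/s]) for >= 0.15 [s] with expiration resuming afterwards.}
#'   \item{envelope_window}{running-median window for the local flow
#'     envelope, 0.3 [s].}
#'   \item{repeat_tiers, repeat_tiers_pediatric}{repeatability tiers (A/B,
#'     C, D grade cut-offs) in liters; adult 0.150/0.200/0.250, age <= 6
#'     years 0.100/0.150/0.200.}
#'   \item{pediatric_age}{age at or below which pediatric tiers apply, 6
#'     [years].}
#' }
#'
#' @return A named list of class \code{"spiro_config"}.
#' @examples
#' cfg <- spiro_config(plateau_dv = 0.030)
#' cfg$plateau_dv
#' @export
spiro_config <- function(...) {
  cfg <- list(
    sample_interval = 0.01,
    flow_tol = 0.05,
    bev_abs = 0.100,
    bev_frac = 0.05,
    plateau_dv = 0.025,
    plateau_window = 1.0,
    fet_long = 15.0,
    repeat_tol = 0.150,
    zero_flow_floor = 0.025,
    smooth_window = 5,
    tpef_max = 0.15,
    cough_drop_frac = 0.25,
    cough_recover_frac = 0.15,
    cough_window = 0.5,
    cough_min_drop = 0.15,
    gc_high_frac = 0.10,
    gc_drop_window = 0.1,
    gc_hold = 0.25,
    flutter_band = c(5, 15),
    flutter_frac = 0.15,
    flutter_min_dur = 0.3,
    flutter_min_flow = 0.25,
    eb_flow = 0.05,
    eb_dur = 0.15,
    envelope_window = 0.3,
    repeat_tiers = c(0.150, 0.200, 0.250),
    repeat_tiers_pediatric = c(0.100, 0.150, 0.200),
    pediatric_age = 6
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("config overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "spiro_config")
}

as_config <- function(config) {
  if (is.null(config)) return(spiro_config())
  if (inherits(config, "spiro_config")) return(config)
  do.call(spiro_config, as.list(config))
}
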