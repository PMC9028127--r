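#' Construct a single forced-expiration maneuver
#'
#' A maneuver is one forced-expiration recording on a uniform time grid:
#' cumulative exhaled volume (liters, BTPS) and expiratory flow (L/s,
#' positive during expiration, negative during an inspiratory excursion).
#' Time starts at recording start, not at back-extrapolated time zero.
#'
#' @param maneuver_id character scalar, unique within a session.
#' @param volume numeric vector of cumulative exhaled volume in liters.
#' @param flow optional numeric vector of flow in L/s. When absent it is
#'   reconstructed by centered finite differences of \code{volume}. When
#'   present it is taken as authoritative and only checked (with a warning)
#'   against the smoothed volume derivative, since numerical differencing
#'   amplifies device noise.
#' @param sample_interval grid spacing in seconds (canonical 0.01).
#' @param t optional explicit time vector; must be a uniform grid starting
#'   at 0 consistent with \code{sample_interval}.
#' @param config a [spiro_config()] list (used for the flow-consistency
#'   tolerance).
#'
#' @return An object of class \code{"spiro_maneuver"}: a list with fields
#'   \code{maneuver_id}, \code{t}, \code{volume}, \code{flow},
#'   \code{sample_interval}.
#' @examples
#' m <- maneuver("m1", volume = c(0, 0.05), sample_interval = 0.01)
#' m$flow
#' @export
maneuver <- function(maneuver_id, volume, flow = NULL,
                     sample_interval = 0.01, t = NULL, config = NULL) {
  cfg <- as_config(config)
  if (!is.character(maneuver_id) || length(maneuver_id) != 1L ||
      is.na(maneuver_id) || !nzchar(maneuver_id))
    stop("maneuver_id must be a non-empty string", call. = FALSE)
  volume <- as.numeric(volume)
  n <- length(volume)
  if (n < 2L) stop("maneuver needs at least 2 samples", call. = FALSE)
  if (anyNA(volume)) stop("volume contains missing values", call. = FALSE)
  if (volume[1] < -1e-9)
    stop("volume[1] must be >= 0 (cumulative exhaled volume)", call. = FALSE)
  if (!is.numeric(sample_interval) || sample_interval <= 0)
    stop("sample_interval must be a positive number", call. = FALSE)
  grid <- (seq_len(n) - 1L) * sample_interval
  if (!is.null(t)) {
    t <- as.numeric(t)
    if (length(t) != n)
      stop("t and volume lengths differ", call. = FALSE)
    if (max(abs(t - grid)) > 1e-9)
      stop("t is not a uniform grid starting at 0 with spacing ",
           sample_interval, call. = FALSE)
  }
  if (is.null(flow)) {
    flow <- finite_diff(volume, sample_interval)
  } else {
    flow <- as.numeric(flow)
    if (length(flow) != n)
      stop("flow and volume lengths differ", call. = FALSE)
    if (anyNA(flow)) stop("flow contains missing values", call. = FALSE)
    dv <- moving_average(finite_diff(volume, sample_interval),
                         cfg$smooth_window)
    fl <- moving_average(flow, cfg$smooth_window)
    # the cusp at peak flow disagrees with any finite-difference scheme
    # by construction, so it is excluded from the consistency check
    excl <- abs(seq_len(n) - which.max(flow)) <= 2L * cfg$smooth_window
    dmax <- max(abs(fl - dv)[!excl], 0)
    if (dmax > cfg$flow_tol)
      warning("flow channel disagrees with dV/dt by up to ",
              signif(dmax, 3),
              " L/s; keeping the recorded flow channel", call. = FALSE)
  }
  structure(
    list(maneuver_id = maneuver_id, t = grid, volume = volume,
         flow = flow, sample_interval = sample_interval),
    class = "spiro_maneuver"
  )
}

#' @export
print.spiro_maneuver <- function(x, ...) {
  cat(sprintf("<spiro_maneuver %s: %d samples @ %.3g s, %.2f L exhaled>\n",
              x$maneuver_id, length(x$t), x$sample_interval,
              max(x$volume) - x$volume[1]))
  invisible(x)
}

#' Construct a spirometry session
#'
#' A session bundles the forced-expiration maneuvers of one test occasion
#' (typically three) with optional subject age, which switches the grading
#' layer to pediatric repeatability tiers.
#'
#' @param session_id character scalar.
#' @param maneuvers list of [maneuver()] objects, at least one, with unique
#'   maneuver ids.
#' @param subject_age optional age in years.
#' @return An object of class \code{"spiro_session"}.
#' @export
session <- function(session_id, maneuvers, subject_age = NULL) {
  if (!is.character(session_id) || length(session_id) != 1L ||
      !nzchar(session_id))
    stop("session_id must be a non-empty string", call. = FALSE)
  if (!is.list(maneuvers) || length(maneuvers) < 1L)
    stop("session needs at least one maneuver", call. = FALSE)
  ok <- vapply(maneuvers, inherits, logical(1), "spiro_maneuver")
  if (!all(ok))
    stop("maneuvers must all be spiro_maneuver objects", call. = FALSE)
  ids <- vapply(maneuvers, `[[`, character(1), "maneuver_id")
  if (anyDuplicated(ids))
    stop("duplicated maneuver_id within session: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!is.null(subject_age)) {
    subject_age <- as.numeric(subject_age)
    if (length(subject_age) != 1L || is.na(subject_age) || subject_age < 0)
      stop("subject_age must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(session_id = session_id, subject_age = subject_age,
         maneuvers = maneuvers),
    class = "spiro_session"
  )
}

#' @export
print.spiro_session <- function(x, ...) {
  cat(sprintf("<spiro_session %s: %d maneuver(s)%s>\n", x$session_id,
              length(x$maneuvers),
              if (is.null(x$subject_age)) ""
              else sprintf(", age %g", x$subject_age)))
  invisible(x)
}

#' Read a session file
#'
#' Reads the package's JSON session schema: one object per file with fields
#' \code{session_id}, optional \code{subject_age}, and \code{maneuvers}, an
#' array of objects with \code{maneuver_id}, \code{sample_interval},
#' \code{volume} (liters) and optional \code{flow} (L/s). The time grid is
#' implicit: sample i sits at \code{(i-1) * sample_interval}. This schema is
#' a vendor-neutral reconstruction of the numeric intermediate that QC
#' systems extract from device reports; it is not a vendor export format.
#'
#' @param path path to a session JSON file.
#' @param config a [spiro_config()] list.
#' @return A [session()] object.
#' @seealso [write_session()], [resample_to_grid()]
#' @export
read_session <- function(path, config = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed session file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("session file ", path, ": missing field '", field, "' in ",
           where, call. = FALSE)
    x[[field]]
  }
  sid <- need(raw, "session_id", "top-level object")
  mans_raw <- need(raw, "maneuvers", "top-level object")
  if (length(mans_raw) < 1L)
    stop("session file ", path, ": 'maneuvers' is empty", call. = FALSE)
  mans <- lapply(mans_raw, function(m) {
    mid <- need(m, "maneuver_id", "maneuver")
    dt <- as.numeric(need(m, "sample_interval", paste0("maneuver ", mid)))
    vol <- as.numeric(unlist(need(m, "volume", paste0("maneuver ", mid))))
    flow <- if (is.null(m$flow)) NULL else as.numeric(unlist(m$flow))
    maneuver(as.character(mid), volume = vol, flow = flow,
             sample_interval = dt, config = config)
  })
  age <- if (is.null(raw$subject_age)) NULL else as.numeric(raw$subject_age)
  session(as.character(sid), mans, subject_age = age)
}

#' Write a session file
#'
#' Serializes a session to the JSON schema documented in [read_session()].
#' Numeric series are written at full double precision, so a write/read
#' round trip reproduces the series to better than 1e-9 L and the output
#' bytes are stable for identical input.
#'
#' @param session a [session()] object.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_session <- function(session, path) {
  if (!inherits(session, "spiro_session"))
    stop("not a spiro_session", call. = FALSE)
  doc <- list(
    session_id = session$session_id,
    subject_age = session$subject_age,
    maneuvers = lapply(session$maneuvers, function(m)
      list(maneuver_id = m$maneuver_id,
           sample_interval = m$sample_interval,
           volume = m$volume,
           flow = m$flow))
  )
  if (is.null(session$subject_age)) doc$subject_age <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Resample an irregular volume-time recording onto the canonical grid
#'
#' Linearly interpolates a strictly increasing (possibly irregular) time /
#' cumulative-volume recording onto a uniform grid with the canonical
#' 0.01-s spacing spanning the recorded interval, re-bases time to 0, and
#' reconstructs flow by centered finite differences. Input already on the
#' canonical grid passes through unchanged, so the operation is idempotent.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param volume numeric vector of cumulative exhaled volume in liters.
#' @param maneuver_id id for the resulting maneuver.
#' @param sample_interval target grid spacing in seconds.
#' @param config a [spiro_config()] list.
#' @return A [maneuver()] object on the uniform grid.
#' @examples
#' tt <- seq(0, 1, by = 0.013)
#' m <- resample_to_grid(tt, 2 * tt)
#' range(m$flow)
#' @export
resample_to_grid <- function(t, volume, maneuver_id = "m1",
                             sample_interval = 0.01, config = NULL) {
  t <- as.numeric(t); volume <- as.numeric(volume)
  if (length(t) != length(volume))
    stop("t and volume lengths differ", call. = FALSE)
  if (length(t) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  grid <- seq(0, t[length(t)] - t[1],
              by = sample_interval)
  v <- stats::approx(t - t[1], volume, xout = grid, rule = 2)$y
  maneuver(maneuver_id, volume = v, sample_interval = sample_interval,
           config = config)
}

#' Import one maneuver from a two-column CSV
#'
#' Reads a CSV with columns \code{time} (seconds) and \code{volume}
#' (liters, cumulative exhaled) and resamples it onto the canonical grid.
#'
#' @inheritParams resample_to_grid
#' @param path CSV file path.
#' @return A [maneuver()] object.
#' @export
read_maneuver_csv <- function(path, maneuver_id = NULL,
                              sample_interval = 0.01, config = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time", "volume") %in% names(df)))
    stop("CSV must have columns 'time' and 'volume': ", path, call. = FALSE)
  if (is.null(maneuver_id))
    maneuver_id <- sub("\\.[^.]*$", "", basename(path))
  resample_to_grid(df$time, df$volume, maneuver_id = maneuver_id,
                   sample_interval = sample_interval, config = config)
}
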