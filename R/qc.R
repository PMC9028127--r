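# Rule layer: combine quantitative checks and artifact findings into
# per-maneuver acceptability/usability, session-level A-F/U grades, and
# operator/patient messages.
#
# The decision table ships as data (inst/extdata/qc_criteria.csv): one row
# per criterion with the index it affects (fev1, fvc or both), whether it
# gates usability or only acceptability (or is warning-only), and the
# operator/patient message texts. Acceptability requires every usability
# criterion as well, so acceptable always implies usable.

.qc_cache <- new.env(parent = emptyenv())

#' The acceptability/usability criteria catalog
#'
#' Returns the decision table the QC layer applies: criterion id, the index
#' it affects (\code{fev1}, \code{fvc} or \code{both}), its effect
#' (\code{usability}, \code{acceptability} or \code{warning}), and the
#' operator and patient message texts. The table is shipped as a CSV data
#' file so corrections do not require code changes.
#'
#' @return A data.frame with columns \code{criterion}, \code{index},
#'   \code{effect}, \code{operator_message}, \code{guidance}.
#' @export
qc_criteria <- function() {
  if (is.null(.qc_cache$criteria)) {
    path <- system.file("extdata", "qc_criteria.csv", package = "spiroqc")
    .qc_cache$criteria <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .qc_cache$criteria
}

overlaps_window <- function(findings, kind, lo, hi) {
  f <- findings[findings$kind == kind, , drop = FALSE]
  any(f$t_start <= hi & f$t_end >= lo)
}

#' Assess one maneuver's FEV1 and FVC acceptability and usability
#'
#' Applies the criteria catalog to the computed indices and the artifact
#' findings of one maneuver. Any failed criterion from either source fails
#' the affected flag (union of failures). FEV1 is gated by what happens in
#' the first second after time zero: usability requires the BEV within
#' limits, a measurable first second, and no cough / glottic closure /
#' flutter overlapping it; acceptability additionally requires no extra
#' breath before t0 + 1 s. FVC usability requires the BEV within limits and
#' an uncorrupted volume record (no extra breath or flutter anywhere);
#' acceptability additionally requires the end-of-forced-expiration rule
#' and no glottic closure or early termination.
#'
#' @param indices a [compute_indices()] result.
#' @param findings a findings table from [scan_artifacts()] (or any subset
#'   of detectors). Findings must lie within the maneuver's recorded span.
#' @param best_fvc_delta optional session-level difference (liters) between
#'   the session's best FVC and this maneuver's FVC, for the repeatability
#'   branch of the end-of-forced-expiration rule.
#' @param config a [spiro_config()] list.
#' @return An object of class \code{"spiro_maneuver_qc"}: the four logical
#'   flags \code{fev1_acceptable}, \code{fev1_usable}, \code{fvc_acceptable},
#'   \code{fvc_usable} and a \code{reasons} data.frame with one row per
#'   criterion evaluated (\code{criterion}, \code{index}, \code{effect},
#'   \code{passed}, \code{detail}).
#' @export
assess_maneuver <- function(indices, findings, best_fvc_delta = NULL,
                            config = NULL) {
  cfg <- as_config(config)
  if (nrow(findings)) {
    t_last <- if (is.null(indices$t_last)) Inf else indices$t_last
    if (any(findings$t_start < 0 - 1e-9) ||
        any(findings$t_end > t_last + 1e-9))
      stop("finding outside the maneuver's recorded span", call. = FALSE)
  }
  t0 <- indices$t0
  first_sec <- c(t0, t0 + 1)
  bev_lim <- max(cfg$bev_abs, cfg$bev_frac * indices$fvc)
  eofe_ok <- eofe_met(indices, best_fvc_delta, config = cfg)
  et_present <- overlaps_window(findings, "early_termination",
                                -Inf, Inf)
  checks <- list(
    bev_limit = list(
      passed = indices$bev <= bev_lim,
      detail = sprintf("BEV %.3f L vs limit %.3f L", indices$bev, bev_lim)),
    fev1_measurable = list(
      passed = !is.na(indices$fev1),
      detail = if (is.na(indices$fev1))
        "record ends before t0 + 1 s" else
          sprintf("FEV1 %.3f L", indices$fev1)),
    cough_first_second = list(
      passed = !overlaps_window(findings, "cough", first_sec[1], first_sec[2]),
      detail = "cough overlapping [t0, t0 + 1 s]"),
    glottic_closure_first_second = list(
      passed = !overlaps_window(findings, "glottic_closure",
                                first_sec[1], first_sec[2]),
      detail = "glottic closure overlapping [t0, t0 + 1 s]"),
    flutter_first_second = list(
      passed = !overlaps_window(findings, "flutter_obstruction",
                                first_sec[1], first_sec[2]),
      detail = "flutter overlapping [t0, t0 + 1 s]"),
    extra_breath_first_second = list(
      passed = !overlaps_window(findings, "extra_breath", -Inf, first_sec[2]),
      detail = "extra breath before t0 + 1 s"),
    extra_breath_any = list(
      passed = !overlaps_window(findings, "extra_breath", -Inf, Inf),
      detail = "extra breath during the maneuver"),
    flutter_any = list(
      passed = !overlaps_window(findings, "flutter_obstruction", -Inf, Inf),
      detail = "flutter during the maneuver"),
    eofe = list(
      passed = eofe_ok,
      detail = sprintf(
        "plateau=%s, FET=%.2f s, best-FVC delta=%s",
        indices$plateau, indices$fet,
        if (is.null(best_fvc_delta)) "n/a"
        else sprintf("%.3f L", best_fvc_delta))),
    glottic_closure_any = list(
      passed = !overlaps_window(findings, "glottic_closure", -Inf, Inf),
      detail = "glottic closure during the maneuver"),
    early_termination = list(
      passed = !(et_present && !eofe_ok),
      detail = "expiration ended before plateau, long FET or repeatable FVC"),
    variable_flow = list(
      passed = !overlaps_window(findings, "variable_flow", -Inf, Inf),
      detail = sprintf("tPEF %.2f s", indices$tpef))
  )
  cat_tab <- qc_criteria()
  stopifnot(all(names(checks) %in% cat_tab$criterion))
  reasons <- data.frame(
    criterion = cat_tab$criterion,
    index = cat_tab$index,
    effect = cat_tab$effect,
    passed = vapply(cat_tab$criterion, function(id) checks[[id]]$passed,
                    logical(1)),
    detail = vapply(cat_tab$criterion, function(id) checks[[id]]$detail,
                    character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  flag <- function(ix, acceptability) {
    rel <- reasons$index %in% c(ix, "both") &
      reasons$effect %in% c("usability",
                            if (acceptability) "acceptability")
    all(reasons$passed[rel])
  }
  structure(
    list(maneuver_id = indices$maneuver_id,
         fev1_acceptable = flag("fev1", TRUE),
         fev1_usable = flag("fev1", FALSE),
         fvc_acceptable = flag("fvc", TRUE),
         fvc_usable = flag("fvc", FALSE),
         reasons = reasons),
    class = "spiro_maneuver_qc"
  )
}

#' @export
print.spiro_maneuver_qc <- function(x, ...) {
  cat(sprintf(
    "<maneuver QC %s: FEV1 %s/%s, FVC %s/%s (acceptable/usable)>\n",
    x$maneuver_id,
    x$fev1_acceptable, x$fev1_usable, x$fvc_acceptable, x$fvc_usable))
  failed <- x$reasons[!x$reasons$passed, ]
  if (nrow(failed))
    cat("  failed:", paste(failed$criterion, collapse = ", "), "\n")
  invisible(x)
}

grade_one <- function(n_acc, n_usable, delta, tiers) {
  if (n_acc == 0) return(if (n_usable >= 1) "U" else "F")
  if (n_acc == 1) return("E")
  if (n_acc >= 3 && delta <= tiers[1]) return("A")
  if (n_acc == 2 && delta <= tiers[1]) return("B")
  if (delta <= tiers[2]) return("C")
  if (delta <= tiers[3]) return("D")
  "E"
}

#' Grade a session's FEV1 and FVC quality (A-F/U)
#'
#' Applies the session-level rating tiers per index: A requires at least
#' three acceptable maneuvers with the two largest values within the first
#' repeatability tier (adult 0.150 L); B is two acceptable within the first
#' tier; C at least two within the second tier (0.200 L); D at least two
#' within the third (0.250 L); E at least two beyond that or exactly one
#' acceptable; U no acceptable but at least one usable maneuver; F neither.
#' Subjects aged 6 or younger use the tighter pediatric tiers
#' (0.100/0.150/0.200 L). Grades A-C are "good quality".
#'
#' @param qcs list of [assess_maneuver()] results, one per maneuver.
#' @param fev1_values,fvc_values numeric vectors aligned with \code{qcs}
#'   (liters; \code{NA} allowed where an index was not measurable).
#' @param subject_age optional age in years.
#' @param config a [spiro_config()] list.
#' @return An object of class \code{"spiro_session_grade"}: per-index
#'   grades and repeatability deltas, acceptable/usable counts, and (after
#'   [generate_messages()]) operator messages and patient guidance.
#' @examples
#' # three clean maneuvers, repeatable within 0.05 L, grade A
#' @export
grade_session <- function(qcs, fev1_values, fvc_values, subject_age = NULL,
                          config = NULL) {
  cfg <- as_config(config)
  if (!length(qcs)) stop("no maneuver QC results supplied", call. = FALSE)
  if (length(fev1_values) != length(qcs) || length(fvc_values) != length(qcs))
    stop("value vectors must align with qcs", call. = FALSE)
  tiers <- if (!is.null(subject_age) && subject_age <= cfg$pediatric_age)
    cfg$repeat_tiers_pediatric else cfg$repeat_tiers
  pull <- function(field) vapply(qcs, `[[`, logical(1), field)
  one_index <- function(acc, usable, values) {
    vals <- values[acc & !is.na(values)]
    delta <- if (length(vals)) repeatability_delta(vals) else 0
    list(n_acc = sum(acc), n_usable = sum(usable), delta = delta,
         grade = grade_one(sum(acc), sum(usable), delta, tiers))
  }
  f1 <- one_index(pull("fev1_acceptable"), pull("fev1_usable"), fev1_values)
  fv <- one_index(pull("fvc_acceptable"), pull("fvc_usable"), fvc_values)
  structure(
    list(fev1_grade = f1$grade, fvc_grade = fv$grade,
         fev1_delta = f1$delta, fvc_delta = fv$delta,
         n_fev1_acceptable = f1$n_acc, n_fev1_usable = f1$n_usable,
         n_fvc_acceptable = fv$n_acc, n_fvc_usable = fv$n_usable,
         messages = character(), guidance = character()),
    class = "spiro_session_grade"
  )
}

#' @export
print.spiro_session_grade <- function(x, ...) {
  cat(sprintf(
    "<session grade: FEV1 %s (delta %.3f L, %d/%d acc/usable), FVC %s (delta %.3f L, %d/%d)>\n",
    x$fev1_grade, x$fev1_delta, x$n_fev1_acceptable, x$n_fev1_usable,
    x$fvc_grade, x$fvc_delta, x$n_fvc_acceptable, x$n_fvc_usable))
  for (m in x$messages) cat("  ! ", m, "\n", sep = "")
  invisible(x)
}

#' Generate operator warnings and patient guidance for a session
#'
#' Emits one operator warning and one patient instruction per distinct
#' failed criterion across the session's maneuvers (deduplicated, ordered
#' by criterion id), plus a prompt to repeat the maneuver whenever either
#' index grades below C. Messages are a function of the set of failed
#' criterion ids only.
#'
#' @param qcs list of [assess_maneuver()] results.
#' @param grade a [grade_session()] result.
#' @return A list with character vectors \code{messages} and
#'   \code{guidance}.
#' @export
generate_messages <- function(qcs, grade) {
  failed <- sort(unique(unlist(lapply(qcs, function(q)
    q$reasons$criterion[!q$reasons$passed]))))
  cat_tab <- qc_criteria()
  rows <- cat_tab[match(failed, cat_tab$criterion), , drop = FALSE]
  messages <- rows$operator_message
  guidance <- unique(rows$guidance)
  if (!(grade$fev1_grade %in% c("A", "B", "C")) ||
      !(grade$fvc_grade %in% c("A", "B", "C"))) {
    messages <- c(messages,
                  "Session quality is below grade C; perform an additional maneuver.")
    guidance <- c(guidance,
                  "Please take a short rest; we will repeat the test once more.")
  }
  list(messages = messages, guidance = guidance)
}

#' Run the full QC pipeline on one session
#'
#' Computes indices and artifact findings for every maneuver, assesses
#' acceptability/usability in two passes (the second pass supplies each
#' maneuver's distance to the session's best usable FVC, which can satisfy
#' the end-of-forced-expiration rule through the repeatability branch),
#' grades the session per index, and attaches operator messages and
#' patient guidance.
#'
#' @param session a [session()] object.
#' @param config a [spiro_config()] list.
#' @return An object of class \code{"spiro_session_report"}: lists
#'   \code{indices}, \code{findings}, \code{qc} (one element per maneuver)
#'   plus \code{grade} and \code{session_id}.
#' @examples
#' tt <- seq(0, 8, by = 0.01)
#' mk <- function(id, fvc) maneuver(id, volume = fvc * (1 - exp(-tt / 0.45)),
#'                                  flow = fvc / 0.45 * exp(-tt / 0.45))
#' s <- session("s1", list(mk("m1", 4.00), mk("m2", 3.96), mk("m3", 4.03)))
#' assess_session(s)$grade
#' @export
assess_session <- function(session, config = NULL) {
  cfg <- as_config(config)
  if (!inherits(session, "spiro_session"))
    stop("not a spiro_session", call. = FALSE)
  idx <- lapply(session$maneuvers, compute_indices, config = cfg)
  finds <- mapply(scan_artifacts, session$maneuvers, idx,
                  MoreArgs = list(config = cfg), SIMPLIFY = FALSE)
  qcs <- mapply(assess_maneuver, idx, finds,
                MoreArgs = list(best_fvc_delta = NULL, config = cfg),
                SIMPLIFY = FALSE)
  fvc_vals <- vapply(idx, `[[`, numeric(1), "fvc")
  usable <- vapply(qcs, `[[`, logical(1), "fvc_usable")
  if (any(usable)) {
    best <- max(fvc_vals[usable])
    deltas <- pmax(best - fvc_vals, 0)
    idx <- mapply(function(ind, d) {
      ind$eofe_met <- eofe_met(ind, d, config = cfg)
      ind
    }, idx, deltas, SIMPLIFY = FALSE)
    qcs <- mapply(function(ind, f, d)
      assess_maneuver(ind, f, best_fvc_delta = d, config = cfg),
      idx, finds, deltas, SIMPLIFY = FALSE)
  }
  fev1_vals <- vapply(idx, `[[`, numeric(1), "fev1")
  grade <- grade_session(qcs, fev1_vals, fvc_vals,
                         subject_age = session$subject_age, config = cfg)
  msg <- generate_messages(qcs, grade)
  grade$messages <- msg$messages
  grade$guidance <- msg$guidance
  structure(
    list(session_id = session$session_id, indices = idx, findings = finds,
         qc = qcs, grade = grade),
    class = "spiro_session_report"
  )
}

#' @export
print.spiro_session_report <- function(x, ...) {
  cat(sprintf("<session report %s: %d maneuver(s)>\n", x$session_id,
              length(x$qc)))
  print(x$grade)
  invisible(x)
}

report_to_list <- function(report) {
  list(
    session_id = report$session_id,
    grade = unclass(report$grade),
    maneuvers = mapply(function(ind, f, q) {
      list(maneuver_id = ind$maneuver_id,
           indices = unclass(ind)[c("t0", "bev", "fev1", "fvc", "pef",
                                    "tpef", "fet", "plateau",
                                    "plateau_onset", "eofe_met")],
           findings = f,
           fev1_acceptable = q$fev1_acceptable,
           fev1_usable = q$fev1_usable,
           fvc_acceptable = q$fvc_acceptable,
           fvc_usable = q$fvc_usable,
           reasons = q$reasons)
    }, report$indices, report$findings, report$qc, SIMPLIFY = FALSE)
  )
}

#' Write a session QC report
#'
#' Serializes an [assess_session()] report to JSON (per-maneuver indices,
#' findings with intervals, criterion-level reasons, session grade,
#' messages and guidance).
#'
#' @param report a \code{spiro_session_report}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Flatten session reports to one row per maneuver
#'
#' Builds the flat audit table (one row per maneuver across sessions) used
#' for batch review: indices, the four QC flags, the per-index session
#' grade and the artifact kinds found.
#'
#' @param reports a list of \code{spiro_session_report} objects (a single
#'   report is also accepted).
#' @return A data.frame.
#' @export
qc_report_table <- function(reports) {
  if (inherits(reports, "spiro_session_report")) reports <- list(reports)
  rows <- lapply(reports, function(rep) {
    do.call(rbind, mapply(function(ind, f, q) {
      data.frame(
        session_id = rep$session_id, maneuver_id = ind$maneuver_id,
        t0 = ind$t0, bev = ind$bev, fev1 = ind$fev1, fvc = ind$fvc,
        pef = ind$pef, tpef = ind$tpef, fet = ind$fet,
        plateau = ind$plateau, eofe_met = ind$eofe_met,
        fev1_acceptable = q$fev1_acceptable, fev1_usable = q$fev1_usable,
        fvc_acceptable = q$fvc_acceptable, fvc_usable = q$fvc_usable,
        fev1_grade = rep$grade$fev1_grade, fvc_grade = rep$grade$fvc_grade,
        artifacts = paste(f$kind, collapse = ";"),
        stringsAsFactors = FALSE)
    }, rep$indices, rep$findings, rep$qc, SIMPLIFY = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
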