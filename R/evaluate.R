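# Evaluation statistics: binary-classification metrics, grade accuracy,
# and the proportion-trend comparison across operator groups.

GRADE_LEVELS <- c("A", "B", "C", "D", "E", "U", "F")

#' Confusion-matrix classification metrics
#'
#' Computes the five standard metrics from truth/prediction pairs:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN) and balanced accuracy (sensitivity+specificity)/2, all
#' as percents. Ratios with a zero denominator are reported as \code{NA}
#' and listed in \code{undefined} rather than silently set to 0.
#'
#' @param truth,pred logical vectors of equal length (>= 1).
#' @return An object of class \code{"eval_metrics"}: counts \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}, the five metrics in percent (exact,
#'   not display-rounded), and \code{undefined}, the names of metrics with
#'   a zero denominator.
#' @examples
#' confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion_metrics <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred lengths differ", call. = FALSE)
  if (!length(truth)) stop("empty input", call. = FALSE)
  truth <- as.logical(truth); pred <- as.logical(pred)
  if (anyNA(truth) || anyNA(pred))
    stop("truth and pred must not contain NA", call. = FALSE)
  tp <- sum(truth & pred); fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  bal <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  vals <- c(sensitivity = sens, specificity = spec,
            balanced_accuracy = bal, ppv = ppv, npv = npv)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec, balanced_accuracy = bal,
         ppv = ppv, npv = npv,
         undefined = names(vals)[is.na(vals)]),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.1f", round_half_up(v, 1))
  cat(sprintf(
    "<eval_metrics TP=%d FP=%d TN=%d FN=%d | bal acc %s, sens %s, spec %s, PPV %s, NPV %s (%%)>\n",
    x$tp, x$fp, x$tn, x$fn, fmt(x$balanced_accuracy), fmt(x$sensitivity),
    fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Balanced accuracy from sensitivity and specificity
#'
#' The identity behind the balanced-accuracy column of a published metrics
#' table: the mean of sensitivity and specificity, display-rounded half-up
#' to one decimal like the other percents.
#'
#' @param sensitivity,specificity percents.
#' @return Balanced accuracy in percent, rounded to 1 decimal.
#' @examples
#' balanced_accuracy(97.8, 92.4)
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  round_half_up((sensitivity + specificity) / 2, 1)
}

#' Exact-match accuracy of quality grades
#'
#' @param truth_grades,pred_grades character vectors of equal length with
#'   values in the 7-grade domain A-F/U.
#' @return Overall exact-match accuracy in percent.
#' @examples
#' grade_accuracy(c("A", "B", "C"), c("A", "B", "D"))
#' @export
grade_accuracy <- function(truth_grades, pred_grades) {
  if (length(truth_grades) != length(pred_grades))
    stop("grade vectors differ in length", call. = FALSE)
  if (!length(truth_grades)) stop("empty input", call. = FALSE)
  bad <- !(c(truth_grades, pred_grades) %in% GRADE_LEVELS)
  if (any(bad))
    stop("invalid grade letter(s): ",
         paste(unique(c(truth_grades, pred_grades)[bad]), collapse = ", "),
         call. = FALSE)
  100 * mean(truth_grades == pred_grades)
}

#' Compare quality proportions across groups
#'
#' Tests homogeneity of per-group proportions (e.g. monthly fractions of
#' acceptable maneuvers) with Pearson's chi-squared test on the k x 2
#' table of successes and failures, without continuity correction.
#' P-values below 1e-4 display as \code{"< .0001"}.
#'
#' @param groups a data.frame with columns \code{label}, \code{num},
#'   \code{den} (successes and totals per group), or a list of
#'   \code{list(label, num, den)} triples. At least 2 groups.
#' @return An object of class \code{"trend_result"}: the input counts,
#'   \code{percent} (exact) and \code{percent_display} (half-up, 1
#'   decimal) per group, \code{chi2}, \code{df}, \code{p_value} and
#'   \code{p_display}.
#' @examples
#' monthly_quality_comparison(data.frame(
#'   label = c("month 0", "month 1", "month 2"),
#'   num = c(140, 359, 771), den = c(171, 431, 840)))
#' @export
monthly_quality_comparison <- function(groups) {
  if (is.data.frame(groups)) {
    df <- groups
  } else {
    df <- do.call(rbind, lapply(groups, function(g)
      data.frame(label = g[[1]], num = g[[2]], den = g[[3]],
                 stringsAsFactors = FALSE)))
  }
  if (!all(c("label", "num", "den") %in% names(df)))
    stop("groups need fields label, num, den", call. = FALSE)
  if (nrow(df) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(df$den <= 0)) stop("zero or negative denominator", call. = FALSE)
  if (any(df$num < 0) || any(df$num > df$den))
    stop("numerators must lie in [0, denominator]", call. = FALSE)
  tab <- cbind(df$num, df$den - df$num)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  pct <- 100 * df$num / df$den
  structure(
    list(label = df$label, num = df$num, den = df$den,
         percent = pct, percent_display = round_half_up(pct, 1),
         chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value,
         p_display = if (ct$p.value < 1e-4) "< .0001"
         else sprintf("%.4f", ct$p.value)),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat("<trend_result>\n")
  for (i in seq_along(x$label))
    cat(sprintf("  %-10s %d/%d (%.1f%%)\n", x$label[i], x$num[i], x$den[i],
                x$percent_display[i]))
  cat(sprintf("  chi2 = %.2f (df %d), p %s\n", x$chi2, x$df,
              if (x$p_display == "< .0001") x$p_display
              else paste("=", x$p_display)))
  invisible(x)
}

truth_flags <- function(truth) {
  rows <- lapply(truth, function(ts) {
    do.call(rbind, lapply(ts$maneuvers, function(tm)
      data.frame(session_id = ts$session_id,
                 maneuver_id = tm$maneuver_id,
                 fev1_acceptable = tm$fev1_acceptable,
                 fev1_usable = tm$fev1_usable,
                 fvc_acceptable = tm$fvc_acceptable,
                 fvc_usable = tm$fvc_usable,
                 stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}

#' Run the QC pipeline over a batch of session files
#'
#' Reads each session file, runs [assess_session()], and writes one JSON
#' report per session plus a flat CSV audit table into \code{report_dir}.
#' Unreadable or malformed files are logged and skipped. When a truth
#' sidecar (written by [write_truth()]) is supplied, an evaluation report
#' with per-flag [confusion_metrics()] and per-index [grade_accuracy()] is
#' also produced.
#'
#' @param session_paths character vector of session-file paths.
#' @param truth_path optional path to a truth JSON sidecar.
#' @param report_dir output directory (created if missing).
#' @param config a [spiro_config()] list.
#' @return Invisibly, a list with \code{n_ok}, \code{n_skipped},
#'   \code{skipped} (named character vector of error messages),
#'   \code{table} (the flat audit data.frame) and, with truth,
#'   \code{metrics} (per-flag \code{eval_metrics}) and
#'   \code{grade_accuracy} (named percents).
#' @export
run_batch <- function(session_paths, truth_path = NULL,
                      report_dir = "qc_reports", config = NULL) {
  cfg <- as_config(config)
  if (!dir.exists(report_dir))
    dir.create(report_dir, recursive = TRUE)
  reports <- list()
  skipped <- character()
  for (p in session_paths) {
    rep <- tryCatch(
      assess_session(read_session(p, config = cfg), config = cfg),
      error = function(e) conditionMessage(e))
    if (is.character(rep)) {
      skipped[p] <- rep
      message("skipping ", p, ": ", rep)
      next
    }
    write_qc_report(rep, file.path(report_dir,
                                   paste0(rep$session_id, "_qc.json")))
    reports[[rep$session_id]] <- rep
  }
  out <- list(n_ok = length(reports), n_skipped = length(skipped),
              skipped = skipped)
  if (length(reports)) {
    tab <- qc_report_table(reports)
    utils::write.csv(tab, file.path(report_dir, "maneuvers.csv"),
                     row.names = FALSE)
    out$table <- tab
    if (!is.null(truth_path)) {
      truth <- read_truth(truth_path)
      tf <- truth_flags(truth)
      key <- paste(tab$session_id, tab$maneuver_id)
      tf <- tf[match(key, paste(tf$session_id, tf$maneuver_id)), ]
      if (anyNA(tf$fev1_usable))
        stop("truth sidecar does not cover all assessed maneuvers",
             call. = FALSE)
      flags <- c("fev1_acceptable", "fev1_usable",
                 "fvc_acceptable", "fvc_usable")
      out$metrics <- lapply(stats::setNames(flags, flags), function(fl)
        confusion_metrics(tf[[fl]], tab[[fl]]))
      truth_grades <- do.call(rbind, lapply(truth, function(ts)
        data.frame(session_id = ts$session_id, fev1 = ts$fev1_grade,
                   fvc = ts$fvc_grade, stringsAsFactors = FALSE)))
      pred_grades <- unique(tab[c("session_id", "fev1_grade", "fvc_grade")])
      tg <- truth_grades[match(pred_grades$session_id,
                               truth_grades$session_id), ]
      out$grade_accuracy <- c(
        fev1 = grade_accuracy(tg$fev1, pred_grades$fev1_grade),
        fvc = grade_accuracy(tg$fvc, pred_grades$fvc_grade))
      eval_doc <- list(
        metrics = lapply(out$metrics, unclass),
        grade_accuracy = as.list(out$grade_accuracy))
      jsonlite::write_json(eval_doc,
                           file.path(report_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
  }
  invisible(out)
}
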