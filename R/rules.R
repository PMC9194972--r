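# Replan-trigger rule evaluation: does a patient's GDSA trace, under a
# simple threshold rule, predict the physician's decision to replan?
# Exceedance is signed positive (GDSA > threshold) by default: anatomy
# loss (weight loss, tumor shrinkage) raises the transit signal, and it is
# positive deviations that motivate a replan. A magnitude mode exists for
# sensitivity studies.

#' A replan-trigger rule
#'
#' The rule fires when at least `min_exceeding_fractions` fractions exceed
#' `threshold_percent`, counting only fractions before the final
#' `exclude_last_n_fractions` of the course (a deviation so late that
#' little treatment remains cannot justify a replan).
#'
#' @param threshold_percent GDSA threshold in percent (> 0).
#' @param min_exceeding_fractions Minimum number of qualifying fractions
#'   (any fractions, not necessarily consecutive).
#' @param exclude_last_n_fractions Number of final fractions excluded from
#'   the qualifying window.
#' @param magnitude If `TRUE`, compare `|GDSA|` instead of signed GDSA.
#' @param label Optional short name.
#' @return A `rule_spec` object.
#' @export
rule_spec <- function(threshold_percent, min_exceeding_fractions = 1L,
                      exclude_last_n_fractions = 0L, magnitude = FALSE,
                      label = NULL) {
  if (threshold_percent <= 0) abort("`threshold_percent` must be > 0.", class = "epidwatch_config_error")
  if (min_exceeding_fractions < 1) abort("`min_exceeding_fractions` must be >= 1.", class = "epidwatch_config_error")
  if (exclude_last_n_fractions < 0) abort("`exclude_last_n_fractions` must be >= 0.", class = "epidwatch_config_error")
  structure(list(threshold_percent = threshold_percent,
                 min_exceeding_fractions = as.integer(min_exceeding_fractions),
                 exclude_last_n_fractions = as.integer(exclude_last_n_fractions),
                 magnitude = isTRUE(magnitude),
                 label = label %||% sprintf(">%g%% x%d excl%d", threshold_percent,
                                            min_exceeding_fractions,
                                            exclude_last_n_fractions)),
            class = "rule_spec")
}

#' The five standard replan-trigger rules
#'
#' A: one fraction > 3%. B: one fraction > 2%. C: two fractions > 2%.
#' D: two fractions > 2%, not counting the last five fractions. E: one
#' fraction > 2%, not counting the last five fractions.
#'
#' @return A named list of [rule_spec()] objects `A`..`E`.
#' @export
replan_rules <- function() {
  list(
    A = rule_spec(3, 1, 0, label = "One fraction > 3%"),
    B = rule_spec(2, 1, 0, label = "One fraction > 2%"),
    C = rule_spec(2, 2, 0, label = "Two fractions > 2%"),
    D = rule_spec(2, 2, 5, label = "Two fractions > 2%, not last 5"),
    E = rule_spec(2, 1, 5, label = "One fraction > 2%, not last 5")
  )
}

#' Apply a replan-trigger rule to one GDSA trace
#'
#' @param trace Numeric vector of per-fraction GDSA values in date order
#'   (complete fractions only), or a `gdsa_records` tibble for one course.
#' @param rule A [rule_spec()].
#' @return `TRUE` if the rule fires. A course no longer than
#'   `exclude_last_n_fractions` evaluates over an empty window and returns
#'   `FALSE`.
#' @export
apply_rule <- function(trace, rule) {
  if (is.data.frame(trace)) {
    trace <- complete_sorted(trace)$gdsa_percent
  }
  n <- length(trace)
  window <- seq_len(max(0L, n - rule$exclude_last_n_fractions))
  v <- trace[window]
  if (rule$magnitude) v <- abs(v)
  sum(v > rule$threshold_percent) >= rule$min_exceeding_fractions
}

#' Contingency table of rule predictions against replan labels
#'
#' @param predictions Named logical vector (or plain logical vector) of
#'   per-patient rule decisions.
#' @param labels Logical vector of physician replan decisions ("ground
#'   truth"), with the same patients (names, when present, must match as
#'   sets).
#' @return An object of class `contingency_table` with fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
contingency <- function(predictions, labels) {
  if (!is.null(names(predictions)) && !is.null(names(labels))) {
    if (!setequal(names(predictions), names(labels))) {
      abort("Prediction and label patient sets differ.",
            class = "epidwatch_identity_error")
    }
    labels <- labels[names(predictions)]
  } else if (length(predictions) != length(labels)) {
    abort("Prediction and label lengths differ.", class = "epidwatch_identity_error")
  }
  structure(list(
    tp = sum(predictions & labels),
    fn = sum(!predictions & labels),
    fp = sum(predictions & !labels),
    tn = sum(!predictions & !labels)
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> TP %d  FN %d  FP %d  TN %d  (sens %.3f, spec %.3f)\n",
              x$tp, x$fn, x$fp, x$tn, sensitivity(x), specificity(x)))
  invisible(x)
}

undefined_proportion <- function(what) {
  warn(sprintf("%s is undefined (zero denominator).", what),
       class = "epidwatch_undefined_signal")
  NA_real_
}

#' Sensitivity and specificity of a contingency table
#'
#' `sensitivity` is TP/(TP+FN); `specificity` is TN/(TN+FP). A zero
#' denominator yields `NA` with a classed warning.
#'
#' @param ct A [contingency()] table, or the counts as named arguments via
#'   `contingency_counts()`.
#' @return A proportion in \[0, 1\], or `NA`.
#' @export
sensitivity <- function(ct) {
  if (ct$tp + ct$fn == 0) return(undefined_proportion("Sensitivity"))
  ct$tp / (ct$tp + ct$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(ct) {
  if (ct$tn + ct$fp == 0) return(undefined_proportion("Specificity"))
  ct$tn / (ct$tn + ct$fp)
}

#' Build a contingency table directly from counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `contingency_table`.
#' @export
contingency_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) abort("Counts must be non-negative.", class = "epidwatch_config_error")
  structure(as.list(counts), class = "contingency_table")
}

#' Truncate a proportion or percentage for tabulation
#'
#' Floors towards zero at the given number of decimals -- the convention
#' used when reporting tabulated sensitivities/specificities (e.g.
#' 105/133 = 0.789... tabulated as 0.78).
#'
#' @param x Numeric.
#' @param digits Decimal places kept.
#' @return Truncated numeric.
#' @export
truncate_decimal <- function(x, digits = 2) {
  floor(x * 10^digits) / 10^digits
}

#' Evaluate replan-trigger rules over a patient cohort
#'
#' @param traces Named list of per-patient GDSA traces (numeric vectors in
#'   date order), or a `gdsa_records` tibble covering several courses (one
#'   trace per patient_id).
#' @param labels Named logical vector of replan decisions per patient.
#' @param rules Named list of [rule_spec()] objects (default
#'   [replan_rules()]).
#' @return A tibble with one row per rule: `rule`, `description`, `tp`,
#'   `fn`, `fp`, `tn`, `sensitivity`, `specificity` (exact), and the
#'   two-decimal truncated `sensitivity_2dp` / `specificity_2dp`.
#' @export
evaluate_rules <- function(traces, labels, rules = replan_rules()) {
  if (is.data.frame(traces)) {
    rec <- traces
    ids <- unique(rec$patient_id)
    traces <- setNames(map(ids, function(p) {
      complete_sorted(rec[rec$patient_id == p, ])$gdsa_percent
    }), ids)
  }
  if (length(traces) == 0) abort("No traces supplied.", class = "epidwatch_config_error")
  labels <- labels[names(traces)]
  rows <- imap(rules, function(rs, name) {
    pred <- map_lgl(traces, apply_rule, rule = rs)
    ct <- contingency(pred, labels)
    se <- sensitivity(ct)
    sp <- specificity(ct)
    tibble(rule = name, description = rs$label,
           tp = ct$tp, fn = ct$fn, fp = ct$fp, tn = ct$tn,
           sensitivity = se, specificity = sp,
           sensitivity_2dp = truncate_decimal(se, 2),
           specificity_2dp = truncate_decimal(sp, 2))
  })
  bind_rows(rows)
}
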