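#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_errorbar geom_raster labs theme_minimal scale_fill_gradient2
#'   facet_wrap
NULL

#' Plot a per-fraction GDSA trace
#'
#' Fraction-by-fraction GDSA values with the trend (+/-3%) and acute
#' (+/-10%) alert bands; omitted fractions are drawn hollow.
#'
#' @param records A `gdsa_records` tibble (one or more courses; faceted by
#'   patient when several are present).
#' @param config A [flag_config()] supplying the band levels.
#' @return A ggplot object.
#' @export
plot_gdsa_trace <- function(records, config = flag_config()) {
  p <- ggplot(records, aes(x = fraction_index, y = gdsa_percent)) +
    geom_hline(yintercept = c(-1, 1) * config$type_b_threshold_percent,
               linetype = "dashed", colour = "orange") +
    geom_hline(yintercept = c(-1, 1) * config$type_a_threshold_percent,
               linetype = "dashed", colour = "red") +
    geom_line(data = function(d) d[d$status == "complete", ], na.rm = TRUE) +
    geom_point(aes(shape = status), na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(complete = 16, omitted = 1)) +
    labs(x = "Fraction", y = "GDSA mean (%)") +
    theme_minimal()
  if (length(unique(records$patient_id)) > 1) {
    p <- p + facet_wrap(~patient_id)
  }
  p
}

#' @rdname plot_gdsa_trace
#' @param object,x A `gdsa_records` tibble.
#' @param ... Ignored.
#' @method autoplot gdsa_records
#' @export
autoplot.gdsa_records <- function(object, ...) plot_gdsa_trace(object, ...)

#' Plot daily clinic means as a control chart
#'
#' Daily clinic-wide GDSA mean with +/-1 SD whiskers (patient variability)
#' and the machine-flag band around zero.
#'
#' @param summaries A `daily_summaries` tibble.
#' @param config A [flag_config()].
#' @return A ggplot object.
#' @export
plot_daily_means <- function(summaries, config = flag_config()) {
  s <- mutate(summaries,
              lower = mean_percent - ifelse(is.na(sd_percent), 0, sd_percent),
              upper = mean_percent + ifelse(is.na(sd_percent), 0, sd_percent))
  ggplot(s, aes(x = date, y = mean_percent)) +
    geom_hline(yintercept = c(-1, 1) * config$machine_threshold_percent,
               linetype = "dashed", colour = "red") +
    geom_errorbar(aes(ymin = lower, ymax = upper), width = 0.2, colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = "Treatment day", y = "Daily GDSA mean (%)") +
    theme_minimal()
}

#' @rdname plot_daily_means
#' @param object,x A `daily_summaries` tibble.
#' @param ... Ignored.
#' @method autoplot daily_summaries
#' @export
autoplot.daily_summaries <- function(object, ...) plot_daily_means(object, ...)

#' Relative-difference panel between a fraction and the baseline image
#'
#' @param fraction,baseline [epid_image()] objects of matching shape.
#' @return A ggplot raster of the per-pixel relative difference (%).
#' @export
plot_difference_panel <- function(fraction, baseline) {
  rel <- 100 * (fraction$pixels - baseline$pixels) /
    pmax(baseline$pixels, .Machine$double.eps)
  df <- tidyr::expand_grid(row = seq_len(nrow(rel)), col = seq_len(ncol(rel)))
  df$value <- as.vector(t(rel))
  ggplot(df, aes(x = col, y = row, fill = value)) +
    geom_raster() +
    scale_fill_gradient2(name = "diff (%)", limits = c(-15, 15),
                         oob = scales_squish) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(-15, 15)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a contingency table
#'
#' @param x A [contingency()] table.
#' @param ... Ignored.
#' @return `tidy()`: one row per cell (`cell`, `count`). `glance()`: a
#'   one-row tibble with the counts, sensitivity and specificity.
#' @method tidy contingency_table
#' @export
tidy.contingency_table <- function(x, ...) {
  tibble(cell = c("tp", "fn", "fp", "tn"),
         count = c(x$tp, x$fn, x$fp, x$tn))
}

#' @rdname tidy.contingency_table
#' @method glance contingency_table
#' @export
glance.contingency_table <- function(x, ...) {
  tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
         n = x$tp + x$fn + x$fp + x$tn,
         sensitivity = sensitivity(x), specificity = specificity(x))
}
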