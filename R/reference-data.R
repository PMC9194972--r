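# Reference tabulations from a published retrospective surveillance cohort
# on a Halcyon transit imager (1633 patients, 35 759 fractions, Nov 2017 -
# Dec 2020; 345-patient 6-month prospective follow-up). These printed
# counts are the worked-example inputs for the arithmetic-consistency
# checks and the replan-rule sensitivity/specificity reproduction.

#' Site-specific distribution of a reference surveillance cohort
#'
#' Per-treatment-site patient and fraction counts, GDSA mean/SD, printed
#' percentage share of fractions, and the number of fractions whose GDSA
#' magnitude exceeded 3%, from a retrospective clinical cohort observed
#' with this surveillance design.
#'
#' @return A tibble with one row per treatment site.
#' @export
site_distribution_reference <- function() {
  tibble(
    site = c("abdomen_pelvis", "head_neck", "brain", "chest_lung", "extremities"),
    patients = c(671L, 390L, 283L, 254L, 35L),
    fractions = c(17134L, 8909L, 5393L, 3833L, 490L),
    share_percent_printed = c(48, 25, 15, 11, 1),
    mean_gdsa_percent = c(-0.02, 0.34, 0.07, 0.34, -0.26),
    sd_gdsa_percent = c(0.86, 1.15, 0.57, 1.46, 1.19),
    n_exceeding_3pct = c(126L, 237L, 8L, 206L, 20L)
  )
}

#' Replan-rule contingency counts of a reference head-and-neck cohort
#'
#' True/false positive/negative counts for the five standard replan-trigger
#' rules ([replan_rules()]) evaluated against physician replan decisions
#' (52 replans among 182 head-and-neck patients), together with the
#' tabulated (two-decimal truncated) sensitivity and specificity.
#'
#' @return A tibble with one row per rule `A`..`E`.
#' @export
replan_contingency_reference <- function() {
  tibble(
    rule = c("A", "B", "C", "D", "E"),
    tp = c(10L, 33L, 28L, 28L, 33L),
    fn = c(38L, 19L, 24L, 24L, 19L),
    fp = c(28L, 64L, 50L, 37L, 51L),
    tn = c(105L, 66L, 80L, 93L, 79L),
    sensitivity_printed = c(0.2, 0.63, 0.53, 0.53, 0.63),
    specificity_printed = c(0.78, 0.50, 0.61, 0.71, 0.60)
  )
}

#' Cohort-level counts of the reference surveillance study
#'
#' @return A list: retrospective patients/fractions and consecutive-
#'   fraction (Type-B) flag counts, and the corresponding prospective
#'   counts.
#' @export
surveillance_cohort_reference <- function() {
  list(
    retrospective_patients = 1633L,
    retrospective_fractions = 35759L,
    retrospective_type_b_patients = 45L,
    prospective_patients = 345L,
    prospective_type_b_patients = 13L
  )
}
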