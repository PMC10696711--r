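# Published reference results for the six-class neonatal LUS task.
#
# The clinical cohort behind this framework is access-restricted, so its
# per-image data cannot ship here; what was published are row-percentage
# confusion matrices (two decimals) for four evaluation settings plus the
# cohort composition. These printed summaries are inputs: they allow the
# metric arithmetic (accuracy, weighted F1) to be recomputed and checked
# without the restricted images.

#' Cohort composition of the reference clinical data sets
#'
#' Per-class patient, video and image counts of the imbalanced (as
#' collected) and balanced (four patients per condition) reference data
#' sets.
#'
#' @return List with data frames `imbalanced` and `balanced`.
#' @export
reference_cohorts <- function() {
  list(
    imbalanced = data.frame(
      class = LUS_CLASSES,
      patients = c(6L, 6L, 7L, 5L, 7L, 11L),
      videos = c(37L, 36L, 61L, 21L, 49L, 106L),
      images = c(185L, 180L, 305L, 105L, 245L, 530L)),
    balanced = data.frame(
      class = LUS_CLASSES,
      patients = rep(4L, 6L),
      videos = c(24L, 24L, 24L, 19L, 24L, 24L),
      images = rep(120L, 6L))
  )
}

#' Published confusion matrices (row percentages) of the reference study
#'
#' Row-percentage confusion matrices for the four cross-validation
#' settings of the reference clinical evaluation: per-image leave-one-out
#' (LOO) and per-subject leave-one-subject-out (LOSO), each on the
#' balanced and imbalanced cohorts. Rows are true classes, columns
#' predicted classes, in [LUS_CLASSES] order. The published overall
#' accuracies and weighted F1 scores are attached so metric arithmetic
#' can be validated against them.
#'
#' @return Named list of settings; each has `rowpct` (6 x 6 matrix),
#'   `row_totals`, `accuracy` (percent) and `weighted_f1`.
#' @export
reference_confusions <- function() {
  dn <- list(true = LUS_CLASSES, predicted = LUS_CLASSES)
  m <- function(...) matrix(c(...), 6, 6, byrow = TRUE, dimnames = dn)
  bal <- rep(120L, 6L)
  imb <- c(185L, 180L, 305L, 105L, 245L, 530L)
  list(
    loo_balanced = list(
      rowpct = m(98.33, 0, 0, 0.83, 0, 0.83,
                 0, 100, 0, 0, 0, 0,
                 0, 0, 95.83, 0, 4.17, 0,
                 9.17, 0, 0.83, 76.67, 0, 13.33,
                 0, 0, 4.17, 0, 92.5, 3.33,
                 3.33, 0, 0, 3.33, 0, 93.33),
      row_totals = bal, accuracy = 92.78, weighted_f1 = 0.927),
    loo_imbalanced = list(
      rowpct = m(17.84, 0, 0, 7.03, 0, 75.14,
                 0, 100, 0, 0, 0, 0,
                 0, 0, 99.02, 0, 0.98, 0,
                 8.57, 0, 12.38, 17.14, 25.71, 36.19,
                 2.86, 0, 8.98, 5.31, 57.55, 25.31,
                 4.53, 0, 0, 2.26, 2.83, 90.38),
      row_totals = imb, accuracy = 74.39, weighted_f1 = 0.740),
    loso_balanced = list(
      rowpct = m(93.33, 0, 0, 1.67, 0, 5,
                 0, 100, 0, 0, 0, 0,
                 0, 0, 78.33, 0, 21.67, 0,
                 11.67, 0, 2.5, 40.83, 5.83, 39.17,
                 0, 0, 28.33, 0, 52.5, 19.17,
                 9.17, 0, 0, 5.83, 0, 85),
      row_totals = bal, accuracy = 75.00, weighted_f1 = 0.713),
    loso_imbalanced = list(
      rowpct = m(4.86, 0, 0, 11.89, 0, 83.24,
                 0, 100, 0, 0, 0, 0,
                 0, 0, 96.39, 0, 3.61, 0,
                 23.81, 0, 15.24, 3.81, 22.86, 34.29,
                 5.71, 0, 17.96, 6.12, 39.59, 30.61,
                 13.96, 0, 0, 5.09, 5.47, 75.47),
      row_totals = imb, accuracy = 63.48, weighted_f1 = 0.606)
  )
}
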