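#' Decision rules predicting the IHC expression pattern
#'
#' The three explicit screening rules operating on the four-grade marker
#' scores and the histology category:
#' \describe{
#'   \item{basal-like}{CK5/6 grade 3, or CK5/6 grade >= 2 together with
#'     p63 grade >= 2, or CK5/6 grade >= 2 together with squamous
#'     differentiation histology.  ("2+" in a compound rule is read as a
#'     floor, so grade 3 satisfies it too.)}
#'   \item{classical}{GATA6 grade 3 and HNF4a grade 3.}
#'   \item{not basal-like}{CK5/6 grade 0 or p63 grade 0.}
#' }
#' `predict_basal`, `predict_classical` and `predict_not_basal` evaluate
#' one rule each; [classify_cases()] applies all three with precedence.
#'
#' @param ck56,p63,gata6,hnf4a Integer grade vectors (0-3).
#' @param histology Histology factor/character
#'   (`glandular|por_comp|sq_diff`).
#' @return Logical vector.
#' @name rules
NULL

#' @rdname rules
#' @export
predict_basal <- function(ck56, p63, histology) {
  check_int_range(ck56, 0L, 3L, "ck56 grade")
  check_int_range(p63, 0L, 3L, "p63 grade")
  histology <- parse_enum(histology, histology_levels(), "histology")
  ck56 == 3L | (ck56 >= 2L & p63 >= 2L) | (ck56 >= 2L & histology == "sq_diff")
}

#' @rdname rules
#' @export
predict_classical <- function(gata6, hnf4a) {
  check_int_range(gata6, 0L, 3L, "gata6 grade")
  check_int_range(hnf4a, 0L, 3L, "hnf4a grade")
  gata6 == 3L & hnf4a == 3L
}

#' @rdname rules
#' @export
predict_not_basal <- function(ck56, p63) {
  check_int_range(ck56, 0L, 3L, "ck56 grade")
  check_int_range(p63, 0L, 3L, "p63 grade")
  ck56 == 0L | p63 == 0L
}

#' Apply the pattern-prediction rules to a cohort
#'
#' Evaluates the basal-like, not-basal and classical rules for every case
#' with precedence basal > not-basal > classical: when the basal rule
#' fires, the not-basal flag is suppressed (the two can formally co-fire
#' for a CK5/6 2+ / p63 0 / squamous-differentiation case).  The
#' classical flag is independent of the basal-axis flags.  A case with
#' CK5/6 grade 2 and poorly-differentiated-component histology on which no
#' rule fires is marked equivocal, matching the combination reported as
#' not classifiable by the rules alone.
#'
#' @param cohort An `ihc_cohort` (or anything [as_cohort()] accepts).
#' @return A `rule_prediction` data frame: `case_id`, logical
#'   `basal_pred`, `not_basal_pred`, `classical_pred`, `equivocal`.
#' @export
classify_cases <- function(cohort) {
  cohort <- as_cohort(cohort)
  basal <- predict_basal(cohort$ck56_grade, cohort$p63_grade, cohort$histology)
  not_basal <- predict_not_basal(cohort$ck56_grade, cohort$p63_grade) & !basal
  classical <- predict_classical(cohort$gata6_grade, cohort$hnf4a_grade)
  equivocal <- cohort$ck56_grade == 2L & cohort$histology == "por_comp" &
    !basal & !not_basal & !classical
  out <- data.frame(case_id = cohort$case_id,
                    basal_pred = basal,
                    not_basal_pred = not_basal,
                    classical_pred = classical,
                    equivocal = equivocal,
                    stringsAsFactors = FALSE)
  class(out) <- c("rule_prediction", "data.frame")
  out
}

#' Sensitivity / specificity of a binary prediction
#'
#' @param predictions Logical vector of predicted positives.
#' @param truth Logical vector of true positives, same length.
#' @return A `confusion_summary` list: `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity` = TP / (TP + FN), `specificity` = TN / (TN + FP).  A
#'   rate whose denominator is zero (degenerate truth) is reported as
#'   `NA`, never as 0.
#' @examples
#' sens_spec(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
#' @export
sens_spec <- function(predictions, truth) {
  predictions <- as.logical(predictions)
  truth <- as.logical(truth)
  if (length(predictions) != length(truth) || anyNA(predictions) || anyNA(truth))
    ihcsub_error("predictions and truth must be equal-length logicals without NA",
                 "range_error")
  TP <- sum(predictions & truth)
  FP <- sum(predictions & !truth)
  TN <- sum(!predictions & !truth)
  FN <- sum(!predictions & truth)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> TP=%d FP=%d TN=%d FN=%d  sens=%s spec=%s\n",
              x$TP, x$FP, x$TN, x$FN,
              format(x$sensitivity, digits = 4), format(x$specificity, digits = 4)))
  invisible(x)
}

#' Evaluate the basal-like rule against a reference pattern
#'
#' Convenience evaluation of the basal-like screening rule against a
#' reference pattern labeling (latent pattern of a synthetic cohort, or a
#' clustering assignment).  Because the equivocal state is explicit, the
#' rates are reported both with equivocal cases counted as rule-negative
#' and with equivocal cases excluded.
#'
#' @param cohort An `ihc_cohort`.
#' @param truth Reference basal indicator: logical vector, or the name of
#'   a pattern column (`"latent_pattern"` or `"pattern"`) whose value
#'   `"basal_like"` defines the positives.
#' @return List with `included` and `excluded` `confusion_summary`
#'   elements and the prediction table.
#' @export
evaluate_basal_rule <- function(cohort, truth = "latent_pattern") {
  cohort <- as_cohort(cohort)
  if (is.character(truth) && length(truth) == 1) {
    col <- cohort[[truth]]
    if (is.null(col))
      ihcsub_error(paste("no such pattern column:", truth), "schema_error")
    truth <- col == "basal_like"
  }
  pred <- classify_cases(cohort)
  keep <- !pred$equivocal
  list(predictions = pred,
       included = sens_spec(pred$basal_pred, truth),
       excluded = sens_spec(pred$basal_pred[keep], truth[keep]))
}
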