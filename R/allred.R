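#' Allred total score
#'
#' Sum of the staining intensity score (0 negative, 1 weak, 2 moderate,
#' 3 strong) and the proportional score (0: 0%, 1: <1%, 2: 1-10%,
#' 3: 10-33%, 4: 33-67%, 5: >67%), giving a total in 0-8.  A stain with
#' intensity 0 must have proportion 0 and vice versa, so totals 1 is
#' unattainable (the smallest positive stain is 1 + 1 = 2).
#'
#' @param intensity Integer vector, each in 0-3.
#' @param proportion Integer vector, each in 0-5.
#' @return Integer vector of totals in 0-8.
#' @examples
#' allred_total(3, 5)  # 8, the strongest possible stain
#' allred_total(0, 0)  # 0
#' @export
allred_total <- function(intensity, proportion) {
  check_int_range(intensity, 0L, 3L, "intensity")
  check_int_range(proportion, 0L, 5L, "proportion")
  if (length(intensity) != length(proportion))
    ihcsub_error("intensity and proportion must have equal length", "range_error")
  bad <- xor(intensity == 0L, proportion == 0L)
  if (any(bad))
    ihcsub_error(
      sprintf("inconsistent zero pair at position %d: intensity=%d, proportion=%d (intensity 0 iff proportion 0)",
              which(bad)[1], intensity[which(bad)[1]], proportion[which(bad)[1]]),
      "zero_pair_error")
  as.integer(intensity + proportion)
}

check_int_range <- function(x, lo, hi, what) {
  if (length(x) == 0 || anyNA(x) || any(x != as.integer(x)))
    ihcsub_error(sprintf("%s must be integer-valued and non-missing", what),
                 "range_error")
  if (any(x < lo | x > hi))
    ihcsub_error(sprintf("%s out of range [%d, %d]: %s", what, lo, hi,
                         paste(x[x < lo | x > hi], collapse = ", ")),
                 "range_error")
  invisible(x)
}

#' Collapse an Allred total score to the four-grade scale
#'
#' Totals 0-2 map to grade 0, 3-5 to grade 1 ("1+"), 6-7 to grade 2
#' ("2+") and 8 to grade 3 ("3+").
#'
#' @param total Integer vector of Allred totals in 0-8.
#' @return Integer vector of grades in 0-3.
#' @examples
#' grade_of_total(c(0, 2, 3, 5, 6, 7, 8))  # 0 0 1 1 2 2 3
#' @export
grade_of_total <- function(total) {
  check_int_range(total, 0L, 8L, "total")
  c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 3L)[total + 1L]
}

#' Render / parse grade tokens
#'
#' Grades are integers 0-3 internally and rendered `"0"`, `"1+"`, `"2+"`,
#' `"3+"` externally.
#' @param grade Integer vector in 0-3.
#' @return `render_grade`: character vector of tokens.
#' @export
render_grade <- function(grade) {
  check_int_range(grade, 0L, 3L, "grade")
  c("0", "1+", "2+", "3+")[grade + 1L]
}

#' @rdname render_grade
#' @param token Character vector of `"0"/"1+"/"2+"/"3+"` tokens.
#' @return `parse_grade`: integer vector in 0-3.
#' @export
parse_grade <- function(token) {
  g <- match(token, c("0", "1+", "2+", "3+")) - 1L
  if (anyNA(g))
    ihcsub_error(sprintf("unknown grade token: %s",
                         paste(unique(token[is.na(g)]), collapse = ", ")),
                 "enum_error")
  g
}

#' Grade matrix of a cohort
#'
#' The n x 4 matrix of four-grade marker scores, one row per case, columns
#' in the fixed order CK56, P63, GATA6, HNF4A.  This is the input space of
#' the clustering that defines the expression patterns.
#'
#' @param cohort An `ihc_cohort`.
#' @param values `"grade"` (default) for the 0-3 grades or `"total"` for
#'   the raw 0-8 Allred totals.
#' @return Integer matrix with case ids as row names.
#' @export
grade_matrix <- function(cohort, values = c("grade", "total")) {
  values <- match.arg(values)
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0)
    ihcsub_error("cohort is empty", "empty_cohort_error")
  cols <- paste0(ihc_markers(), "_", values)
  m <- as.matrix(cohort[, cols])
  dimnames(m) <- list(cohort$case_id, unname(marker_labels()))
  storage.mode(m) <- "integer"
  m
}

#' Composite IHC score of a grade row
#'
#' `(CK5/6 + p63) - (GATA6 + HNF4a)` on the 0-3 grade scale, range -6..6.
#' High values correspond to the basal-like marker profile (high CK5/6 and
#' p63 with low GATA6 and HNF4a) and low values to the classical profile.
#' Used only to label clusters deterministically; it is not itself a
#' classifier.
#'
#' @param grades A length-4 grade vector in panel order, or an n x 4 grade
#'   matrix as returned by [grade_matrix()].
#' @return Numeric vector of composite scores.
#' @examples
#' ihc_composite_score(c(3, 3, 0, 0))  #  6: fully basal profile
#' ihc_composite_score(c(0, 0, 3, 3))  # -6: fully classical profile
#' @export
ihc_composite_score <- function(grades) {
  if (is.null(dim(grades))) grades <- matrix(grades, nrow = 1)
  if (ncol(grades) != 4)
    ihcsub_error("grade input must have 4 columns (CK56, P63, GATA6, HNF4A)",
                 "range_error")
  check_int_range(as.vector(grades), 0L, 3L, "grade")
  as.numeric((grades[, 1] + grades[, 2]) - (grades[, 3] + grades[, 4]))
}
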