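#' Construct / validate an IHC cohort
#'
#' An `ihc_cohort` is a data frame with one row per case carrying the
#' Allred intensity and proportion for each of the four panel markers
#' (with derived totals and grades), the histology category, clinical
#' stage (NA when unknown), sex, age, overall-survival time in days and
#' the death-event flag.  Synthetic cohorts additionally carry the latent
#' expression pattern that generated each case.
#'
#' @param df A data frame with columns `case_id`,
#'   `<marker>_intensity` and `<marker>_proportion` for each of `ck56`,
#'   `p63`, `gata6`, `hnf4a`, plus `histology`
#'   (`glandular|por_comp|sq_diff`), `stage` (`I|II|III|IV` or NA), `sex`
#'   (`M|F`), `age`, `time_days`, `event` (0/1), and optionally
#'   `latent_pattern` (`classical|transitional|basal_like`).
#' @return A validated `ihc_cohort` (data frame subclass) with derived
#'   `<marker>_total` and `<marker>_grade` columns.
#' @export
new_cohort <- function(df) {
  required <- c("case_id",
                paste0(rep(ihc_markers(), each = 2), "_",
                       c("intensity", "proportion")),
                "histology", "stage", "sex", "age", "time_days", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    ihcsub_error(paste("missing columns:", paste(missing_cols, collapse = ", ")),
                 "schema_error")
  df$case_id <- as.character(df$case_id)
  if (anyNA(df$case_id) || any(df$case_id == ""))
    ihcsub_error("case_id must be non-missing and non-empty", "schema_error")
  if (anyDuplicated(df$case_id))
    ihcsub_error(sprintf("duplicate case_id: %s",
                         df$case_id[duplicated(df$case_id)][1]),
                 "duplicate_id_error")
  for (m in ihc_markers()) {
    it <- df[[paste0(m, "_intensity")]]
    pr <- df[[paste0(m, "_proportion")]]
    tot <- tryCatch(allred_total(as_int(it, paste0(m, "_intensity")),
                                 as_int(pr, paste0(m, "_proportion"))),
                    ihcsub_error = function(e)
                      ihcsub_error(paste0("marker ", m, ": ", conditionMessage(e)),
                                   sub("^ihcsub_", "", class(e)[1])))
    df[[paste0(m, "_intensity")]] <- as.integer(it)
    df[[paste0(m, "_proportion")]] <- as.integer(pr)
    df[[paste0(m, "_total")]] <- tot
    df[[paste0(m, "_grade")]] <- grade_of_total(tot)
  }
  df$histology <- parse_enum(df$histology, histology_levels(), "histology")
  df$stage <- parse_enum(df$stage, stage_levels(), "stage", na_ok = TRUE)
  df$sex <- parse_enum(df$sex, c("M", "F"), "sex")
  df$age <- as_int(df$age, "age")
  if (any(df$age < 0)) ihcsub_error("age must be >= 0", "range_error")
  df$time_days <- as.numeric(df$time_days)
  if (anyNA(df$time_days) || any(df$time_days < 0))
    ihcsub_error("time_days must be non-missing and >= 0", "range_error")
  if (!all(df$event %in% c(0, 1, TRUE, FALSE)))
    ihcsub_error("event must be 0/1", "enum_error")
  df$event <- as.integer(df$event)
  if (!is.null(df$latent_pattern) && !all(is.na(df$latent_pattern)))
    df$latent_pattern <- parse_enum(df$latent_pattern, ihc_patterns(),
                                    "latent_pattern", na_ok = TRUE)
  ord <- c("case_id",
           as.vector(t(outer(ihc_markers(),
                             c("intensity", "proportion", "total", "grade"),
                             paste, sep = "_"))),
           "histology", "stage", "sex", "age", "time_days", "event",
           intersect("latent_pattern", names(df)))
  df <- df[, ord]
  rownames(df) <- NULL
  class(df) <- c("ihc_cohort", "data.frame")
  df
}

as_int <- function(x, what) {
  xi <- suppressWarnings(as.integer(x))
  if (anyNA(xi) || any(xi != as.numeric(x)))
    ihcsub_error(sprintf("%s must be integer-valued and non-missing", what),
                 "range_error")
  xi
}

parse_enum <- function(x, levels, what, na_ok = FALSE) {
  x <- as.character(x)
  x[x %in% c("NA", "")] <- NA_character_
  if (!na_ok && anyNA(x))
    ihcsub_error(sprintf("%s has missing values", what), "enum_error")
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    ihcsub_error(sprintf("unknown %s token at row %d: '%s' (allowed: %s)",
                         what, which(bad)[1], x[which(bad)[1]],
                         paste(levels, collapse = ", ")),
                 "enum_error")
  factor(x, levels = levels)
}

#' @rdname new_cohort
#' @param x Object to coerce/validate.
#' @export
as_cohort <- function(x) {
  if (inherits(x, "ihc_cohort")) x else new_cohort(as.data.frame(x))
}

#' @export
print.ihc_cohort <- function(x, ...) {
  cat(sprintf("<ihc_cohort> %d cases\n", nrow(x)))
  if ("latent_pattern" %in% names(x) && !all(is.na(x$latent_pattern))) {
    tb <- table(x$latent_pattern)
    cat("  latent patterns:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Reads the documented cohort CSV schema (comma-separated, header row,
#' UTF-8): `case_id`, eight `<marker>_intensity` / `<marker>_proportion`
#' integer columns, `histology`, `stage` (token `NA` for unknown), `sex`,
#' `age`, `time_days`, `event`, and optionally `latent_pattern`.  Grade
#' columns in the file, if present, are ignored on input and re-derived
#' from intensity + proportion.  With `grades_only = TRUE` the file may
#' instead carry pre-collapsed `<marker>_grade` columns (`0/1+/2+/3+`
#' tokens or integers 0-3); representative intensity/proportion pairs are
#' back-filled so downstream code sees a full cohort.
#'
#' @param path Path to a CSV file.
#' @param grades_only Accept grade-only input (default `FALSE`).
#' @return An `ihc_cohort`.
#' @export
read_cohort <- function(path, grades_only = FALSE) {
  if (!file.exists(path))
    ihcsub_error(paste("file not found:", path), "missing_file_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(case_id = "character"))
  if (grades_only) {
    for (m in ihc_markers()) {
      gcol <- paste0(m, "_grade")
      if (is.null(df[[gcol]]))
        ihcsub_error(paste("grades_only input lacks column", gcol),
                     "schema_error")
      g <- df[[gcol]]
      g <- if (is.character(g)) parse_grade(g) else check_int_range(g, 0L, 3L, gcol)
      # representative (intensity, proportion) with the correct grade
      df[[paste0(m, "_intensity")]] <- c(0L, 1L, 3L, 3L)[g + 1L]
      df[[paste0(m, "_proportion")]] <- c(0L, 2L, 3L, 5L)[g + 1L]
      df[[gcol]] <- NULL
    }
  } else {
    df <- df[, setdiff(names(df), paste0(ihc_markers(), "_grade"))]
  }
  df <- df[, setdiff(names(df), paste0(ihc_markers(), "_total"))]
  new_cohort(df)
}

#' Write a cohort to CSV
#'
#' Writes the cohort CSV schema with the derived grade columns included,
#' rendered as `0/1+/2+/3+` tokens; `read_cohort()` of the result
#' reproduces the cohort field-for-field.  Unknown stage is written as the
#' token `NA`.
#'
#' @param cohort An `ihc_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  out <- as.data.frame(cohort)
  out <- out[, setdiff(names(out), paste0(ihc_markers(), "_total"))]
  for (m in ihc_markers())
    out[[paste0(m, "_grade")]] <- render_grade(cohort[[paste0(m, "_grade")]])
  out$stage <- ifelse(is.na(out$stage), "NA", as.character(out$stage))
  ok <- tryCatch({ write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ihcsub_error(paste("cannot write:", path), "write_error")
  invisible(path)
}

#' Cross-tabulate two cohort factors
#'
#' Builds the r x c contingency table of two categorical case attributes,
#' in the style of the clinicopathologic characteristics table: `stage`,
#' `sex`, `histology`, `age_group` (dichotomized at 70 years),
#' `latent_pattern`, `pattern` (a cluster/pattern assignment previously
#' attached with [set_pattern()]), or any factor column of the cohort.
#'
#' @param cohort An `ihc_cohort`.
#' @param row_factor,col_factor Factor names.
#' @param drop_unknown Drop cases with missing values (e.g. unknown stage)
#'   in either factor (default `TRUE`); with `FALSE`, missing values form
#'   an explicit `"unknown"` level.
#' @return A `contingency_table`.
#' @export
build_table <- function(cohort, row_factor, col_factor, drop_unknown = TRUE) {
  cohort <- as_cohort(cohort)
  r <- cohort_factor(cohort, row_factor)
  co <- cohort_factor(cohort, col_factor)
  if (drop_unknown) {
    keep <- !is.na(r) & !is.na(co)
    r <- droplevels(r[keep]); co <- droplevels(co[keep])
  } else {
    levels_with_na <- function(f) {
      f <- addNA(f, ifany = TRUE)
      levels(f)[is.na(levels(f))] <- "unknown"
      droplevels(f)
    }
    r <- levels_with_na(r); co <- levels_with_na(co)
  }
  r <- droplevels(r); co <- droplevels(co)
  if (nlevels(r) < 2 || nlevels(co) < 2)
    ihcsub_error(sprintf("degenerate table: factor '%s' has a single observed level",
                         if (nlevels(r) < 2) row_factor else col_factor),
                 "degenerate_table_error")
  contingency_table(unclass(table(r, co)))
}

cohort_factor <- function(cohort, name) {
  if (name == "age_group")
    return(factor(ifelse(cohort$age >= 70, ">=70", "<70"),
                  levels = c("<70", ">=70")))
  if (name == "pattern" && is.null(cohort[["pattern"]])) name <- "latent_pattern"
  if (name %in% paste0(ihc_markers(), "_pos")) {
    m <- sub("_pos$", "", name)
    return(factor(ifelse(cohort[[paste0(m, "_grade")]] >= 1, "positive", "negative"),
                  levels = c("negative", "positive")))
  }
  x <- cohort[[name]]
  if (is.null(x))
    ihcsub_error(paste("unknown cohort factor:", name), "schema_error")
  if (!is.factor(x)) x <- factor(x)
  x
}

#' Attach a pattern assignment to a cohort
#'
#' @param cohort An `ihc_cohort`.
#' @param assignment A `pattern_assignment` from [label_patterns()], or a
#'   character/factor vector of pattern labels in cohort case order.
#' @return The cohort with a `pattern` column.
#' @export
set_pattern <- function(cohort, assignment) {
  cohort <- as_cohort(cohort)
  p <- if (inherits(assignment, "pattern_assignment")) {
    idx <- match(cohort$case_id, assignment$case_id)
    if (anyNA(idx))
      ihcsub_error("assignment does not cover every case", "schema_error")
    assignment$pattern[idx]
  } else factor(as.character(assignment), levels = ihc_patterns())
  if (length(p) != nrow(cohort))
    ihcsub_error("pattern assignment length mismatch", "schema_error")
  cohort$pattern <- p
  cohort
}

#' Contingency table of non-negative integer counts
#'
#' @param counts An r x c matrix of non-negative integers (r, c >= 2),
#'   optionally with dimnames.
#' @param row_labels,col_labels Optional label vectors overriding the
#'   dimnames.
#' @return A `contingency_table` object (a labelled integer matrix with
#'   total `n` attribute).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    ihcsub_error("contingency table must be at least 2 x 2",
                 "degenerate_table_error")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    ihcsub_error("counts must be non-negative integers", "range_error")
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  if (is.null(rownames(counts))) rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  structure(counts, n = sum(counts), class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d x %d, n = %d\n", nrow(x), ncol(x),
              attr(x, "n")))
  print(matrix(as.integer(x), nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Packaged in-study fixture tables
#'
#' Returns the printed contingency tables of the reference 190-case
#' cohort (pattern columns classical/transitional/basal-like crossed with
#' stage, sex, age group or histology; stage rows cover the 182 staged
#' cases) and the cohort-wide marker grade distribution, shipped as CSV
#' under `inst/extdata`.
#'
#' @param name One of `"table2_stage"`, `"table2_sex"`, `"table2_age"`,
#'   `"table2_histology"`, `"table1_marginals"`.
#' @return A `contingency_table`, or for `"table1_marginals"` a 4 x 4
#'   integer matrix (markers x grades).
#' @export
ihcsub_fixture <- function(name = c("table2_stage", "table2_sex", "table2_age",
                                    "table2_histology", "table1_marginals")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "ihcsub",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (name == "table1_marginals") return(m)
  contingency_table(m)
}
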