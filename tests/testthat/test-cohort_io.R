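write_tmp_cohort <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("read_cohort round-trips a well-formed file", {
  path <- write_tmp_cohort(cohort_df(2))
  co <- read_cohort(path)
  expect_s3_class(co, "ihc_cohort")
  expect_identical(nrow(co), 2L)
  expect_identical(co$ck56_total, c(8L, 0L))
  expect_identical(co$ck56_grade, c(3L, 0L))
})

test_that("malformed rows raise distinct named errors, not silent drops", {
  bad <- cohort_df(2); bad$ck56_intensity[1] <- 4L
  expect_error(read_cohort(write_tmp_cohort(bad)),
               "ck56.*intensity", class = "ihcsub_range_error")
  dup <- cohort_df(2); dup$case_id <- c("a", "a")
  expect_error(read_cohort(write_tmp_cohort(dup)),
               class = "ihcsub_duplicate_id_error")
  en <- cohort_df(2); en$histology[2] <- "tubular"
  expect_error(read_cohort(write_tmp_cohort(en)),
               "row 2", class = "ihcsub_enum_error")
  zp <- cohort_df(2); zp$p63_intensity[1] <- 0L
  expect_error(read_cohort(write_tmp_cohort(zp)),
               class = "ihcsub_zero_pair_error")
  expect_error(read_cohort(tempfile()), class = "ihcsub_missing_file_error")
  sc <- cohort_df(2); sc$sex <- NULL
  expect_error(read_cohort(write_tmp_cohort(sc)), class = "ihcsub_schema_error")
})

test_that("write_cohort renders grade tokens and inverts read_cohort", {
  co <- generate_cohort(cohort_sim_config(n = 40, quotas = NULL), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  txt <- readLines(path)
  expect_match(txt[1], "ck56_grade")
  expect_true(any(grepl("3\\+", txt[-1])))
  rt <- read_cohort(path)
  expect_equal(as.data.frame(rt), as.data.frame(co), ignore_attr = TRUE)
})

test_that("round-trip is the identity on randomized cohorts", {
  for (s in 1:5) {
    co <- generate_cohort(cohort_sim_config(n = 25, quotas = NULL), seed = s)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, path)
    expect_equal(as.data.frame(read_cohort(path)), as.data.frame(co),
                 ignore_attr = TRUE)
  }
})

test_that("grades_only ingestion accepts pre-collapsed grades", {
  df <- data.frame(case_id = c("a", "b"),
                   ck56_grade = c("3+", "0"), p63_grade = c("2+", "0"),
                   gata6_grade = c("0", "3+"), hnf4a_grade = c("1+", "3+"),
                   histology = c("sq_diff", "glandular"),
                   stage = c("IV", "NA"), sex = c("M", "F"),
                   age = c(70L, 60L), time_days = c(10, 20), event = c(1L, 0L))
  co <- read_cohort(write_tmp_cohort(df), grades_only = TRUE)
  expect_identical(co$ck56_grade, c(3L, 0L))
  expect_identical(co$hnf4a_grade, c(1L, 3L))
  expect_true(is.na(co$stage[2]))
})

test_that("shipped fixture matches fixture_cohort_190() and its quotas", {
  co <- read_cohort(system.file("extdata", "synthetic_cohort_190.csv",
                                package = "ihcsub"))
  expect_identical(as.vector(table(co$latent_pattern)), c(85L, 85L, 20L))
  expect_equal(as.data.frame(fixture_cohort_190()), as.data.frame(co),
               ignore_attr = TRUE)
})

test_that("build_table reproduces the printed cross-tabulations exactly", {
  co <- fixture_cohort_190()
  hist_tab <- build_table(co, "histology", "latent_pattern")
  expect_identical(matrix(as.integer(hist_tab), 3),
                   matrix(c(61L, 24L, 0L, 73L, 12L, 0L, 0L, 4L, 16L), 3))
  expect_identical(unname(rowSums(hist_tab)), c(134, 40, 16))
  expect_identical(unname(colSums(hist_tab)), c(85, 85, 20))
  sex_tab <- build_table(co, "sex", "latent_pattern")
  expect_identical(matrix(as.integer(sex_tab), 2),
                   matrix(c(44L, 41L, 45L, 40L, 7L, 13L), 2))
  age_tab <- build_table(co, "age_group", "latent_pattern")
  expect_identical(matrix(as.integer(age_tab), 2),
                   matrix(c(38L, 47L, 42L, 43L, 6L, 14L), 2))
  stage_tab <- build_table(co, "stage", "latent_pattern", drop_unknown = TRUE)
  expect_identical(attr(stage_tab, "n"), 182L)
  expect_identical(matrix(as.integer(stage_tab), 4),
                   matrix(as.integer(ihcsub_fixture("table2_stage")), 4))
  with_unknown <- build_table(co, "stage", "latent_pattern", drop_unknown = FALSE)
  expect_identical(attr(with_unknown, "n"), 190L)
  expect_true("unknown" %in% rownames(with_unknown))
})

test_that("build_table marginals equal independent tallies", {
  co <- generate_cohort(seed = 3)
  tab <- build_table(co, "histology", "latent_pattern")
  expect_equal(unname(rowSums(tab)),
               unname(as.vector(table(co$histology))))
  expect_equal(unname(colSums(tab)),
               unname(as.vector(table(co$latent_pattern))))
})

test_that("degenerate factors are rejected", {
  expect_error(build_table(new_cohort(cohort_df(1)), "sex", "histology"),
               class = "ihcsub_degenerate_table_error")
  same_sex <- cohort_df(4); same_sex$sex <- "M"
  expect_error(build_table(new_cohort(same_sex), "sex", "histology"),
               class = "ihcsub_degenerate_table_error")
})

test_that("fixture tables ship with the printed totals", {
  expect_identical(attr(ihcsub_fixture("table2_stage"), "n"), 182L)
  expect_identical(attr(ihcsub_fixture("table2_sex"), "n"), 190L)
  expect_identical(attr(ihcsub_fixture("table2_age"), "n"), 190L)
  expect_identical(attr(ihcsub_fixture("table2_histology"), "n"), 190L)
  expect_identical(unname(colSums(ihcsub_fixture("table2_histology"))),
                   c(85, 85, 20))
})
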