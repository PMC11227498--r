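test_that("km_estimate matches hand product-limit computations", {
  # all censored -> constant 1
  km0 <- km_estimate(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "ihcsub_range_error")
})

test_that("km curves satisfy bounds, monotonicity, duplication invariance", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    t <- round(rexp(n, 0.1), 2)
    e <- rbinom(n, 1, 0.6)
    km <- km_estimate(t, e)
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(diff(km$n_risk) < 0))
    km2 <- km_estimate(rep(t, 2), rep(e, 2))
    expect_equal(km2$survival, km$survival)
  }
})

test_that("logrank is zero for identical groups and matches the oracle", {
  g <- list(c(1, 2, 3, 5, 8), c(1, 0, 1, 1, 0))
  r <- logrank_test(list(g, g))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  skip_if_not_installed("survival")
  set.seed(43)
  for (rep in 1:15) {
    n <- sample(20:60, 1)
    t <- round(rexp(n, 0.05)) + 1
    e <- rbinom(n, 1, 0.7)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2) next
    mine <- logrank_test(list(list(t[grp == 0], e[grp == 0]),
                              list(t[grp == 1], e[grp == 1])))
    oracle <- survival::survdiff(survival::Surv(t, e) ~ grp)
    expect_equal(mine$chi2, unname(oracle$chisq), tolerance = 1e-8)
  }
})

test_that("logrank p is invariant to group relabeling and chi2 >= 0", {
  set.seed(47)
  gs <- lapply(1:3, function(i) {
    n <- 25
    list(round(rexp(n, 0.02 * i)) + 1, rbinom(n, 1, 0.6))
  })
  r <- logrank_test(gs)
  expect_gte(r$chi2, 0)
  expect_equal(logrank_test(rev(gs))$chi2, r$chi2, tolerance = 1e-10)
  expect_identical(r$df, 2)
})

test_that("gehan-wilcoxon weights emphasize early differences", {
  expect_equal(gehan_wilcoxon_test(list(list(c(1, 2, 3), c(1, 1, 0)),
                                        list(c(1, 2, 3), c(1, 1, 0))))$p_value, 1)
  # early separation, late crossing: heavy early weights help Wilcoxon
  early_a <- list(c(1, 1, 2, 2, 3, 50, 60, 70), c(1, 1, 1, 1, 1, 0, 0, 0))
  early_b <- list(c(10, 12, 14, 16, 18, 20, 22, 24), c(1, 1, 1, 1, 1, 1, 1, 1))
  lw <- gehan_wilcoxon_test(list(early_a, early_b))
  lr <- logrank_test(list(early_a, early_b))
  expect_lt(lw$p_value, lr$p_value)
  # with a single distinct event time all weights coincide
  one_a <- list(c(5, 5, 9), c(1, 1, 0))
  one_b <- list(c(5, 5, 7), c(1, 0, 0))
  expect_equal(gehan_wilcoxon_test(list(one_a, one_b))$chi2,
               logrank_test(list(one_a, one_b))$chi2, tolerance = 1e-12)
})

test_that("cox_fit agrees with the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(53)
  n <- 250
  x <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  t <- round(rexp(n, 0.01 * exp(0.6 * x[, 1] - 0.4 * x[, 2]))) + 1  # ties
  e <- rbinom(n, 1, 0.75)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(x, t, e, ties)
    oracle <- survival::coxph(survival::Surv(t, e) ~ x, ties = ties)
    expect_equal(mine$coefficients$coef, unname(coef(oracle)), tolerance = 1e-6)
    expect_equal(mine$coefficients$se, unname(sqrt(diag(vcov(oracle)))),
                 tolerance = 1e-6)
    expect_equal(mine$loglik, oracle$loglik[2], tolerance = 1e-6)
  }
})

test_that("efron and breslow agree when all event times are distinct", {
  set.seed(59)
  n <- 80
  x <- matrix(rnorm(n), dimnames = list(NULL, "x"))
  t <- rexp(n, 0.05 * exp(0.5 * x[, 1]))  # continuous: no ties
  e <- rep(1L, n)
  f1 <- cox_fit(x, t, e, "efron")
  f2 <- cox_fit(x, t, e, "breslow")
  expect_equal(f1$coefficients$coef, f2$coefficients$coef, tolerance = 1e-6)
})

test_that("cox_fit flags degenerate inputs instead of fabricating estimates", {
  n <- 40
  x <- matrix(rep(1, n), dimnames = list(NULL, "const"))
  expect_error(cox_fit(x, rexp(n, 0.1), rep(1L, n)),
               class = "ihcsub_constant_covariate_error")
  # perfect separation: all events in one arm, ordered times
  xs <- matrix(rep(c(0, 1), each = 20), dimnames = list(NULL, "sep"))
  ts <- c(seq(1, 20), seq(100, 119))
  expect_warning(f <- cox_fit(xs, ts, rep(1L, 40)), "monotone|separation")
  expect_true(f$divergent)
  expect_false(f$converged)
})

test_that("hazard ratios and confidence bounds are exp-transformed coefficients", {
  set.seed(61)
  n <- 150
  x <- matrix(rbinom(n, 1, 0.5), dimnames = list(NULL, "g"))
  t <- rexp(n, 0.02 * exp(0.7 * x[, 1]))
  f <- cox_fit(x, t, rep(1L, n))
  co <- f$coefficients
  expect_equal(co$hr, exp(co$coef))
  expect_equal(co$ci_lower, exp(co$coef - 1.96 * co$se))
  expect_equal(co$ci_upper, exp(co$coef + 1.96 * co$se))
})

test_that("run_survival_analysis assembles the full report on a cohort", {
  co <- generate_cohort(seed = 6)
  res <- run_survival_analysis(co)
  expect_named(res$km, ihc_patterns())
  expect_lt(res$logrank$p_value, 0.05)
  multi <- res$cox_multivariate$coefficients
  expect_true("expression_type" %in% multi$term)
  # generator injects hazard ratios > 1 for non-classical patterns
  expect_gt(multi$hr[multi$term == "expression_type"], 1)
  # unknown stage cases are excluded from the multivariate model
  expect_equal(res$cox_multivariate$n, sum(!is.na(co$stage)))
  # CK5/6 positivity sub-analysis restricted to glandular histology
  res2 <- run_survival_analysis(co, grouping = "ck56_pos",
                                subset_histology = "glandular")
  expect_named(res2$km, c("negative", "positive"))
  expect_identical(
    res2$cox_multivariate$n + sum(is.na(co$stage[co$histology == "glandular"])),
    as.integer(sum(co$histology == "glandular")))
})

test_that("grouping by a random coin yields null log-rank p-values", {
  set.seed(67)
  ps <- replicate(60, {
    co <- generate_cohort(cohort_sim_config(n = 120, quotas = NULL),
                          seed = sample.int(1e6, 1))
    coin <- rbinom(nrow(co), 1, 0.5)
    if (length(unique(coin)) < 2) return(NA_real_)
    logrank_test(list(list(co$time_days[coin == 0], co$event[coin == 0]),
                      list(co$time_days[coin == 1], co$event[coin == 1])))$p_value
  })
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
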