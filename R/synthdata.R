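#' Synthetic cohort configuration
#'
#' Defaults emulate the 190-case reference cohort: three latent patterns
#' with quotas 85/85/20 (classical/transitional/basal-like), per-pattern
#' marker grade distributions with the classical profile concentrated at
#' GATA6/HNF4a grade 3 and CK5/6/p63 grade 0-1 and the basal-like profile
#' at the opposite ends, histology conditional on pattern matching the
#' printed cross-tabulation (basal-like: 16/20 squamous differentiation,
#' 4/20 poorly differentiated, no glandular), stage/sex/age marginals and
#' an 8/190 missing-stage rate matching the printed marginals, and
#' exponential survival with pattern hazard ratios 1 / 1.9 / 3.5
#' (classical-referenced, matching the printed univariate hazard ratio
#' for expression type and the ordering of the survival curves) under
#' ~40% independent censoring.
#'
#' @param n Cohort size (default 190).
#' @param quotas Exact per-pattern counts (default 85/85/20); set to NULL
#'   to sample pattern membership multinomially from `pattern_probs`.
#' @param pattern_probs Pattern probabilities for multinomial mode.
#' @param grade_probs Named list (pattern -> marker -> length-4
#'   probability vector over grades 0-3).
#' @param histology_probs Named list (pattern -> length-3 probability
#'   vector over glandular/por_comp/sq_diff).
#' @param stage_probs Length-4 probability vector over stages I-IV among
#'   staged cases (independent of pattern).
#' @param stage_missing_rate Probability that stage is unknown.
#' @param sex_prob_male,age_lt70_prob Marginal probabilities (independent
#'   of pattern).
#' @param baseline_hazard Exponential event rate per day for the
#'   classical pattern.
#' @param hazard_ratios Per-pattern hazard ratios (classical,
#'   transitional, basal-like).
#' @param censoring_rate Target fraction of censored cases.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n = 190,
                              quotas = c(classical = 85, transitional = 85,
                                         basal_like = 20),
                              pattern_probs = c(85, 85, 20) / 190,
                              grade_probs = default_grade_probs(),
                              histology_probs = default_histology_probs(),
                              stage_probs = c(15, 23, 37, 107) / 182,
                              stage_missing_rate = 8 / 190,
                              sex_prob_male = 96 / 190,
                              age_lt70_prob = 86 / 190,
                              baseline_hazard = log(2) / 365,
                              hazard_ratios = c(classical = 1,
                                                transitional = 1.9,
                                                basal_like = 3.5),
                              censoring_rate = 0.4) {
  cfg <- list(n = n, quotas = quotas, pattern_probs = pattern_probs,
              grade_probs = grade_probs, histology_probs = histology_probs,
              stage_probs = stage_probs,
              stage_missing_rate = stage_missing_rate,
              sex_prob_male = sex_prob_male, age_lt70_prob = age_lt70_prob,
              baseline_hazard = baseline_hazard,
              hazard_ratios = hazard_ratios,
              censoring_rate = censoring_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "cohort_sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(p, what, len) {
    if (length(p) != len || anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      ihcsub_error(sprintf("%s must be a length-%d probability vector summing to 1",
                           what, len), "config_error")
  }
  if (!is.null(cfg$quotas)) {
    if (length(cfg$quotas) != 3 || any(cfg$quotas < 0) || sum(cfg$quotas) != cfg$n)
      ihcsub_error("quotas must be 3 non-negative counts summing to n",
                   "config_error")
  } else chk_prob(cfg$pattern_probs, "pattern_probs", 3)
  for (p in ihc_patterns()) {
    for (m in ihc_markers())
      chk_prob(cfg$grade_probs[[p]][[m]], paste("grade_probs", p, m), 4)
    chk_prob(cfg$histology_probs[[p]], paste("histology_probs", p), 3)
  }
  chk_prob(cfg$stage_probs, "stage_probs", 4)
  if (any(cfg$hazard_ratios <= 0))
    ihcsub_error("hazard ratios must be > 0", "config_error")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    ihcsub_error("censoring_rate must be in [0, 1)", "config_error")
  invisible(cfg)
}

# Default per-pattern grade distributions.  Chosen once: the classical and
# basal-like profiles follow the verbal marker profile of the patterns,
# the transitional profile sits between them, the cohort-wide CK5/6
# grade-0 mass lands near the printed 77%, and the CK5/6 2+/3+ mass is
# confined to the basal-like pattern so the patterns are well separated
# (the reference clustering showed clearly separated clusters, which
# independent per-marker sampling can only emulate through separated
# marginals).
default_grade_probs <- function() {
  list(
    classical = list(
      ck56  = c(0.95, 0.05, 0.00, 0.00),
      p63   = c(0.95, 0.05, 0.00, 0.00),
      gata6 = c(0.00, 0.00, 0.05, 0.95),
      hnf4a = c(0.00, 0.00, 0.10, 0.90)),
    transitional = list(
      ck56  = c(0.70, 0.30, 0.00, 0.00),
      p63   = c(0.05, 0.55, 0.40, 0.00),
      gata6 = c(0.10, 0.55, 0.35, 0.00),
      hnf4a = c(0.65, 0.30, 0.05, 0.00)),
    basal_like = list(
      ck56  = c(0.00, 0.02, 0.23, 0.75),
      p63   = c(0.00, 0.15, 0.40, 0.45),
      gata6 = c(0.20, 0.55, 0.25, 0.00),
      hnf4a = c(0.65, 0.30, 0.05, 0.00)))
}

# Histology given pattern, from the printed pattern x histology
# cross-tabulation (columns classical 61/24/0, transitional 73/12/0,
# basal-like 0/4/16 over glandular / por_comp / sq_diff).
default_histology_probs <- function() {
  list(classical = c(61, 24, 0) / 85,
       transitional = c(73, 12, 0) / 85,
       basal_like = c(0, 4, 16) / 20)
}

#' A null (no-effect) cohort configuration
#'
#' All three patterns share the same grade and histology distributions
#' and the same hazard; clustering recovery and survival tests on such a
#' cohort should find nothing.
#' @param n Cohort size.
#' @return A `cohort_sim_config`.
#' @export
null_cohort_config <- function(n = 190) {
  flat <- list(ck56 = c(146, 21, 9, 14) / 190,
               p63 = c(125, 43, 14, 8) / 190,
               gata6 = c(2, 13, 60, 115) / 190,
               hnf4a = c(28, 31, 65, 66) / 190)
  hist_flat <- c(134, 40, 16) / 190
  cohort_sim_config(
    n = n,
    grade_probs = list(classical = flat, transitional = flat,
                       basal_like = flat),
    histology_probs = list(classical = hist_flat, transitional = hist_flat,
                           basal_like = hist_flat),
    quotas = NULL,
    hazard_ratios = c(classical = 1, transitional = 1, basal_like = 1))
}

#' Generate a synthetic cohort
#'
#' Samples a cohort from a [cohort_sim_config()]: latent pattern (exact
#' quotas by default), marker grades given pattern (each grade realized
#' as a consistent intensity/proportion pair), histology given pattern,
#' stage/sex/age from the configured marginals independent of pattern,
#' and day-resolution survival times from an exponential model with
#' pattern-specific hazards under independent exponential censoring
#' calibrated to the target censoring rate.  Deterministic given the
#' seed.
#'
#' @param config A `cohort_sim_config`.
#' @param seed Integer seed (default 1).
#' @return An `ihc_cohort` with a `latent_pattern` column.
#' @export
generate_cohort <- function(config = cohort_sim_config(), seed = 1) {
  validate_sim_config(config)
  with_seed(seed, {
    n <- config$n
    pat <- if (!is.null(config$quotas)) {
      sample(rep(ihc_patterns(), times = config$quotas))
    } else {
      sample(ihc_patterns(), n, replace = TRUE, prob = config$pattern_probs)
    }
    df <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
    for (m in ihc_markers()) {
      grade <- integer(n)
      for (p in ihc_patterns()) {
        idx <- which(pat == p)
        grade[idx] <- sample(0:3, length(idx), replace = TRUE,
                             prob = config$grade_probs[[p]][[m]])
      }
      ip <- realize_allred(grade)
      df[[paste0(m, "_intensity")]] <- ip$intensity
      df[[paste0(m, "_proportion")]] <- ip$proportion
    }
    hist <- character(n)
    for (p in ihc_patterns()) {
      idx <- which(pat == p)
      hist[idx] <- sample(histology_levels(), length(idx), replace = TRUE,
                          prob = config$histology_probs[[p]])
    }
    df$histology <- hist
    staged <- runif(n) >= config$stage_missing_rate
    stage <- rep(NA_character_, n)
    stage[staged] <- sample(stage_levels(), sum(staged), replace = TRUE,
                            prob = config$stage_probs)
    df$stage <- stage
    df$sex <- ifelse(runif(n) < config$sex_prob_male, "M", "F")
    lt70 <- runif(n) < config$age_lt70_prob
    df$age <- ifelse(lt70, sample(40:69, n, replace = TRUE),
                     sample(70:87, n, replace = TRUE))
    hr <- config$hazard_ratios[match(pat, ihc_patterns())]
    rate <- config$baseline_hazard * hr
    T_event <- rexp(n, rate = rate)
    cr <- config$censoring_rate
    if (cr > 0) {
      mu <- cr / (1 - cr) * mean(rate)
      C <- rexp(n, rate = mu)
    } else C <- rep(Inf, n)
    df$time_days <- pmax(1, round(pmin(T_event, C)))
    df$event <- as.integer(T_event <= C)
    df$latent_pattern <- pat
    new_cohort(df)
  })
}

# Realize a grade as a consistent (intensity, proportion) pair: draw an
# Allred total uniformly from the grade's preimage ({0, 2} for grade 0,
# total 1 being unattainable), then an intensity uniformly from the valid
# range; proportion is the remainder.
realize_allred <- function(grade) {
  n <- length(grade)
  total <- integer(n)
  pools <- list(`0` = c(0L, 2L), `1` = 3:5, `2` = 6:7, `3` = 8L)
  for (g in 0:3) {
    idx <- which(grade == g)
    pool <- pools[[as.character(g)]]
    total[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  intensity <- integer(n)
  pos <- total > 0
  lo <- pmax(1L, total[pos] - 5L)
  hi <- pmin(3L, total[pos] - 1L)
  u <- floor(runif(sum(pos)) * (hi - lo + 1))
  intensity[pos] <- as.integer(lo + pmin(u, hi - lo))
  list(intensity = intensity, proportion = total - intensity)
}

#' Synthetic expression configuration
#'
#' Two-group (basal-like vs classical) negative-binomial count matrices
#' in which the five signature genes (TP63, KRT5, KRT6A up in basal-like;
#' GATA6, HNF4A down) carry configurable log2 effects and all other genes
#' carry none.
#'
#' @param n_genes Total genes including the five signature genes.
#' @param n_per_group Samples per group.
#' @param base_log2_mean,base_log2_sd Per-gene baseline log2 mean
#'   expression distribution.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param effect_up,effect_down Log2 effects in the basal-like group on
#'   the up and down signature genes.
#' @return An `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 1000, n_per_group = 50,
                            base_log2_mean = 8, base_log2_sd = 1,
                            dispersion = 0.2,
                            effect_up = 1, effect_down = -1) {
  if (n_genes < 10 || n_per_group < 2)
    ihcsub_error("need n_genes >= 10 and n_per_group >= 2", "config_error")
  if (dispersion <= 0)
    ihcsub_error("dispersion must be > 0", "config_error")
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
                 dispersion = dispersion, effect_up = effect_up,
                 effect_down = effect_down),
            class = "expr_sim_config")
}

#' Generate a synthetic two-group expression matrix
#'
#' @param config An `expr_sim_config`.
#' @param seed Integer seed (default 1).
#' @return List with `matrix` (an `expr_matrix` of counts) and `groups`
#'   (factor `classical`/`basal_like` per sample).
#' @export
generate_expression <- function(config = expr_sim_config(), seed = 1) {
  with_seed(seed, {
    sig <- custom5_signature()
    sig_genes <- c(sig$up, sig$down)
    n_other <- config$n_genes - length(sig_genes)
    genes <- c(sig_genes, sprintf("GENE%04d", seq_len(n_other)))
    n <- 2 * config$n_per_group
    groups <- factor(rep(c("classical", "basal_like"),
                         each = config$n_per_group),
                     levels = c("classical", "basal_like"))
    base <- rnorm(config$n_genes, config$base_log2_mean, config$base_log2_sd)
    effect <- numeric(config$n_genes)
    effect[seq_along(sig$up)] <- config$effect_up
    effect[length(sig$up) + seq_along(sig$down)] <- config$effect_down
    log2mu <- matrix(base, config$n_genes, n) +
      outer(effect, as.numeric(groups == "basal_like"))
    mu <- 2^log2mu
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                     nrow = config$n_genes,
                     dimnames = list(genes, sprintf("sample_%03d", seq_len(n))))
    list(matrix = expression_matrix(counts, "counts"), groups = groups)
  })
}
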