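#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up durations.
#' @param events Logical/0-1 event indicators (TRUE = death observed).
#' @return A `surv_curve` data frame with one row per distinct observed
#'   time: `time`, `n_risk` (at risk just before the time), `n_event`,
#'   `n_censor`, and `survival` (the product-limit estimate just after
#'   the time).  Survival starts at 1, is non-increasing, and a fully
#'   censored sample yields the constant curve 1.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))  # S(1) = 2/3, S(3) = 0
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  events <- as.integer(as.logical(events))
  ut <- sort(unique(times))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1L), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0L), numeric(1))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  class(out) <- c("surv_curve", "data.frame")
  out
}

check_surv <- function(times, events) {
  if (length(times) == 0 || length(times) != length(events))
    ihcsub_error("times and events must be non-empty and equal-length",
                 "range_error")
  if (anyNA(times) || any(times < 0))
    ihcsub_error("times must be non-missing and >= 0", "range_error")
  if (anyNA(events) || !all(events %in% c(0, 1, TRUE, FALSE)))
    ihcsub_error("events must be 0/1", "range_error")
  invisible(NULL)
}

# Shared machinery of the k-sample weighted log-rank family.  weight_fn
# maps the total at-risk count at an event time to the weight: constant 1
# gives the log-rank test, the at-risk count itself gives Gehan-Wilcoxon.
weighted_logrank <- function(groups, weight_fn) {
  k <- length(groups)
  if (k < 2) ihcsub_error("need at least 2 groups", "range_error")
  for (g in groups) check_surv(g[[1]], g[[2]])
  times <- unlist(lapply(groups, `[[`, 1))
  events <- as.integer(as.logical(unlist(lapply(groups, `[[`, 2))))
  grp <- rep(seq_len(k), vapply(groups, function(g) length(g[[1]]), numeric(1)))
  ev_times <- sort(unique(times[events == 1L]))
  U <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at <- times >= t
    n <- sum(at)
    d <- sum(events[times == t])
    ng <- vapply(seq_len(k), function(g) sum(at & grp == g), numeric(1))
    dg <- vapply(seq_len(k), function(g) sum(events[times == t & grp == g]),
                 numeric(1))
    w <- weight_fn(n)
    U <- U + w * (dg - d * ng / n)
    if (n > 1) {
      fac <- w^2 * d * (n - d) / (n - 1)
      p <- ng / n
      V <- V + fac * (diag(p, k) - tcrossprod(p))
    }
  }
  idx <- seq_len(k - 1)
  Vi <- V[idx, idx, drop = FALSE]
  chi2 <- if (all(abs(U) < 1e-12)) 0 else
    drop(t(U[idx]) %*% pseudo_solve(Vi) %*% U[idx])
  chi2 <- max(0, chi2)
  list(chi2 = chi2, df = k - 1,
       p_value = pchisq(chi2, k - 1, lower.tail = FALSE),
       observed = vapply(seq_len(k), function(g) sum(events[grp == g]),
                         numeric(1)))
}

pseudo_solve <- function(m) {
  s <- svd(m)
  pos <- s$d > max(s$d) * 1e-10
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' k-sample log-rank test
#'
#' Standard (unweighted) log-rank test comparing the survival experience
#' of k groups, with the hypergeometric variance at each event time and a
#' chi-square reference distribution on k - 1 degrees of freedom.
#'
#' @param groups List of k groups, each a list/pair `(times, events)`.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
logrank_test <- function(groups) weighted_logrank(groups, function(n) 1)

#' Gehan-Wilcoxon (Gehan-Breslow) test
#'
#' At-risk-weighted variant of the log-rank test (weight = number at risk
#' at each event time), emphasizing early differences between curves.
#'
#' @inheritParams logrank_test
#' @return List with `chi2`, `df`, `p_value`.
#' @export
gehan_wilcoxon_test <- function(groups) weighted_logrank(groups, identity)

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with Efron
#' (default) or Breslow handling of tied event times.  Convergence is
#' declared when the gradient max-norm drops below 1e-8, or when no
#' likelihood improvement beyond double precision remains while the
#' gradient max-norm is already below 1e-6 (with large log-likelihoods the
#' absolute 1e-8 target can sit below the attainable float resolution);
#' the iteration cap is 50.  A monotone partial likelihood (perfect
#' separation) is
#' reported through `converged = FALSE` / `divergent = TRUE` rather than
#' as a silently huge coefficient.
#'
#' @param covariates Numeric design matrix (n x p), no intercept; no
#'   column may be constant.
#' @param times,events Follow-up durations and event indicators.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit`: data frame `coefficients` with `coef`, `se`,
#'   `hr`, `ci_lower`, `ci_upper` (95%, normal theory), `z`, `p_value`;
#'   plus `loglik`, `iterations`, `converged`, `divergent`, `ties`, `n`,
#'   `n_events`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  check_surv(times, events)
  if (nrow(X) != length(times))
    ihcsub_error("covariates and times differ in length", "range_error")
  if (nrow(X) <= ncol(X))
    ihcsub_error("need more subjects than covariates", "range_error")
  csd <- apply(X, 2, sd)
  if (any(csd == 0))
    ihcsub_error(sprintf("constant covariate: column %d", which(csd == 0)[1]),
                 "constant_covariate_error")
  events <- as.integer(as.logical(events))
  p <- ncol(X)
  beta <- rep(0, p)
  ll_old <- cox_loglik(beta, X, times, events, ties)$loglik
  converged <- FALSE; divergent <- FALSE; iter <- 0
  for (iter in seq_len(50)) {
    lk <- cox_loglik(beta, X, times, events, ties)
    if (!is.finite(lk$loglik) || max(abs(beta)) > 15) { divergent <- TRUE; break }
    if (max(abs(lk$grad)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(lk$hess, lk$grad), error = function(e) NULL)
    if (is.null(step)) { divergent <- TRUE; break }
    newbeta <- beta - step
    newll <- cox_loglik(newbeta, X, times, events, ties)$loglik
    halved <- 0
    while ((!is.finite(newll) || newll < lk$loglik - 1e-12) && halved < 20) {
      step <- step / 2
      newbeta <- beta - step
      newll <- cox_loglik(newbeta, X, times, events, ties)$loglik
      halved <- halved + 1
    }
    # numerical floor: no meaningful likelihood improvement is possible and
    # the gradient is already tiny relative to the likelihood scale
    if (abs(newll - lk$loglik) < 1e-12 * max(1, abs(newll)) &&
        max(abs(lk$grad)) < 1e-6) {
      beta <- newbeta
      converged <- TRUE
      break
    }
    beta <- newbeta
    ll_old <- newll
  }
  lk <- cox_loglik(beta, X, times, events, ties)
  if (!converged && max(abs(lk$grad)) < 1e-8) converged <- TRUE
  if (max(abs(beta)) > 15) { divergent <- TRUE; converged <- FALSE }
  if (divergent)
    warning("Cox partial likelihood appears monotone (perfect separation?); ",
            "estimates are unreliable")
  vcov <- tryCatch(solve(-lk$hess), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  coef_tab <- data.frame(
    term = colnames(X) %||% paste0("x", seq_len(p)),
    coef = beta, se = se, hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    z = z, p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, loglik = lk$loglik, vcov = vcov,
                 iterations = iter, converged = converged,
                 divergent = divergent, ties = ties, n = nrow(X),
                 n_events = sum(events)),
            class = "cox_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, loglik = %.4f%s\n",
              x$n, x$n_events, x$ties, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

# Partial log-likelihood, gradient and Hessian.  Subjects are sorted by
# descending time so that risk-set sums are cumulative sums; tied event
# times are handled per Efron or Breslow.
cox_loglik <- function(beta, X, times, events, ties) {
  ord <- order(-times)
  X <- X[ord, , drop = FALSE]
  times <- times[ord]; events <- events[ord]
  p <- ncol(X); n <- nrow(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  wX <- X * w
  S0 <- cumsum(w)
  S1 <- apply(wX, 2, cumsum)
  S2 <- apply(array_outer(X, w), 2, cumsum)  # n x (p*p), row-wise cumsum
  ll <- 0; grad <- rep(0, p); hess <- matrix(0, p, p)
  ev_idx <- which(events == 1L)
  if (!length(ev_idx)) return(list(loglik = 0, grad = grad, hess = diag(-1e-10, p)))
  for (t in unique(times[ev_idx])) {
    D <- which(times == t & events == 1L)
    d <- length(D)
    last <- max(which(times == t))  # risk set = subjects with time >= t
    s0 <- S0[last]; s1 <- S1[last, ]; s2 <- matrix(S2[last, ], p, p)
    s0d <- sum(w[D]); s1d <- colSums(wX[D, , drop = FALSE])
    s2d <- matrix(colSums(array_outer(X[D, , drop = FALSE], w[D])), p, p)
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      f <- if (ties == "efron") l / d else 0
      den <- s0 - f * s0d
      num1 <- s1 - f * s1d
      num2 <- s2 - f * s2d
      mu <- num1 / den
      ll <- ll - log(den)
      grad <- grad - mu
      hess <- hess - (num2 / den - tcrossprod(mu))
    }
    grad <- grad + colSums(X[D, , drop = FALSE])
  }
  list(loglik = ll, grad = grad, hess = hess)
}

# Row-wise outer products x_i x_i' * w_i flattened to an n x (p*p) matrix.
array_outer <- function(X, w) {
  p <- ncol(X)
  out <- matrix(0, nrow(X), p * p)
  for (a in seq_len(p))
    for (b in seq_len(p))
      out[, (a - 1) * p + b] <- X[, a] * X[, b] * w
  out
}

#' Cohort-level survival analysis
#'
#' Kaplan-Meier curves per group, log-rank and Gehan-Wilcoxon tests, and
#' univariate plus multivariate Cox models using the fixed covariate
#' codings of the reference analysis: age >= 70 vs < 70, male vs female,
#' stage III/IV vs I/II (unknown stage excluded from models that include
#' stage), histology with vs without squamous differentiation, and
#' expression type transitional + basal-like vs classical.
#'
#' @param cohort An `ihc_cohort`; the pattern grouping uses the `pattern`
#'   column if present (see [set_pattern()]) and falls back to
#'   `latent_pattern`.
#' @param grouping `"pattern"` (three expression patterns) or
#'   `"ck56_pos"` (CK5/6 grade >= 1 vs 0).
#' @param subset_histology Optional histology level to restrict to before
#'   analysis (e.g. `"glandular"` for the CK5/6 sub-analysis of
#'   glandular-pattern cases).
#' @param ties Tie handling for the Cox fits.
#' @return List with `km` (per-group `surv_curve`s), `logrank`,
#'   `wilcoxon`, `cox_univariate` (one `cox_fit` per factor),
#'   `cox_multivariate`, and `groups` (the grouping factor used).
#' @export
run_survival_analysis <- function(cohort, grouping = c("pattern", "ck56_pos"),
                                  subset_histology = NULL,
                                  ties = c("efron", "breslow")) {
  grouping <- match.arg(grouping)
  ties <- match.arg(ties)
  cohort <- as_cohort(cohort)
  if (!is.null(subset_histology)) {
    cohort <- cohort[cohort$histology %in% subset_histology, , drop = FALSE]
    class(cohort) <- c("ihc_cohort", "data.frame")
  }
  grp <- cohort_factor(cohort, if (grouping == "pattern") "pattern" else "ck56_pos")
  if (anyNA(grp))
    ihcsub_error("grouping factor has missing values", "schema_error")
  grp <- droplevels(grp)
  if (any(table(grp) == 0) || nlevels(grp) < 2)
    ihcsub_error("empty group after filtering", "empty_group_error")
  split_te <- lapply(levels(grp), function(g)
    list(cohort$time_days[grp == g], cohort$event[grp == g]))
  names(split_te) <- levels(grp)
  km <- lapply(split_te, function(g) km_estimate(g[[1]], g[[2]]))

  covs <- list(
    age70 = as.numeric(cohort$age >= 70),
    male = as.numeric(cohort$sex == "M"),
    stage34 = ifelse(is.na(cohort$stage), NA_real_,
                     as.numeric(cohort$stage %in% c("III", "IV"))),
    sq_diff = as.numeric(cohort$histology == "sq_diff"))
  if (grouping == "pattern") {
    covs$expression_type <- as.numeric(grp != "classical")
  } else {
    covs$ck56_pos <- as.numeric(grp == "positive")
  }
  uni <- lapply(names(covs), function(nm) {
    x <- covs[[nm]]
    keep <- !is.na(x)
    m <- matrix(x[keep], dimnames = list(NULL, nm))
    tryCatch(cox_fit(m, cohort$time_days[keep], cohort$event[keep], ties),
             ihcsub_error = function(e) e)
  })
  names(uni) <- names(covs)
  Xm <- do.call(cbind, covs)
  keep <- stats::complete.cases(Xm)
  Xk <- Xm[keep, , drop = FALSE]
  Xk <- Xk[, apply(Xk, 2, sd) > 0, drop = FALSE]
  multi <- cox_fit(Xk, cohort$time_days[keep], cohort$event[keep], ties)

  list(groups = grp, km = km,
       logrank = logrank_test(split_te),
       wilcoxon = gehan_wilcoxon_test(split_te),
       cox_univariate = uni,
       cox_multivariate = multi)
}
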