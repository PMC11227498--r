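# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-derivations (brute force / exhaustive enumeration)
# kept free of any code path they are used to check.

# Greedy minimum-delta-ESS agglomeration by explicit ESS recomputation,
# with the same deterministic tie-break as ward_linkage (lexicographically
# smallest pair of smallest original indices).
oracle_ward_heights <- function(pts) {
  ess <- function(x) if (nrow(x) < 2) 0 else sum(sweep(x, 2, colMeans(x))^2)
  cl <- lapply(seq_len(nrow(pts)), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(cl) > 1) {
    best <- Inf; bi <- bj <- NA; blo <- Inf; bhi <- Inf
    for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
      d <- ess(pts[c(cl[[i]], cl[[j]]), , drop = FALSE]) -
        ess(pts[cl[[i]], , drop = FALSE]) - ess(pts[cl[[j]], , drop = FALSE])
      lo <- min(min(cl[[i]]), min(cl[[j]]))
      hi <- max(min(cl[[i]]), min(cl[[j]]))
      tol <- 1e-9 * max(1, abs(best))
      if (d < best - tol ||
          (abs(d - best) <= tol && (lo < blo || (lo == blo && hi < bhi)))) {
        best <- d; bi <- i; bj <- j; blo <- lo; bhi <- hi
      }
    }
    heights <- c(heights, best)
    merges <- c(merges, list(sort(c(min(cl[[bi]]), min(cl[[bj]])))))
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl[[bj]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Exhaustive Freeman-Halton p-value: list every non-negative integer table
# with the observed margins via composition recursion in plain R, then sum
# the multivariate hypergeometric probabilities of tables no more probable
# than the observed one.
oracle_ffh_p <- function(tab, rel_tol = 1e-7) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  lfact <- lgamma(seq_len(n + 1))
  cons <- sum(lfact[rs + 1]) + sum(lfact[cs + 1]) - lfact[n + 1]
  logp <- function(t) cons - sum(lfact[t + 1])
  tables <- list()
  fill_row <- function(rowrem, colrem) {
    # all compositions of rowrem into length(colrem) parts bounded by colrem
    if (length(colrem) == 1) {
      if (rowrem <= colrem) return(list(rowrem)) else return(list())
    }
    out <- list()
    for (v in 0:min(rowrem, colrem[1]))
      for (rest in fill_row(rowrem - v, colrem[-1]))
        out <- c(out, list(c(v, rest)))
    out
  }
  build <- function(i, colrem, acc) {
    if (i == nrow(tab)) {
      tables[[length(tables) + 1]] <<- do.call(rbind, c(acc, list(colrem)))
      return(invisible())
    }
    for (row in fill_row(rs[i], colrem))
      build(i + 1, colrem - row, c(acc, list(row)))
  }
  build(1, cs, list())
  lps <- vapply(tables, logp, numeric(1))
  stopifnot(abs(sum(exp(lps)) - 1) < 1e-8)
  sum(exp(lps[lps <= logp(tab) + log1p(rel_tol)]))
}

random_table <- function(nmax = 25, r = 2, cc = 3) {
  repeat {
    n <- sample(4:nmax, 1)
    t <- matrix(0L, r, cc)
    idx <- sample(r * cc, n, replace = TRUE)
    for (i in idx) t[i] <- t[i] + 1L
    if (all(rowSums(t) > 0) && all(colSums(t) > 0)) return(t)
  }
}

# A tiny hand-writable cohort data frame (defaults give two valid cases).
cohort_df <- function(n = 2) {
  data.frame(
    case_id = sprintf("c%02d", seq_len(n)),
    ck56_intensity = rep(c(3L, 0L), length.out = n),
    ck56_proportion = rep(c(5L, 0L), length.out = n),
    p63_intensity = rep(c(3L, 0L), length.out = n),
    p63_proportion = rep(c(5L, 0L), length.out = n),
    gata6_intensity = rep(c(0L, 3L), length.out = n),
    gata6_proportion = rep(c(0L, 5L), length.out = n),
    hnf4a_intensity = rep(c(0L, 3L), length.out = n),
    hnf4a_proportion = rep(c(0L, 5L), length.out = n),
    histology = rep(c("sq_diff", "glandular"), length.out = n),
    stage = rep(c("IV", "II"), length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    age = rep(c(72L, 65L), length.out = n),
    time_days = rep(c(120, 400), length.out = n),
    event = rep(c(1L, 0L), length.out = n),
    stringsAsFactors = FALSE)
}

# z-scored expression matrix with prescribed values, for signature tests
zmat <- function(values, genes, samples = paste0("s", seq_len(ncol(values)))) {
  m <- matrix(values, nrow = length(genes),
              dimnames = list(genes, samples))
  expression_matrix(m, "zscore")
}
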