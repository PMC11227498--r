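counts_fixture <- function() {
  m <- matrix(c(90, 10, 0,
                80, 15, 5,
                50, 30, 20) * 10, nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2", "s3")))
  expression_matrix(m, "counts")
}

test_that("the transform-state machine rejects out-of-order operations", {
  cm <- counts_fixture()
  expect_error(zscore_genes(cm), class = "ihcsub_transform_state_error")
  expect_error(signature_score(cm, custom5_signature()),
               class = "ihcsub_transform_state_error")
  lc <- cpm_log2(cm)
  expect_error(cpm_log2(lc), class = "ihcsub_transform_state_error")
  expect_error(rank_log2fc(zscore_genes(lc), c("low", "high", "high")),
               class = "ihcsub_transform_state_error")
})

test_that("cpm_log2 matches closed forms and conserves a million", {
  one <- expression_matrix(matrix(c(7, 0), 2, 1,
                                  dimnames = list(c("g1", "g2"), "s")),
                           "counts")
  lc <- cpm_log2(one)
  expect_equal(unclass(lc)["g1", "s"], log2(1e6 + 1))  # whole library
  expect_equal(unclass(lc)["g2", "s"], 0)              # zero count, pc = 1
  cm <- counts_fixture()
  cpm <- 2^unclass(cpm_log2(cm)) - 1
  expect_equal(unname(colSums(cpm)), rep(1e6, 3))
  zero <- expression_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")),
                            "counts")
  expect_error(cpm_log2(zero), class = "ihcsub_zero_library_error")
})

test_that("zscore_genes standardizes rows and zeroes constant ones", {
  vals <- matrix(c(1, 2, 3, 4, 4, 4), 2, byrow = TRUE,
                 dimnames = list(c("v", "k"), c("s1", "s2", "s3")))
  z <- zscore_genes(expression_matrix(vals, "log_cpm"))
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(sd(unclass(z)["v", ]), 1)
  expect_equal(unname(unclass(z)["k", ]), c(0, 0, 0))
  # invariant to per-gene affine shifts of the input
  shifted <- expression_matrix(vals + c(10, -3), "log_cpm")
  expect_equal(unclass(zscore_genes(shifted)), unclass(z))
  single <- expression_matrix(matrix(1, 1, 1, dimnames = list("g", "s")),
                              "log_cpm")
  expect_error(zscore_genes(single), class = "ihcsub_range_error")
})

test_that("signature_score sums signed z-scores", {
  z0 <- zmat(matrix(0, 4, 3), c("TP63", "KRT5", "KRT6A", "GATA6"))
  expect_equal(signature_score(z0, gene_signature("s", up = c("TP63", "KRT5")))$score,
               c(0, 0, 0))
  z1 <- zmat(matrix(1, 3, 2), c("A", "B", "C"))
  expect_equal(signature_score(z1, gene_signature("s", up = c("A", "B", "C")))$score,
               c(3, 3))
  # antisymmetric under swapping up and down
  set.seed(3)
  z <- zmat(matrix(rnorm(12), 4), c("A", "B", "C", "D"))
  s_up <- signature_score(z, gene_signature("s", up = c("A", "B"), down = c("C", "D")))
  s_dn <- signature_score(z, gene_signature("s", up = c("C", "D"), down = c("A", "B")))
  expect_equal(s_up$score, -s_dn$score)
  # missing genes skipped with warning; all missing is an error
  expect_warning(
    s <- signature_score(z, gene_signature("s", up = c("A", "NOPE"))),
    "missing")
  expect_equal(s$score, unname(unclass(z)["A", ]))
  expect_error(
    suppressWarnings(signature_score(z, gene_signature("s", up = "NOPE"))),
    class = "ihcsub_missing_gene_error")
})

test_that("custom5_score is exactly signature_score on the fixed sets", {
  for (s in 1:5) {
    sim <- generate_expression(expr_sim_config(n_genes = 50, n_per_group = 10),
                               seed = s)
    z <- zscore_genes(cpm_log2(sim$matrix))
    expect_identical(custom5_score(z)$score,
                     signature_score(z, custom5_signature())$score)
  }
  # hand-built check: up z-scores 1, down z-scores 0 -> 3
  z <- zmat(matrix(c(1, 1, 1, 0, 0), 5, 2), c("TP63", "KRT5", "KRT6A",
                                              "GATA6", "HNF4A"))
  expect_equal(custom5_score(z)$score, c(3, 3))
  # case-insensitive symbol matching
  zl <- zmat(matrix(0, 5, 2), c("tp63", "Krt5", "KRT6a", "gata6", "HNF4a"))
  expect_equal(custom5_score(zl)$score, c(0, 0))
  zm <- zmat(matrix(0, 4, 2), c("TP63", "KRT5", "KRT6A", "GATA6"))
  expect_error(custom5_score(zm), "HNF4A",
               class = "ihcsub_missing_gene_error")
})

test_that("dichotomize_scores splits at the median with ties going low", {
  sv <- structure(data.frame(sample_id = c("a", "b", "c"),
                             score = c(-1, 0, 2)),
                  class = c("score_vector", "data.frame"))
  expect_identical(as.character(dichotomize_scores(sv)),
                   c("low", "low", "high"))
  # symmetric even-n score vector splits evenly
  sv2 <- structure(data.frame(sample_id = letters[1:4],
                              score = c(-2, -1, 1, 2)),
                   class = c("score_vector", "data.frame"))
  expect_identical(unname(table(dichotomize_scores(sv2))[["high"]]), 2L)
  # invariant under monotone transforms
  sv3 <- sv2; sv3$score <- exp(sv2$score)
  expect_identical(dichotomize_scores(sv3), dichotomize_scores(sv2))
  svc <- sv2; svc$score <- rep(1, 4)
  expect_warning(lab <- dichotomize_scores(svc), "identical")
  expect_true(all(lab == "low"))
})

test_that("rank_log2fc recovers constructed shifts", {
  vals <- matrix(c(5, 5, 6, 6,    # +1 in the high group
                   3, 3, 3, 3),   # flat
                 2, byrow = TRUE,
                 dimnames = list(c("up1", "flat"), paste0("s", 1:4)))
  lc <- expression_matrix(vals, "log_cpm")
  fc <- rank_log2fc(lc, c("low", "low", "high", "high"))
  expect_equal(fc$log2fc[fc$gene_id == "up1"], 1)
  expect_equal(fc$log2fc[fc$gene_id == "flat"], 0)
  expect_identical(fc$gene_id[1], "up1")  # sorted descending
  # identical groups -> all zero
  fc0 <- rank_log2fc(lc, c("low", "high", "low", "high"))
  expect_equal(fc0$log2fc[fc0$gene_id == "flat"], 0)
  expect_error(rank_log2fc(lc, rep("low", 4)), class = "ihcsub_empty_group_error")
})

test_that("expression matrices round-trip through delimited text", {
  sim <- generate_expression(expr_sim_config(n_genes = 30, n_per_group = 4),
                             seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim$matrix, path)
  back <- read_expression(path)
  expect_equal(unclass(back), unclass(sim$matrix))
})
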