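#' Expression matrix with a tracked transform state
#'
#' A genes x samples numeric matrix tagged with its transform state:
#' `"counts"` (raw non-negative counts), `"log_cpm"` (counts per million,
#' log2 with pseudocount) or `"zscore"` (per-gene standardized log-CPM).
#' Every operation checks the state of its input, so out-of-order
#' application (e.g. z-scoring raw counts) fails loudly.
#'
#' @param values Numeric matrix with unique row (gene) and column
#'   (sample) names.
#' @param transform State tag, default `"counts"`.
#' @return An `expr_matrix`.
#' @export
expression_matrix <- function(values,
                              transform = c("counts", "log_cpm", "zscore")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ihcsub_error("expression matrix needs gene row names and sample column names",
                 "schema_error")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    ihcsub_error("gene and sample ids must be unique", "duplicate_id_error")
  if (anyNA(values) || !is.numeric(values))
    ihcsub_error("expression values must be numeric and non-missing",
                 "range_error")
  if (transform == "counts" && any(values < 0))
    ihcsub_error("counts must be non-negative", "range_error")
  structure(values, transform = transform,
            class = c("expr_matrix", "matrix"))
}

expr_state <- function(m) attr(m, "transform") %||% "counts"

require_state <- function(m, state, op) {
  if (!identical(expr_state(m), state))
    ihcsub_error(sprintf("%s requires a matrix in state '%s' (got '%s')",
                         op, state, expr_state(m)),
                 "transform_state_error")
  invisible(m)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), expr_state(x)))
  invisible(x)
}

#' Read / write a genes x samples matrix as delimited text
#'
#' Tab-separated, first column the gene id, remaining columns one per
#' sample.
#' @param path File path.
#' @param transform State tag to attach on read.
#' @return An `expr_matrix` (read) or `path` invisibly (write).
#' @export
read_expression <- function(path, transform = "counts") {
  if (!file.exists(path))
    ihcsub_error(paste("file not found:", path), "missing_file_error")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, transform)
}

#' @rdname read_expression
#' @param matrix An `expr_matrix`.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix),
                   as.data.frame(unclass(matrix), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Counts-per-million, log2
#'
#' Library-size normalization: each value becomes
#' `log2(1e6 * value / column_sum + pseudocount)`.  Before the log, the
#' CPM values of each sample sum to one million.
#'
#' @param counts An `expr_matrix` in state `"counts"`; no column may sum
#'   to zero.
#' @param pseudocount Added before the log (default 1, so a zero count
#'   maps to 0).
#' @return An `expr_matrix` in state `"log_cpm"`.
#' @export
cpm_log2 <- function(counts, pseudocount = 1) {
  require_state(counts, "counts", "cpm_log2")
  lib <- colSums(counts)
  if (any(lib == 0))
    ihcsub_error(sprintf("zero library size in sample '%s'",
                         colnames(counts)[which(lib == 0)[1]]),
                 "zero_library_error")
  out <- log2(sweep(unclass(counts), 2, 1e6 / lib, "*") + pseudocount)
  expression_matrix(out, "log_cpm")
}

#' Per-gene z-score normalization
#'
#' Centers and scales each gene row across samples (sample sd, n - 1
#' denominator); zero-variance rows map to all-zeros.
#'
#' @param matrix An `expr_matrix` in state `"log_cpm"` with >= 2 samples.
#' @return An `expr_matrix` in state `"zscore"`.
#' @export
zscore_genes <- function(matrix) {
  require_state(matrix, "log_cpm", "zscore_genes")
  if (ncol(matrix) < 2)
    ihcsub_error("z-scoring needs at least 2 samples", "range_error")
  m <- unclass(matrix)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  expression_matrix(out, "zscore")
}

#' Gene signature
#'
#' A named set of up genes and (optionally) down genes whose z-scores are
#' summed with signs +1 / -1.
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene symbols; disjoint, union
#'   non-empty.
#' @return A `gene_signature`.
#' @export
gene_signature <- function(name, up, down = character(0)) {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(toupper(up), toupper(down))))
    ihcsub_error("up and down gene sets overlap", "schema_error")
  if (!length(up) && !length(down))
    ihcsub_error("signature has no genes", "schema_error")
  structure(list(name = name, up = up, down = down),
            class = "gene_signature")
}

#' The custom five-gene basal-vs-classical signature
#'
#' Up genes TP63, KRT5, KRT6A (basal/squamous axis); down genes GATA6,
#' HNF4A (classical/progenitor axis) — the transcript counterparts of the
#' four-protein IHC panel.
#' @return A `gene_signature`.
#' @export
custom5_signature <- function() {
  gene_signature("custom5", up = c("TP63", "KRT5", "KRT6A"),
                 down = c("GATA6", "HNF4A"))
}

match_genes <- function(matrix, symbols) {
  # case-insensitive symbol match (data sources mix e.g. HNF4A / HNF4a)
  idx <- match(toupper(symbols), toupper(rownames(matrix)))
  setNames(idx, symbols)
}

#' Signature score per sample
#'
#' For each sample, the sum of z-scores over the signature's up genes
#' minus the sum over its down genes.  Symbols are matched
#' case-insensitively; missing genes are skipped with a warning, and an
#' error is raised only when no signature gene is present at all.
#'
#' @param matrix An `expr_matrix` in state `"zscore"`.
#' @param signature A `gene_signature`.
#' @return A `score_vector` data frame: `sample_id`, `score`, with the
#'   signature name as attribute.
#' @export
signature_score <- function(matrix, signature) {
  require_state(matrix, "zscore", "signature_score")
  up_idx <- match_genes(matrix, signature$up)
  dn_idx <- match_genes(matrix, signature$down)
  miss <- c(names(up_idx)[is.na(up_idx)], names(dn_idx)[is.na(dn_idx)])
  if (length(miss) == length(up_idx) + length(dn_idx))
    ihcsub_error(sprintf("no gene of signature '%s' present in the matrix",
                         signature$name),
                 "missing_gene_error")
  if (length(miss))
    warning("signature '", signature$name, "': missing genes skipped: ",
            paste(miss, collapse = ", "))
  score <- numeric(ncol(matrix))
  ui <- up_idx[!is.na(up_idx)]
  di <- dn_idx[!is.na(dn_idx)]
  if (length(ui)) score <- score + colSums(unclass(matrix)[ui, , drop = FALSE])
  if (length(di)) score <- score - colSums(unclass(matrix)[di, , drop = FALSE])
  out <- data.frame(sample_id = colnames(matrix), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "signature") <- signature$name
  class(out) <- c("score_vector", "data.frame")
  out
}

#' The custom five-gene score
#'
#' `[z(TP63) + z(KRT5) + z(KRT6A)] - [z(GATA6) + z(HNF4A)]` per sample,
#' computed directly from the named rows (all five genes must be present;
#' matching is case-insensitive).  Identical by construction to
#' `signature_score(matrix, custom5_signature())`, which tests assert.
#'
#' @param matrix An `expr_matrix` in state `"zscore"`.
#' @return A `score_vector`.
#' @export
custom5_score <- function(matrix) {
  require_state(matrix, "zscore", "custom5_score")
  sig <- custom5_signature()
  idx <- match_genes(matrix, c(sig$up, sig$down))
  if (anyNA(idx))
    ihcsub_error(paste("five-gene score needs all of TP63, KRT5, KRT6A,",
                       "GATA6, HNF4A; missing:",
                       paste(names(idx)[is.na(idx)], collapse = ", ")),
                 "missing_gene_error")
  m <- unclass(matrix)
  score <- colSums(m[c(idx["TP63"], idx["KRT5"], idx["KRT6A"]), , drop = FALSE]) -
    colSums(m[c(idx["GATA6"], idx["HNF4A"]), , drop = FALSE])
  out <- data.frame(sample_id = colnames(matrix), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "signature") <- "custom5"
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Median dichotomization of signature scores
#'
#' Scores strictly above the median are `"high"`, scores at or below it
#' `"low"` (ties at the median go low).  An all-identical score vector is
#' degenerate: everything is `"low"`, with a warning.
#'
#' @param scores A `score_vector` (>= 2 samples).
#' @param rule Only `"median"` is implemented.
#' @return Factor of `"low"`/`"high"` labels named by sample id.
#' @export
dichotomize_scores <- function(scores, rule = c("median")) {
  match.arg(rule)
  s <- scores$score
  if (length(s) < 2)
    ihcsub_error("dichotomization needs >= 2 samples", "range_error")
  if (max(s) == min(s))
    warning("all scores identical; every sample assigned to the low group")
  lab <- factor(ifelse(s > median(s), "high", "low"), levels = c("low", "high"))
  setNames(lab, scores$sample_id)
}

#' Rank genes by log2 fold change between groups
#'
#' Per gene, mean log-CPM in the high group minus mean in the low group,
#' sorted descending.
#'
#' @param matrix An `expr_matrix` in state `"log_cpm"`.
#' @param groups `"low"`/`"high"` labels aligned with the samples (e.g.
#'   from [dichotomize_scores()]); both groups must be non-empty.
#' @return Data frame `gene_id`, `log2fc`, sorted by `log2fc` descending.
#' @export
rank_log2fc <- function(matrix, groups) {
  require_state(matrix, "log_cpm", "rank_log2fc")
  groups <- factor(as.character(groups), levels = c("low", "high"))
  if (length(groups) != ncol(matrix) || anyNA(groups))
    ihcsub_error("groups must be low/high labels, one per sample", "range_error")
  if (!all(table(groups) > 0))
    ihcsub_error("empty group", "empty_group_error")
  m <- unclass(matrix)
  fc <- rowMeans(m[, groups == "high", drop = FALSE]) -
    rowMeans(m[, groups == "low", drop = FALSE])
  out <- data.frame(gene_id = rownames(m), log2fc = unname(fc),
                    stringsAsFactors = FALSE)
  out[order(-out$log2fc), , drop = FALSE]
}
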