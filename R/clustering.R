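#' Standardize matrix columns
#'
#' Centers each column to mean 0 and scales to unit sample standard
#' deviation (n - 1 denominator).  Zero-variance columns map to all-zeros
#' instead of NaN so that a marker constant across the cohort simply drops
#' out of the clustering geometry.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @return Numeric matrix of the same shape.
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2)
    ihcsub_error("standardization needs at least 2 rows", "range_error")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  out <- sweep(m, 2, mu)
  nz <- s > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, s[nz], "/")
  out[, !nz] <- 0
  out
}

#' Ward agglomerative clustering
#'
#' Agglomerative hierarchical clustering in Euclidean space under Ward's
#' minimum-variance criterion: at each step the pair of clusters whose
#' merge minimally increases the total within-cluster error sum of squares
#' (ESS) is merged, and the merge height records that increase
#' (delta-ESS).  Implemented with the Lance-Williams recurrence on squared
#' Euclidean distances; equal merge costs (within relative tolerance
#' 1e-9) are broken by the lexicographically smallest pair of smallest
#' original row indices, so the merge sequence is deterministic across
#' platforms.
#'
#' @param points Numeric matrix, one row per observation (n >= 2).
#' @return An `ihc_dendrogram`: list with `merge` (hclust convention:
#'   negative = leaf), `height` (delta-ESS per merge), `size` (merged
#'   cluster sizes), `labels`, and `order` (leaf order for plotting).
#' @examples
#' d <- ward_linkage(cbind(c(0, 1, 10, 11)))
#' d$height   # 0.5, 0.5, 100: delta-ESS of each merge
#' cut_k(d, 2)
#' @export
ward_linkage <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) ihcsub_error("clustering needs n >= 2 points", "range_error")
  labels <- rownames(points)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # D[i, j] = 2 * delta-ESS of merging clusters i, j; for singletons this
  # is the squared Euclidean distance.
  D <- as.matrix(dist(points))^2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  minidx <- seq_len(n)        # smallest original row index in each cluster
  node <- -seq_len(n)         # hclust node id of each active cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  msize <- integer(n - 1)
  members <- as.list(seq_len(n))
  merge_members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    Dsub <- D[idx, idx, drop = FALSE]
    best <- min(Dsub)
    tol <- 1e-9 * max(1, abs(best))
    cand <- which(Dsub <= best + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (min original index of first
    # cluster, min original index of second cluster)
    a <- idx[cand[, 1]]; b <- idx[cand[, 2]]
    lo <- pmin(minidx[a], minidx[b]); hi <- pmax(minidx[a], minidx[b])
    pick <- order(lo, hi)[1]
    i <- a[pick]; j <- b[pick]
    if (minidx[j] < minidx[i]) { tmp <- i; i <- j; j <- tmp }
    height[step] <- D[i, j] / 2
    merge[step, ] <- sort_nodes(node[i], node[j])
    msize[step] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    merge_members[[step]] <- members[[i]]
    # Lance-Williams update for Ward on squared distances
    k <- setdiff(which(active), c(i, j))
    if (length(k)) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      Dnew <- ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
      D[i, k] <- Dnew; D[k, i] <- Dnew
    }
    sizes[i] <- sizes[i] + sizes[j]
    minidx[i] <- min(minidx[i], minidx[j])
    node[i] <- step
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  structure(list(merge = merge, height = height, size = msize,
                 labels = labels, n = n,
                 order = leaf_order(merge, n),
                 merge_members = merge_members),
            class = "ihc_dendrogram")
}

sort_nodes <- function(a, b) {
  # hclust convention: leaves (negative) before internal nodes, then by id
  key <- function(x) if (x < 0) c(0, -x) else c(1, x)
  ka <- key(a); kb <- key(b)
  if (ka[1] < kb[1] || (ka[1] == kb[1] && ka[2] <= kb[2])) c(a, b) else c(b, a)
}

leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' @export
print.ihc_dendrogram <- function(x, ...) {
  cat(sprintf("<ihc_dendrogram> %d leaves, %d merges; height range %.4g .. %.4g\n",
              x$n, x$n - 1, min(x$height), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.ihc_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward (delta-ESS)",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Export a dendrogram as Newick
#'
#' Serializes the merge tree (with delta-ESS heights as branch lengths)
#' to a Newick string or file for external tree viewers.
#'
#' @param dendrogram An `ihc_dendrogram`.
#' @param path Optional output file; when NULL the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(as.hclust(dendrogram))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges (Ward heights are monotone along any
#' root-ward path, so this equals stopping the agglomeration early) and
#' returns the resulting partition.  Cluster ids are renumbered 1..k in
#' order of first-occurring case.
#'
#' @param dendrogram An `ihc_dendrogram`.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Integer vector of cluster labels named by case label.
#' @export
cut_k <- function(dendrogram, k) {
  n <- dendrogram$n
  if (length(k) != 1 || is.na(k) || k != round(k) || k < 1 || k > n)
    ihcsub_error(sprintf("k must be an integer in 1..%d", n), "range_error")
  lab <- seq_len(n)
  if (k < n) {
    # apply the n - k lowest merges; heights are monotone so these are
    # merges 1 .. n-k in order
    for (step in seq_len(n - k)) {
      mem <- dendrogram$merge_members[[step]]
      lab[mem] <- min(lab[mem])
    }
  }
  out <- match(lab, unique(lab))
  names(out) <- dendrogram$labels
  out
}

#' Label three clusters as expression patterns
#'
#' Given a 3-cluster partition of a grade matrix, labels the cluster with
#' the highest mean composite IHC score (see [ihc_composite_score()]) as
#' basal-like, the lowest as classical, and the remaining one as
#' transitional.  Exact ties on the mean composite are broken by making
#' the smaller cluster basal-like (basal-like is the minority pattern); a
#' fully degenerate solution (all three cluster means identical, e.g. from
#' clustering identical rows) is an error.
#'
#' @param labels Integer cluster labels (exactly 3 distinct values), named
#'   by case id or aligned with `matrix` rows.
#' @param matrix The grade matrix the clustering was computed from.
#' @return A `pattern_assignment`: data frame with `case_id` and `pattern`,
#'   plus a `cluster_means` attribute (mean composite per pattern).
#' @export
label_patterns <- function(labels, matrix) {
  if (length(labels) != nrow(matrix))
    ihcsub_error("labels and matrix rows differ in length", "range_error")
  ids <- sort(unique(labels))
  if (length(ids) != 3)
    ihcsub_error("pattern labeling is defined for exactly 3 clusters",
                 "cluster_count_error")
  comp <- ihc_composite_score(matrix)
  means <- vapply(ids, function(g) mean(comp[labels == g]), numeric(1))
  sizes <- vapply(ids, function(g) sum(labels == g), numeric(1))
  if (max(means) == min(means))
    ihcsub_error("degenerate clustering: all clusters have identical mean composite scores",
                 "degenerate_cluster_error")
  # order ascending mean composite; ties: larger cluster first so that the
  # smaller one lands nearer the basal end
  ord <- order(means, -sizes)
  pattern_of_cluster <- character(3)
  pattern_of_cluster[ord] <- ihc_patterns()
  case_id <- if (!is.null(names(labels))) names(labels) else
    if (!is.null(rownames(matrix))) rownames(matrix) else as.character(seq_along(labels))
  out <- data.frame(case_id = case_id,
                    pattern = factor(pattern_of_cluster[match(labels, ids)],
                                     levels = ihc_patterns()),
                    stringsAsFactors = FALSE)
  attr(out, "cluster_means") <- setNames(means[ord], ihc_patterns())
  attr(out, "cluster_sizes") <- setNames(as.integer(sizes[ord]), ihc_patterns())
  class(out) <- c("pattern_assignment", "data.frame")
  out
}

#' Cluster a cohort into expression patterns
#'
#' Convenience wrapper: grade matrix -> (optional) column standardization
#' -> Ward clustering -> k-way cut -> pattern labeling (for k = 3).
#'
#' @param cohort An `ihc_cohort`.
#' @param k Number of clusters (default 3, the pattern solution).
#' @param standardize Standardize grade columns before clustering
#'   (default `TRUE`).
#' @param values `"grade"` (default) or `"total"` input scale.
#' @return List with `dendrogram`, `clusters`, and (k = 3) `assignment`.
#' @export
cluster_cohort <- function(cohort, k = 3, standardize = TRUE,
                           values = c("grade", "total")) {
  gm <- grade_matrix(cohort, match.arg(values))
  x <- if (standardize) standardize_columns(gm) else gm
  dend <- ward_linkage(x)
  cl <- cut_k(dend, k)
  res <- list(dendrogram = dend, clusters = cl)
  if (k == 3) res$assignment <- label_patterns(cl, grade_matrix(cohort))
  res
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    ihcsub_error("partitions differ in length", "range_error")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  nC2 <- ch2(length(a))
  expected <- sum_a * sum_b / nC2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
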