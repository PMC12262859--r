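## Marker statistics: folded pairwise-rank AUC, informative-marker
## counting, balanced-label permutation nulls, two-group tests, clustering.

.check_two_level <- function(labels) {
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  if (length(lv) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) == 0L)) stop("one group is empty")
  droplevels(labels)
}

#' Orientation-agnostic marker AUC
#'
#' AUC of a single marker for a two-level grouping, computed over all
#' cross-group pairs as `(wins + 0.5 * ties) / (n1 * n2)` via midranks,
#' then folded to `max(A, 1 - A)` so the value does not depend on which
#' group is treated as the case (the better of the two orientations, as
#' auto-direction ROC software reports in all but tie-dominated cases).
#' Range `[0.5, 1]`.
#'
#' @param values Numeric marker values, one per sample.
#' @param labels Two-level grouping of the samples.
#' @return AUC in `[0.5, 1]`.
#' @examples
#' marker_auc(c(5, 6, 7, 1, 2, 6), rep(c("a", "b"), each = 3))  # 0.8333
#' @export
marker_auc <- function(values, labels) {
  labels <- .check_two_level(labels)
  stopifnot(length(values) == length(labels))
  rk <- rank(values)
  n1 <- sum(labels == levels(labels)[1L])
  n2 <- length(values) - n1
  u <- sum(rk[labels == levels(labels)[1L]]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n2)
  max(a, 1 - a)
}

#' Per-marker AUCs for a feature matrix
#'
#' @param matrix Samples x markers numeric matrix.
#' @param labels Two-level grouping of the rows.
#' @return Named numeric vector of folded AUCs, one per marker.
#' @export
auc_by_marker <- function(matrix, labels) {
  labels <- .check_two_level(labels)
  stopifnot(nrow(matrix) == length(labels))
  rk <- apply(matrix, 2L, rank)
  n1 <- sum(labels == levels(labels)[1L])
  n2 <- nrow(matrix) - n1
  u <- colSums(rk[labels == levels(labels)[1L], , drop = FALSE]) -
    n1 * (n1 + 1) / 2
  a <- u / (n1 * n2)
  pmax(a, 1 - a)
}

#' Count informative markers
#'
#' A marker is informative when its folded AUC strictly exceeds the
#' threshold (0.9 for reported counts, 0.8 inside the permutation null).
#'
#' @param matrix Samples x markers matrix.
#' @param labels Two-level grouping.
#' @param threshold AUC threshold in (0.5, 1].
#' @return List: `count` and `markers` (the informative column names).
#' @export
count_informative <- function(matrix, labels, threshold = 0.9) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  aucs <- auc_by_marker(matrix, labels)
  inf <- aucs > threshold
  list(count = sum(inf),
       markers = names(aucs)[inf],
       aucs = aucs)
}

#' Permutation test on the informative-marker count
#'
#' Shuffles the (balanced) two-level labels `n_perm` times; each
#' iteration recomputes every marker's folded AUC and counts markers with
#' AUC above `threshold`, building a null distribution of informative
#' counts. The p-value is the fraction of iterations whose null count is
#' greater than or equal to the observed count (`count / n_perm`; it may
#' be 0); the `add_one` estimator `(count + 1) / (n_perm + 1)` is
#' available but off by default. The one-sided 95\% band is reported as
#' the 95\% empirical quantile of the null counts.
#'
#' @param matrix Samples x markers matrix.
#' @param labels Balanced two-level grouping (e.g. 6 vs 6).
#' @param n_perm Number of permutations (default 1000).
#' @param threshold Informative-AUC threshold inside the permutation
#'   (default 0.8).
#' @param seed Optional integer seed; runs are bit-reproducible.
#' @param p_estimator `"count"` (default) or `"add_one"`.
#' @return List of class `permutation_result`: `observed_informative`,
#'   `null_counts`, `p_value`, `null_q95`, `threshold`, `n_perm`.
#' @export
permutation_test <- function(matrix, labels, n_perm = 1000L,
                             threshold = 0.8, seed = NULL,
                             p_estimator = c("count", "add_one")) {
  p_estimator <- match.arg(p_estimator)
  labels <- .check_two_level(labels)
  tab <- table(labels)
  if (tab[1L] != tab[2L])
    stop("unbalanced labels: permutation design requires equal group sizes")
  n <- length(labels)
  n1 <- as.integer(tab[1L])
  n2 <- n - n1

  rk <- apply(matrix, 2L, rank)
  fold_count <- function(idx1) {
    u <- colSums(rk[idx1, , drop = FALSE]) - n1 * (n1 + 1) / 2
    a <- u / (n1 * n2)
    sum(pmax(a, 1 - a) > threshold)
  }
  observed <- fold_count(which(labels == levels(labels)[1L]))

  if (!is.null(seed)) set.seed(seed)
  ## indicator matrix of permuted group-1 memberships
  ind <- matrix(0, n_perm, n)
  for (i in seq_len(n_perm))
    ind[i, sample.int(n, n1)] <- 1
  s1 <- ind %*% rk
  a <- (s1 - n1 * (n1 + 1) / 2) / (n1 * n2)
  null_counts <- rowSums(pmax(a, 1 - a) > threshold)

  p <- if (p_estimator == "count") mean(null_counts >= observed)
       else (sum(null_counts >= observed) + 1) / (n_perm + 1)
  structure(list(observed_informative = observed,
                 null_counts = null_counts,
                 p_value = p,
                 null_q95 = unname(quantile(null_counts, 0.95)),
                 threshold = threshold, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result: observed %d informative markers",
                     " (AUC > %.2f), p = %.4g, null q95 = %.1f (%d perms)\n"),
              x$observed_informative, x$threshold, x$p_value, x$null_q95,
              x$n_perm))
  invisible(x)
}

#' Two-group comparison (rank-sum or t test)
#'
#' Rank-sum (Mann-Whitney U) test by default: exact when
#' `n1 * n2 <= 400` and the data are tie-free, otherwise the normal
#' approximation with continuity correction; the 95\% interval is the
#' Hodges-Lehmann interval on the location shift. `method = "ttest"` runs
#' the corresponding (paired) t test. Degenerate zero-variance inputs are
#' flagged rather than raised.
#'
#' @param values_a,values_b Numeric samples (n >= 2 each; paired tests
#'   require equal lengths).
#' @param paired Paired test?
#' @param method `"utest"` (default) or `"ttest"`.
#' @param exact Override the exactness rule for the U test.
#' @param conf_level Confidence level for the shift interval.
#' @return List: `p_value`, `conf_int`, `estimate`, `method`,
#'   `degenerate`.
#' @export
two_group_test <- function(values_a, values_b, paired = FALSE,
                           method = c("utest", "ttest"), exact = NULL,
                           conf_level = 0.95) {
  method <- match.arg(method)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least 2 values per group")
  if (paired && length(values_a) != length(values_b))
    stop("paired test requires equal lengths")

  if (method == "ttest") {
    res <- tryCatch(t.test(values_a, values_b, paired = paired,
                           conf.level = conf_level),
                    error = function(e) NULL)
    if (is.null(res) || is.na(res$p.value))
      return(list(p_value = NA_real_, conf_int = c(NA_real_, NA_real_),
                  estimate = NA_real_, method = "ttest", degenerate = TRUE))
    return(list(p_value = res$p.value, conf_int = unname(res$conf.int),
                estimate = unname(res$estimate)[1L], method = "ttest",
                degenerate = FALSE))
  }

  has_ties <- if (paired) {
    d <- values_a - values_b
    any(duplicated(abs(d[d != 0]))) || any(d == 0)
  } else anyDuplicated(c(values_a, values_b)) > 0L
  if (is.null(exact))
    exact <- !has_ties &&
      length(values_a) * length(values_b) <= 400L
  degenerate <- if (paired) all(values_a == values_b)
                else all(c(values_a, values_b) == values_a[1L])
  if (degenerate)
    return(list(p_value = 1, conf_int = c(NA_real_, NA_real_),
                estimate = 0, method = "utest", degenerate = TRUE))
  res <- suppressWarnings(
    wilcox.test(values_a, values_b, paired = paired, exact = exact,
                conf.int = TRUE, conf.level = conf_level))
  list(p_value = res$p.value, conf_int = unname(res$conf.int),
       estimate = unname(res$estimate), method = "utest",
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Hierarchical clustering and PCA of a marker matrix
#'
#' Markers are z-scored (constant markers dropped); samples are clustered
#' on Euclidean distance with average linkage, and projected by PCA of
#' the same standardised matrix.
#'
#' @param matrix Samples x markers matrix (>= 3 samples).
#' @return List: `hclust`, `order` (dendrogram order of row names),
#'   `scores`, `variance_explained`.
#' @export
cluster_and_project <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (nrow(m) < 3L) stop("need >= 3 samples")
  sds <- apply(m, 2L, sd)
  keep <- sds > 0
  if (!any(keep)) stop("degenerate input: constant matrix")
  z <- scale(m[, keep, drop = FALSE])
  hc <- hclust(dist(z), method = "average")
  p <- .pca(z)
  list(hclust = hc,
       order = rownames(m)[hc$order],
       scores = p$scores,
       variance_explained = p$variance_explained)
}
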