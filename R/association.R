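#' Pearson correlation between module scores and antibody features
#'
#' One correlation per (module, antibody feature) pair over the shared
#' participants of a group subset. Pairs involving a constant vector are
#' reported missing with a warning.
#'
#' @param btm_scores sets x participants enrichment matrix.
#' @param antibody antibody features x participants matrix.
#' @param participants optional participant subset (>= 3).
#' @return modules x antibody-features correlation matrix.
#' @export
pearson_matrix <- function(btm_scores, antibody, participants = NULL) {
  shared <- intersect(colnames(btm_scores), colnames(antibody))
  if (!is.null(participants)) shared <- intersect(shared, participants)
  if (length(shared) < 3)
    stop("need at least 3 shared participants", call. = FALSE)
  a <- t(btm_scores[, shared, drop = FALSE])
  b <- t(antibody[, shared, drop = FALSE])
  suppressWarnings(r <- stats::cor(a, b, use = "pairwise.complete.obs"))
  if (anyNA(r))
    warning("constant vector(s): some correlations reported missing",
            call. = FALSE)
  r
}

#' PCA with per-variable contributions
#'
#' Centred, unit-variance principal component analysis of a complete
#' participants-in-columns feature table. The contribution of variable v to
#' component c is `100 * loading(v,c)^2 / sum_v loading(v,c)^2`, so
#' contributions sum to 100 per component.
#'
#' @param mat features x participants complete matrix.
#' @param n_components number of components to return (<= min(n, p)).
#' @return list with `var_explained` (fractions, non-increasing), `scores`
#'   (participants x components), `contributions` (features x components,
#'   percent).
#' @export
pca_with_contributions <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat), !anyNA(mat))
  x <- t(mat)   # participants x features
  if (n_components > min(dim(x)))
    stop("n_components = ", n_components, " exceeds min(n, p) = ",
         min(dim(x)), call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  pc <- stats::prcomp(x, center = TRUE, scale. = all(sds > 0))
  keep <- seq_len(n_components)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation[, keep, drop = FALSE]^2, 2,
                         colSums(pc$rotation[, keep, drop = FALSE]^2), "/")
  list(var_explained = var_explained[keep],
       scores = pc$x[, keep, drop = FALSE],
       contributions = contrib)
}

#' Pairwise group-difference tests with BH adjustment
#'
#' Two-sided rank-sum (Wilcoxon) tests for every pair of groups and every
#' feature, Benjamini-Hochberg adjusted across the whole result set, plus
#' the label of the group with the highest median per feature. Groups with
#' fewer than `min_group` members are excluded with a warning.
#'
#' @param mat features x participants matrix.
#' @param groups named group labels covering the participants.
#' @param alpha significance level applied to the adjusted p-values.
#' @param min_group minimum group size (default 3).
#' @return list with `tests` (data frame: feature, group1, group2, p,
#'   p_adjusted, significant) and `highest_median` (named character vector).
#' @export
group_difference_tests <- function(mat, groups, alpha = 0.05, min_group = 3) {
  groups <- groups[colnames(mat)]
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_group]
  if (length(small) > 0L) {
    warning("group(s) with fewer than ", min_group, " members excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% small)
    mat <- mat[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (f in rownames(mat)) {
    for (pi in seq_len(ncol(pairs))) {
      g1 <- pairs[1, pi]; g2 <- pairs[2, pi]
      x1 <- mat[f, groups == g1]; x2 <- mat[f, groups == g2]
      p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group1 = g1, group2 = g2, p = p,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_adjusted <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$p_adjusted < alpha
  medians <- vapply(lv, function(g)
    apply(mat[, groups == g, drop = FALSE], 1, stats::median, na.rm = TRUE),
    numeric(nrow(mat)))
  medians <- matrix(medians, nrow = nrow(mat),
                    dimnames = list(rownames(mat), lv))
  highest <- apply(medians, 1, function(x) lv[which.max(x)])
  list(tests = tests, highest_median = highest)
}
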