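#' K-means clustering of module enrichment profiles
#'
#' Clusters gene sets (rows of the enrichment matrix) into k functional
#' clusters with multiple seeded restarts, and reports the total
#' within-cluster sum of squares over a range of k to support the elbow
#' choice. k is fixed (default 5) rather than auto-selected; the elbow
#' diagnostics are emitted for inspection.
#'
#' @param enr sets x samples enrichment matrix.
#' @param k number of clusters (>= 2, <= number of sets).
#' @param seed integer seed (restarts are reproducible).
#' @param k_range integer vector of k values for elbow diagnostics.
#' @param nstart random restarts per k.
#' @return list with `assignment` (named integer vector set -> cluster),
#'   `centers`, and `elbow` (data frame of k and total within-cluster SS).
#' @export
kmeans_functional_clusters <- function(enr, k = 5, seed = 1L,
                                       k_range = 2:10, nstart = 25) {
  stopifnot(is.matrix(enr), k >= 2)
  if (k > nrow(enr))
    stop("k = ", k, " exceeds the number of gene sets (", nrow(enr), ")",
         call. = FALSE)
  k_range <- k_range[k_range <= nrow(enr)]
  withr::with_seed(seed, {
    elbow <- data.frame(k = k_range, within_ss = vapply(k_range, function(kk) {
      stats::kmeans(enr, centers = kk, nstart = nstart,
                    iter.max = 50)$tot.withinss
    }, numeric(1)))
    fit <- stats::kmeans(enr, centers = k, nstart = nstart, iter.max = 50)
  })
  list(assignment = stats::setNames(fit$cluster, rownames(enr)),
       centers = fit$centers, elbow = elbow)
}

#' Cluster correlated predictors and pick max-IQR representatives
#'
#' Features with pairwise Pearson correlation above `r_threshold` are grouped
#' by agglomerative (Ward.D2) clustering on the distance `1 - r`, cutting at
#' height `1 - r_threshold`. Because Ward heights are not on the correlation
#' scale, each resulting cluster is post-validated: clusters whose minimum
#' pairwise correlation does not exceed the threshold are split recursively
#' until all clusters are mutually correlated above it. Constant features
#' (undefined correlation) become singletons with a warning. The
#' representative of each cluster is its member with the largest IQR (ties
#' broken by name order).
#'
#' @param mat features x participants matrix (>= 3 participants).
#' @param r_threshold Pearson correlation threshold (default 0.8).
#' @return data frame with columns `feature`, `cluster`, `representative`
#'   (logical), ordered by feature name; exactly one representative per
#'   cluster.
#' @export
correlation_clusters <- function(mat, r_threshold = 0.8) {
  stopifnot(is.matrix(mat), ncol(mat) >= 3, !is.null(rownames(mat)))
  feats <- rownames(mat)
  sds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  const <- sds == 0 | is.na(sds)
  if (any(const))
    warning("constant feature(s) assigned singleton clusters: ",
            paste(feats[const], collapse = ", "), call. = FALSE)
  work <- feats[!const]

  groups <- list()
  if (length(work) == 1L) {
    groups <- list(work)
  } else if (length(work) > 1L) {
    cm <- stats::cor(t(mat[work, , drop = FALSE]),
                     use = "pairwise.complete.obs")
    split_valid <- function(members) {
      if (length(members) == 1L) return(list(members))
      sub <- cm[members, members, drop = FALSE]
      if (min(sub) > r_threshold) return(list(members))
      if (length(members) == 2L) return(list(members[1], members[2]))
      hc <- stats::hclust(stats::as.dist(1 - sub), method = "ward.D2")
      parts <- split(members, stats::cutree(hc, k = 2))
      do.call(c, lapply(parts, split_valid))
    }
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "ward.D2")
    initial <- split(work, stats::cutree(hc, h = 1 - r_threshold))
    groups <- do.call(c, lapply(initial, split_valid))
  }
  groups <- c(groups, as.list(feats[const]))
  # deterministic cluster ids: order groups by their first feature name
  groups <- groups[order(vapply(groups, function(g) sort(g)[1], character(1)))]

  iqrs <- apply(mat, 1, stats::IQR, na.rm = TRUE)
  rows <- do.call(rbind, lapply(seq_along(groups), function(ci) {
    g <- sort(groups[[ci]])
    rep <- g[order(-iqrs[g], g)][1]
    data.frame(feature = g, cluster = ci, representative = g == rep,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$feature), ]
  rownames(rows) <- NULL
  rows
}
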