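#' Average importances within correlation clusters
#'
#' Highly correlated predictors split LASSO selection counts and dilute
#' forest permutation importances; the correction replaces every member's
#' raw value by the arithmetic mean of its cluster, so within-cluster values
#' become identical and per-cluster sums are preserved. Applies unchanged to
#' LASSO counts, \%IncMSE-style importances, and mean decrease in accuracy.
#'
#' @param importances named numeric vector (one value per predictor).
#' @param clusters a [correlation_clusters()] data frame covering every
#'   predictor.
#' @return the corrected named vector, same order as the input.
#' @export
correct_importances <- function(importances, clusters) {
  stopifnot(!is.null(names(importances)))
  absent <- setdiff(names(importances), clusters$feature)
  if (length(absent) > 0L)
    stop("predictor(s) absent from the cluster map: ",
         paste(absent, collapse = ", "), call. = FALSE)
  cl <- clusters$cluster[match(names(importances), clusters$feature)]
  means <- tapply(importances, cl, mean)
  out <- as.numeric(means[as.character(cl)])
  names(out) <- names(importances)
  out
}

#' Dense rank with ties
#'
#' Rank 1 goes to the largest value when `descending` (the default: most
#' important first); equal values share a rank and ranks form a gapless
#' sequence 1, 2, ...
#'
#' @param values finite numeric vector.
#' @param descending rank from largest (default) or smallest.
#' @return integer ranks, names preserved.
#' @export
dense_rank <- function(values, descending = TRUE) {
  stopifnot(all(is.finite(values)))
  u <- sort(unique(values), decreasing = descending)
  out <- match(values, u)
  names(out) <- names(values)
  out
}

#' Combine LASSO and forest rankings
#'
#' The combined rank is the elementwise mean of the two dense ranks; it is
#' then standardised (z-scored) within the antibody feature. The population
#' standard deviation (divisor n) is the default.
#'
#' @param lasso_ranks,rf_ranks named rank vectors over the same predictor
#'   universe.
#' @param population standardise with the population SD (default `TRUE`).
#' @return data frame with `predictor`, `lasso_rank`, `rf_rank`, `combined`,
#'   `standardized`.
#' @export
aggregate_ranks <- function(lasso_ranks, rf_ranks, population = TRUE) {
  if (!setequal(names(lasso_ranks), names(rf_ranks))) {
    diff <- c(setdiff(names(lasso_ranks), names(rf_ranks)),
              setdiff(names(rf_ranks), names(lasso_ranks)))
    stop("predictor universes differ: ", paste(diff, collapse = ", "),
         call. = FALSE)
  }
  rf_ranks <- rf_ranks[names(lasso_ranks)]
  combined <- (lasso_ranks + rf_ranks) / 2
  mu <- mean(combined)
  sdv <- if (population) sqrt(mean((combined - mu)^2)) else stats::sd(combined)
  std <- if (sdv > 0) (combined - mu) / sdv else combined * 0
  data.frame(predictor = names(lasso_ranks),
             lasso_rank = as.numeric(lasso_ranks),
             rf_rank = as.numeric(rf_ranks),
             combined = as.numeric(combined),
             standardized = as.numeric(std),
             stringsAsFactors = FALSE)
}

#' Spearman agreement between two rankings
#'
#' @param lasso_ranks,rf_ranks named rank vectors over >= 3 predictors.
#' @return Spearman rho (tie-corrected); `NA` with a warning when either
#'   ranking is constant.
#' @export
rank_agreement <- function(lasso_ranks, rf_ranks) {
  stopifnot(length(lasso_ranks) >= 3)
  rf_ranks <- rf_ranks[names(lasso_ranks)]
  if (stats::sd(lasso_ranks) == 0 || stats::sd(rf_ranks) == 0) {
    warning("constant ranking: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(lasso_ranks, rf_ranks, method = "spearman")
}

#' Rank predictors for one antibody feature from paired fits
#'
#' Applies the correlation-cluster correction to the LASSO selection counts
#' and the forest importances, dense-ranks each corrected vector (correction
#' precedes ranking), and aggregates. Predictors never selected by the LASSO
#' share the worst rank through the count 0 tie.
#'
#' @param summary a [summarize_models()] result.
#' @param clusters a [correlation_clusters()] map over the predictors.
#' @return data frame as [aggregate_ranks()], plus corrected raw values.
#' @export
rank_predictors <- function(summary, clusters) {
  stopifnot(inherits(summary, "model_summary"))
  sel_c <- correct_importances(summary$selection_count, clusters)
  imp_c <- correct_importances(summary$importance, clusters)
  out <- aggregate_ranks(dense_rank(sel_c), dense_rank(imp_c))
  out$lasso_corrected <- as.numeric(sel_c[out$predictor])
  out$rf_corrected <- as.numeric(imp_c[out$predictor])
  out
}

#' Union of top-k predictors across antibody features and timepoints
#'
#' For each (feature, timepoint) ranking, predictors whose dense-ranked
#' combined rank is at most k enter the union. Returns the union ordered by
#' how many rankings each predictor is top-k for (ties by name), the
#' standardized-rank membership matrix, and the per-predictor top-k counts.
#'
#' @param rankings named list of [rank_predictors()] data frames (names like
#'   `"total_Ig|D60"`); typically restricted to predictable features.
#' @param k top cut-off (>= 1).
#' @return list with `predictors`, `membership` (predictor x ranking matrix
#'   of standardized ranks), `counts`.
#' @export
top_k_union <- function(rankings, k = 10) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  stopifnot(length(rankings) >= 1, !is.null(names(rankings)))
  top_lists <- lapply(rankings, function(rk) {
    rk$predictor[dense_rank(rk$combined, descending = FALSE) <= k]
  })
  union_p <- sort(unique(unlist(top_lists)))
  counts <- vapply(union_p, function(p)
    sum(vapply(top_lists, function(tl) p %in% tl, logical(1))), integer(1))
  ord <- order(-counts, union_p)
  union_p <- union_p[ord]; counts <- counts[ord]
  membership <- vapply(rankings, function(rk) {
    stats::setNames(rk$standardized, rk$predictor)[union_p]
  }, numeric(length(union_p)))
  membership <- matrix(membership, nrow = length(union_p),
                       dimnames = list(union_p, names(rankings)))
  list(predictors = union_p, membership = membership, counts = counts)
}
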