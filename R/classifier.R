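#' Classify adjuvant groups from innate features
#'
#' Penalised logistic LASSO discriminating the two adjuvant super-groups
#' (AS01/AS03-like vs AS04/Alum-like) over an outer split plan, with the
#' penalty chosen by the inner cross-validation of [fit_lasso_nested()].
#' Reports per-feature selection frequencies (percent of repeats selecting
#' the feature), adjusted by within-correlation-cluster averaging, the
#' pooled test-set accuracy, the null-model accuracy (the majority-class
#' rate), and a one-sided binomial p-value of the pooled correct count
#' against the null rate (the workflow does not prescribe a test; the
#' one-sided pooled binomial is this package's choice).
#'
#' @param X participants x features matrix (complete, z-scaled).
#' @param labels 2-level factor (or coercible) of group membership aligned
#'   with `rownames(X)`; both classes need >= 5 members.
#' @param plan a [make_split_plan()].
#' @param clusters optional [correlation_clusters()] map for the frequency
#'   adjustment (identity when omitted).
#' @param ... passed to [fit_lasso_nested()] (`inner_repeats`, `seed`, ...).
#' @return list of class `classifier_report`: `frequency` (raw, percent),
#'   `frequency_adjusted`, `accuracy`, `null_accuracy`, `p_value`,
#'   `balanced_accuracy`, `n_repeats_used`, `fits`.
#' @export
classify_groups <- function(X, labels, plan, clusters = NULL, ...) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must have exactly two classes", call. = FALSE)
  if (any(table(labels) < 5))
    stop("both classes need at least 5 members", call. = FALSE)
  names(labels) <- rownames(X)
  fits <- fit_lasso_nested(X, labels, plan, family = "binomial", ...)
  ok <- !vapply(fits, `[[`, logical(1), "skipped")
  if (!any(ok)) stop("no successful repeat", call. = FALSE)

  freq <- stats::setNames(rep(0, ncol(X)), colnames(X))
  for (f in fits[ok]) freq[f$selected] <- freq[f$selected] + 1
  freq <- 100 * freq / sum(ok)
  freq_adj <- if (is.null(clusters)) freq else correct_importances(freq, clusters)

  n_correct <- sum(vapply(fits[ok], `[[`, numeric(1), "n_correct"))
  n_total <- sum(vapply(fits[ok], function(f) length(f$test_ids), numeric(1)))
  null_rate <- max(table(labels)) / length(labels)
  p_value <- stats::binom.test(n_correct, n_total, p = null_rate,
                               alternative = "greater")$p.value

  structure(list(frequency = freq,
                 frequency_adjusted = freq_adj,
                 accuracy = n_correct / n_total,
                 null_accuracy = null_rate,
                 p_value = p_value,
                 balanced_accuracy =
                   mean(vapply(fits[ok], `[[`, numeric(1), "test_metric")),
                 n_repeats_used = sum(ok),
                 fits = fits),
            class = "classifier_report")
}

#' Order discriminating features by adjusted selection frequency
#'
#' @param report a `classifier_report`.
#' @param top_n rows to return (default all).
#' @return data frame `feature`, `frequency` (adjusted, percent), `raw`,
#'   sorted by frequency descending, ties broken lexicographically.
#' @export
report_discriminators <- function(report, top_n = NULL) {
  stopifnot(inherits(report, "classifier_report"))
  f <- report$frequency_adjusted
  ord <- order(-f, names(f))
  out <- data.frame(feature = names(f)[ord],
                    frequency = as.numeric(f[ord]),
                    raw = as.numeric(report$frequency[names(f)[ord]]),
                    stringsAsFactors = FALSE)
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
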