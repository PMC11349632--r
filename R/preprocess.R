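#' Collapse probe-level expression to gene level
#'
#' Probes without a gene symbol are discarded; when several probes map to
#' the same symbol, the single probe with the maximum mean expression across
#' all samples is retained and renamed to the symbol.
#'
#' @param expr probes x samples numeric matrix.
#' @param annotation data frame with columns `probe` and `symbol`
#'   (`NA`/empty symbol = unmapped).
#' @return genes x samples matrix, one row per symbol.
#' @export
collapse_probes <- function(expr, annotation) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            all(c("probe", "symbol") %in% names(annotation)))
  if (anyDuplicated(annotation$probe))
    stop("annotation has duplicate probe ids", call. = FALSE)
  ann <- annotation[!is.na(annotation$symbol) & nzchar(annotation$symbol), ]
  ann <- ann[ann$probe %in% rownames(expr), ]
  if (nrow(ann) == 0L)
    stop("no annotated probe overlaps the expression matrix", call. = FALSE)
  means <- rowMeans(expr[ann$probe, , drop = FALSE], na.rm = TRUE)
  # per symbol, the probe with the maximal mean; ties broken by probe order
  ord <- order(ann$symbol, -means, ann$probe)
  keep <- ann[ord, ][!duplicated(ann$symbol[ord]), ]
  out <- expr[keep$probe, , drop = FALSE]
  rownames(out) <- keep$symbol
  out[order(rownames(out)), , drop = FALSE]
}

#' Filter rows by interquartile range
#'
#' Keeps rows whose IQR is strictly greater than `threshold` (rows with
#' IQR at or below it are removed). Quantiles use the linear-interpolation
#' convention (type 7), the default of the environment the workflow targets.
#'
#' @param mat features x samples numeric matrix (>= 2 samples).
#' @param threshold IQR cut-off; default 0.75.
#' @param type quantile type passed to [stats::quantile()].
#' @return the filtered matrix (possibly 0 rows).
#' @export
iqr_filter <- function(mat, threshold = 0.75, type = 7) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  iqrs <- apply(mat, 1, stats::IQR, na.rm = TRUE, type = type)
  keep <- iqrs > threshold
  if (!any(keep)) message("iqr_filter: no row exceeds IQR ", threshold)
  mat[keep, , drop = FALSE]
}

#' Replace censored analyte values by truncated-normal draws
#'
#' Each censored entry is drawn from a normal distribution with mean half
#' the detection threshold and standard deviation 1, truncated to
#' `[lower, threshold]`. The nominal lower bound of 1 is impossible for
#' thresholds below 1 (e.g. the 0.822 pg/mL cytokine cut-offs), so the lower
#' bound is 1 when the threshold exceeds 1 and 0 otherwise; this is logged.
#'
#' @param panel an `analyte_panel` with censored flags set (see
#'   [apply_censoring()]).
#' @param seed integer seed; draws are deterministic given it.
#' @return the panel with censored values imputed (flags retained).
#' @export
impute_below_loq <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "analyte_panel"))
  thr <- panel$thresholds[rownames(panel$values)]
  if (any(is.na(thr)) || any(thr <= 0))
    stop("all analytes need a positive detection threshold", call. = FALSE)
  withr::with_seed(seed, {
    for (a in rownames(panel$values)) {
      idx <- which(panel$censored[a, ])
      if (length(idx) == 0L) next
      lower <- if (thr[[a]] > 1) 1 else 0
      if (lower == 0)
        message("impute_below_loq: threshold ", thr[[a]], " for ", a,
                " is below 1; using lower truncation bound 0")
      panel$values[a, idx] <- rtruncnorm(length(idx), mean = thr[[a]] / 2,
                                         sd = 1, lower = lower,
                                         upper = thr[[a]])
    }
    panel
  })
}

# inverse-CDF truncated normal sampler
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

# mean of the truncated normal (closed form, used as oracle cross-check)
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Per-participant log fold change (post minus pre)
#'
#' Inputs are already on log scale, so the fold change is the elementwise
#' difference. Participants missing from either timepoint are excluded with
#' a warning.
#'
#' @param post,pre features x participants matrices on log scale.
#' @return features x participants logFC matrix over the shared participants.
#' @export
log_fold_change <- function(post, pre) {
  stopifnot(is.matrix(post), is.matrix(pre))
  if (!identical(sort(rownames(post)), sort(rownames(pre))))
    stop("post and pre matrices have different features", call. = FALSE)
  shared <- intersect(colnames(post), colnames(pre))
  if (length(shared) == 0L)
    stop("no participant present at both timepoints", call. = FALSE)
  lost <- setdiff(union(colnames(post), colnames(pre)), shared)
  if (length(lost) > 0L)
    warning("participants missing one timepoint excluded: ",
            paste(lost, collapse = ", "), call. = FALSE)
  post[, shared, drop = FALSE] - pre[rownames(post), shared, drop = FALSE]
}

#' Apply per-feature scaling rules
#'
#' Rules map each feature (row) to one of `"log10"`, `"log2"`, `"reverse"`
#' (multiply by -1, used for the avidity parameter W1 in ordination mode so
#' that higher values mean higher avidity), or `"none"`. Non-positive values
#' under a log rule are an error naming the offending cell.
#'
#' @param mat features x samples matrix.
#' @param rules named character vector, one rule per row of `mat`.
#' @return the scaled matrix.
#' @export
scale_features <- function(mat, rules) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  missing_rule <- setdiff(rownames(mat), names(rules))
  if (length(missing_rule) > 0L)
    stop("no scaling rule for feature(s): ",
         paste(missing_rule, collapse = ", "), call. = FALSE)
  for (f in rownames(mat)) {
    r <- rules[[f]]
    if (r %in% c("log10", "log2")) {
      bad <- which(!is.na(mat[f, ]) & mat[f, ] <= 0)
      if (length(bad) > 0L)
        stop("non-positive value under ", r, " rule at feature '", f,
             "', sample '", colnames(mat)[bad[1]], "'", call. = FALSE)
      mat[f, ] <- if (r == "log10") log10(mat[f, ]) else log2(mat[f, ])
    } else if (r == "reverse") {
      mat[f, ] <- -mat[f, ]
    } else if (r != "none") {
      stop("unknown scaling rule '", r, "' for feature '", f, "'",
           call. = FALSE)
    }
  }
  mat
}

#' Drop participants with too many missing features
#'
#' A participant is dropped iff their missing fraction strictly exceeds
#' `max_missing_frac` (a participant at exactly the boundary is kept).
#'
#' @param mat features x participants matrix.
#' @param max_missing_frac maximum tolerated missing fraction, in (0, 1).
#' @return the matrix restricted to retained participants, with dropped ids
#'   in attribute `"dropped"`.
#' @export
filter_participants <- function(mat, max_missing_frac = 0.5) {
  stopifnot(max_missing_frac > 0, max_missing_frac < 1)
  frac <- colMeans(is.na(mat))
  drop <- frac > max_missing_frac
  if (all(drop))
    stop("every participant exceeds the missingness threshold", call. = FALSE)
  if (any(drop))
    message("filter_participants: dropped ",
            paste(colnames(mat)[drop], collapse = ", "))
  out <- mat[, !drop, drop = FALSE]
  attr(out, "dropped") <- colnames(mat)[drop]
  out
}

#' K-nearest-neighbour imputation
#'
#' A missing cell for participant j is replaced by the weighted mean of the
#' k participants nearest to j in Euclidean distance over co-observed
#' features, with weights `exp(-d)`; ties are broken by column order, so the
#' result is deterministic. Distances use features as given (the pipeline
#' calls this after z-scaling).
#'
#' @param mat features x participants matrix.
#' @param k number of neighbours (default 10).
#' @return the completed matrix.
#' @export
knn_impute <- function(mat, k = 10) {
  stopifnot(is.matrix(mat), k >= 1)
  n_obs <- rowSums(!is.na(mat))
  if (any(n_obs < k))
    stop("feature(s) observed in fewer than k participants: ",
         paste(rownames(mat)[n_obs < k], collapse = ", "), call. = FALSE)
  if (!anyNA(mat)) return(mat)
  n <- ncol(mat)
  out <- mat   # all reads use the original observed pattern
  for (j in seq_len(n)) {
    miss <- which(is.na(mat[, j]))
    if (length(miss) == 0L) next
    d <- rep(Inf, n)
    for (l in seq_len(n)) {
      if (l == j) next
      co <- which(!is.na(mat[, j]) & !is.na(mat[, l]))
      if (length(co) == 0L) next
      d[l] <- sqrt(sum((mat[co, j] - mat[co, l])^2))
    }
    for (f in miss) {
      cand <- which(is.finite(d) & !is.na(mat[f, ]))
      if (length(cand) == 0L)
        stop("cannot impute feature '", rownames(mat)[f],
             "' for participant '", colnames(mat)[j],
             "': no neighbour observes it", call. = FALSE)
      # k nearest among candidates; stable order breaks distance ties
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      w <- exp(-d[nb])
      if (sum(w) == 0) w <- rep(1, length(nb))
      out[f, j] <- sum(w * mat[f, nb]) / sum(w)
    }
  }
  out
}

#' Z-scale rows of a matrix
#' @param mat features x samples matrix.
#' @param population use the population SD (divisor n) instead of sample SD.
#' @return the row-standardised matrix; constant rows become all zero with a
#'   warning.
#' @export
z_scale <- function(mat, population = FALSE) {
  mu <- rowMeans(mat, na.rm = TRUE)
  centered <- mat - mu
  ss <- rowSums(centered^2, na.rm = TRUE)
  nn <- rowSums(!is.na(mat))
  sd <- sqrt(ss / (nn - !population))
  if (any(sd == 0, na.rm = TRUE)) {
    warning("z_scale: constant feature(s) set to 0: ",
            paste(rownames(mat)[which(sd == 0)], collapse = ", "),
            call. = FALSE)
    sd[sd == 0] <- 1
  }
  centered / sd
}

#' Integrate innate and antibody features into a model-ready table
#'
#' Keeps only participants present in the innate table, merges the antibody
#' features of one timepoint, z-scales every feature over the retained
#' participants, then imputes remaining missing cells with
#' [knn_impute()] (scale first, then impute, mirroring the stated order of
#' the source workflow).
#'
#' @param innate innate features x participants matrix (module scores and
#'   analyte logFC), already participant-filtered.
#' @param antibody antibody features x participants matrix for one timepoint.
#' @param knn_k neighbours for imputation.
#' @param scale_within_train if `FALSE` (default) the whole table is z-scaled
#'   once, reproducing the source order of operations; callers wanting
#'   leakage-free scaling handle it per split.
#' @return complete features x participants matrix (innate rows first).
#' @export
integrate_features <- function(innate, antibody, knn_k = 10,
                               scale_within_train = FALSE) {
  shared <- intersect(colnames(innate), colnames(antibody))
  if (length(shared) == 0L)
    stop("innate and antibody tables share no participants", call. = FALSE)
  merged <- rbind(innate[, shared, drop = FALSE],
                  antibody[, shared, drop = FALSE])
  if (!scale_within_train) merged <- z_scale(merged)
  knn_impute(merged, k = knn_k)
}
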