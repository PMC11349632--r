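#' Build a reproducible outer train/test split plan
#'
#' Uniform random splits, reused verbatim for the LASSO and the random
#' forest so the two methods see identical data (paired comparison). The
#' test set has `round(test_frac * n)` participants.
#'
#' @param ids participant ids (n >= 10).
#' @param outer_repeats number of outer splits (default 100).
#' @param test_frac test fraction (default 0.2, the 80:20 rule).
#' @param seed integer seed.
#' @return list of class `split_plan`; each element has `$train` and `$test`.
#' @export
make_split_plan <- function(ids, outer_repeats = 100, test_frac = 0.2,
                            seed = 1L) {
  n <- length(ids)
  stopifnot(n >= 10, outer_repeats >= 1)
  n_test <- round(test_frac * n)
  if (n_test < 1 || n_test >= n)
    stop("test_frac = ", test_frac, " yields an empty train or test set",
         call. = FALSE)
  plan <- withr::with_seed(seed, {
    lapply(seq_len(outer_repeats), function(r) {
      test <- sort(sample(ids, n_test))
      list(train = setdiff(ids, test), test = test)
    })
  })
  attr(plan, "test_frac") <- test_frac
  attr(plan, "seed") <- seed
  class(plan) <- "split_plan"
  plan
}

#' Balanced accuracy of a binary confusion
#' @param truth,pred factors (or vectors) with the same two-level universe.
#' @return mean of the two class-specific recalls (sensitivity and
#'   specificity).
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  lv <- sort(unique(truth))
  mean(vapply(lv, function(l) mean(pred[truth == l] == l), numeric(1)))
}

test_r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}

# Inner cross-validated curve of prediction error over a fixed lambda grid.
# Returns the curve averaged over `inner_repeats` repeats of
# `inner_folds`-fold CV (pooled error per repeat), plus the ids it touched.
inner_cv_curve <- function(X, y, grid, inner_repeats, inner_folds, family) {
  n <- nrow(X)
  curves <- matrix(0, inner_repeats, length(grid))
  for (r in seq_len(inner_repeats)) {
    folds <- if (family == "binomial") {
      # stratified folds keep both classes in every training part
      f <- integer(n)
      for (cl in levels(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(inner_folds), length(idx)))
      }
      f
    } else {
      sample(rep_len(seq_len(inner_folds), n))
    }
    err <- matrix(NA_real_, n, length(grid))
    for (k in seq_len(inner_folds)) {
      hold <- folds == k
      fit <- glmnet::glmnet(X[!hold, , drop = FALSE], y[!hold],
                            family = family, lambda = grid)
      if (family == "binomial") {
        pr <- stats::predict(fit, X[hold, , drop = FALSE], type = "response")
        yy <- as.numeric(y[hold] == levels(y)[2])
        pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
        err[hold, ] <- -2 * (yy * log(pr) + (1 - yy) * log(1 - pr))
      } else {
        pr <- stats::predict(fit, X[hold, , drop = FALSE])
        err[hold, ] <- (y[hold] - pr)^2
      }
    }
    curves[r, ] <- colMeans(err)
  }
  colMeans(curves)
}

#' Nested cross-validated LASSO over a split plan
#'
#' Per outer repeat: on the training set only, a lambda grid is laid out and
#' the cross-validated error curve is computed for each of `inner_repeats`
#' repeats of `inner_folds`-fold CV; the curves are averaged and the penalty
#' minimising the averaged curve is selected (the averaged-curve reading of
#' the inner-loop rule). The model is refit on the full training set at that
#' penalty; the deviance ratio is recorded from the training fit and the
#' R-squared (or balanced accuracy, for `family = "binomial"`) from the
#' untouched test set. Test R-squared is `1 - SSE/SST` about the test mean
#' and may be negative.
#'
#' Repeats with a degenerate training response (zero variance, or a missing
#' class in classification) are skipped and flagged.
#'
#' @param X participants x features numeric matrix (complete, z-scaled).
#' @param y numeric response, or the values to binarise for classification.
#' @param plan a [make_split_plan()].
#' @param inner_repeats,inner_folds inner CV layout (default 10 x 5).
#' @param n_lambda,lambda_min_ratio lambda grid controls.
#' @param family `"gaussian"` or `"binomial"` (y must then be a 2-level
#'   factor).
#' @param seed integer seed for the inner fold draws.
#' @return list of class `lasso_fits`; each element carries `lambda_opt`,
#'   `coef`, `selected`, `dev_ratio`, `test_metric`, `ids_seen` (all ids that
#'   entered penalty selection; disjoint from `$test` by construction, and
#'   recorded so the property is checkable), and `skipped`.
#' @export
fit_lasso_nested <- function(X, y, plan, inner_repeats = 10, inner_folds = 5,
                             n_lambda = 100, lambda_min_ratio = 0.01,
                             family = c("gaussian", "binomial"), seed = 1L) {
  family <- match.arg(family)
  stopifnot(is.matrix(X), !is.null(rownames(X)), nrow(X) == length(y))
  if (family == "binomial") {
    y <- as.factor(y)
    if (nlevels(y) != 2)
      stop("classification requires exactly two classes overall", call. = FALSE)
  }
  names(y) <- rownames(X)
  fits <- withr::with_seed(seed, lapply(seq_along(plan), function(r) {
    tr <- plan[[r]]$train; te <- plan[[r]]$test
    ytr <- y[tr]
    degenerate <- if (family == "binomial") {
      length(unique(ytr)) < 2 || length(unique(y[te])) < 2
    } else {
      stats::sd(ytr) == 0
    }
    if (degenerate)
      return(list(skipped = TRUE, reason = "degenerate training/test response"))
    Xtr <- X[tr, , drop = FALSE]
    f0 <- glmnet::glmnet(Xtr, ytr, family = family, nlambda = n_lambda,
                         lambda.min.ratio = lambda_min_ratio)
    grid <- f0$lambda
    curve <- inner_cv_curve(Xtr, ytr, grid, inner_repeats, inner_folds, family)
    idx <- which.min(curve)
    beta <- stats::coef(f0, s = grid[idx])
    cf <- stats::setNames(as.numeric(beta)[-1], rownames(beta)[-1])
    n_correct <- NA_integer_
    if (family == "binomial") {
      pred <- stats::predict(f0, X[te, , drop = FALSE], s = grid[idx],
                             type = "class")
      pred <- factor(drop(pred), levels = levels(y))
      metric <- balanced_accuracy(y[te], pred)
      n_correct <- sum(pred == y[te])
    } else {
      pred <- stats::predict(f0, X[te, , drop = FALSE], s = grid[idx])
      metric <- test_r_squared(y[te], drop(pred))
    }
    list(skipped = FALSE,
         n_correct = n_correct,
         lambda_opt = grid[idx],
         coef = cf,
         selected = names(cf)[cf != 0],
         dev_ratio = f0$dev.ratio[idx],
         test_metric = metric,
         ids_seen = tr,
         test_ids = te)
  }))
  attr(fits, "family") <- family
  attr(fits, "features") <- colnames(X)
  class(fits) <- "lasso_fits"
  fits
}

# OOB error of a small forest at a given mtry (used by the tuner).
oob_error <- function(X, y, mtry, num_trees, seed, classification) {
  fit <- ranger::ranger(x = X, y = y, num.trees = num_trees, mtry = mtry,
                        seed = seed, num.threads = 1)
  fit$prediction.error
}

# tuneRF-style stepping: from the default mtry, multiply/divide by
# `step` while the relative OOB improvement exceeds `improve`.
tune_mtry <- function(X, y, step, improve, num_trees, seed, classification) {
  p <- ncol(X)
  m0 <- if (classification) max(1, floor(sqrt(p))) else max(1, floor(p / 3))
  best_m <- m0
  best_err <- oob_error(X, y, m0, num_trees, seed, classification)
  for (direction in c("left", "right")) {
    m <- m0; err <- best_err
    repeat {
      m_new <- if (direction == "left") max(1, floor(m / step))
               else min(p, ceiling(m * step))
      if (m_new == m) break
      err_new <- oob_error(X, y, m_new, num_trees, seed + m_new, classification)
      gain <- if (err > 0) (err - err_new) / err else 0
      if (is.na(gain) || gain <= improve) break
      m <- m_new; err <- err_new
      if (err < best_err) { best_err <- err; best_m <- m }
    }
  }
  best_m
}

#' Random forests over a split plan with OOB-tuned mtry
#'
#' Per outer repeat: `mtry` is tuned on the training set only, by stepping
#' away from the default (multiply/divide by `mtry_step`) while the relative
#' out-of-bag improvement exceeds `mtry_improve` (the tuning forests use
#' `tune_trees` trees, the tuner's customary small default); the final
#' forest uses `n_trees` trees and records scaled permutation importance
#' (the \%IncMSE analogue; mean decrease in accuracy for classification),
#' OOB explained variance (or OOB accuracy), and the test R-squared (or
#' balanced accuracy).
#'
#' @param X participants x features matrix.
#' @param y numeric response or 2-level factor (classification).
#' @param plan a [make_split_plan()] (the same plan as the LASSO).
#' @param n_trees trees in the final forest (default 1000; below 100 the
#'   permutation importance is unstable and a warning is given).
#' @param mtry_step,mtry_improve tuning step factor and relative-improvement
#'   stop rule (defaults 1.5 and 0.01).
#' @param tune_trees trees per tuning forest (default 50).
#' @param seed integer seed.
#' @return list of class `forest_fits`; per repeat: `mtry`, `importance`
#'   (named, covering all features), `oob_metric` (explained variance or
#'   accuracy), `test_metric`, `ids_seen`, `skipped`.
#' @export
fit_forest <- function(X, y, plan, n_trees = 1000, mtry_step = 1.5,
                       mtry_improve = 0.01, tune_trees = 50, seed = 1L) {
  stopifnot(is.matrix(X), !is.null(rownames(X)), nrow(X) == length(y))
  if (n_trees < 100)
    warning("n_trees < 100: permutation importance will be unstable",
            call. = FALSE)
  classification <- is.factor(y)
  names(y) <- rownames(X)
  fits <- lapply(seq_along(plan), function(r) {
    tr <- plan[[r]]$train; te <- plan[[r]]$test
    ytr <- y[tr]
    degenerate <- if (classification) {
      length(unique(ytr)) < 2 || length(unique(y[te])) < 2
    } else {
      stats::sd(ytr) == 0
    }
    if (degenerate)
      return(list(skipped = TRUE, reason = "degenerate training/test response"))
    Xtr <- X[tr, , drop = FALSE]
    rs <- derive_seed(seed, r)
    ytr_fit <- if (classification) droplevels(ytr) else ytr
    m <- tune_mtry(Xtr, ytr_fit, mtry_step, mtry_improve, tune_trees,
                   rs, classification)
    fit <- ranger::ranger(x = Xtr, y = ytr_fit, num.trees = n_trees,
                          mtry = m, importance = "permutation",
                          scale.permutation.importance = TRUE,
                          seed = rs, num.threads = 1)
    pred <- stats::predict(fit, data = X[te, , drop = FALSE],
                           num.threads = 1)$predictions
    if (classification) {
      oob <- 1 - fit$prediction.error
      metric <- balanced_accuracy(y[te], pred)
    } else {
      oob <- fit$r.squared
      metric <- test_r_squared(y[te], pred)
    }
    imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
    imp[names(fit$variable.importance)] <- fit$variable.importance
    list(skipped = FALSE, mtry = m, importance = imp, oob_metric = oob,
         test_metric = metric, ids_seen = tr, test_ids = te)
  })
  attr(fits, "classification") <- classification
  attr(fits, "features") <- colnames(X)
  class(fits) <- "forest_fits"
  fits
}

#' Avidity (W1) classification with both methods
#'
#' Dichotomises W1 at `threshold` (W1 < threshold is labelled
#' `labels[1]`, the source workflow's literal "high-avidity" assignment;
#' the labels are arguments because the opposite reading also circulates)
#' and fits the penalised logistic LASSO and the classification forest over
#' the same plan. Repeats whose training or test set lacks a class are
#' skipped.
#'
#' @param X participants x features matrix.
#' @param w1 numeric W1 values, aligned with `rownames(X)`.
#' @param plan a [make_split_plan()].
#' @param threshold class boundary (default 5).
#' @param labels class labels for `W1 < threshold` and `W1 >= threshold`.
#' @param ... passed to [fit_lasso_nested()] and [fit_forest()]
#'   (`inner_repeats`, `n_trees`, `seed`, ...).
#' @return list with elements `lasso` and `forest`.
#' @export
fit_w1_classifiers <- function(X, w1, plan, threshold = 5,
                               labels = c("high_avidity", "low_avidity"),
                               inner_repeats = 10, inner_folds = 5,
                               n_lambda = 100, n_trees = 1000,
                               mtry_step = 1.5, mtry_improve = 0.01,
                               tune_trees = 50, seed = 1L) {
  stopifnot(length(w1) == nrow(X))
  cls <- factor(ifelse(w1 < threshold, labels[1], labels[2]), levels = labels)
  if (nlevels(droplevels(cls)) < 2)
    stop("only one avidity class present at threshold ", threshold,
         call. = FALSE)
  list(lasso = fit_lasso_nested(X, cls, plan, inner_repeats = inner_repeats,
                                inner_folds = inner_folds, n_lambda = n_lambda,
                                family = "binomial", seed = seed),
       forest = fit_forest(X, cls, plan, n_trees = n_trees,
                           mtry_step = mtry_step, mtry_improve = mtry_improve,
                           tune_trees = tune_trees, seed = seed))
}

#' Summarise paired LASSO / forest fits and apply the predictability gates
#'
#' Regression: predictable iff the mean LASSO deviance ratio reaches
#' `dev_ratio_gate` or the mean forest OOB explained variance reaches
#' `var_explained_gate` (the either-method rule). Classification:
#' predictable iff the mean balanced accuracy (best method) is strictly
#' above `balanced_acc_gate`. Skipped repeats are excluded from all means.
#'
#' @param lasso a `lasso_fits`.
#' @param forest a `forest_fits` over the same plan.
#' @param dev_ratio_gate,var_explained_gate,balanced_acc_gate gate values.
#' @return list of class `model_summary`: means, `predictable`,
#'   `selection_count` (outer repeats with a nonzero LASSO coefficient, per
#'   feature), `importance` (mean forest importance per feature), and repeat
#'   bookkeeping.
#' @export
summarize_models <- function(lasso, forest, dev_ratio_gate = 0.5,
                             var_explained_gate = 0.5,
                             balanced_acc_gate = 0.5) {
  stopifnot(inherits(lasso, "lasso_fits"), inherits(forest, "forest_fits"))
  features <- attr(lasso, "features")
  stopifnot(identical(features, attr(forest, "features")))
  classification <- attr(lasso, "family") == "binomial"
  lok <- !vapply(lasso, `[[`, logical(1), "skipped")
  fok <- !vapply(forest, `[[`, logical(1), "skipped")
  if (!any(lok) || !any(fok))
    stop("no successful repeat to summarise", call. = FALSE)
  mean_of <- function(fits, ok, field)
    mean(vapply(fits[ok], `[[`, numeric(1), field), na.rm = TRUE)

  dev_ratio <- mean_of(lasso, lok, "dev_ratio")
  lasso_metric <- mean_of(lasso, lok, "test_metric")
  rf_oob <- mean_of(forest, fok, "oob_metric")
  rf_metric <- mean_of(forest, fok, "test_metric")

  sel <- stats::setNames(rep(0L, length(features)), features)
  for (f in lasso[lok]) sel[f$selected] <- sel[f$selected] + 1L
  imp <- rowMeans(vapply(forest[fok], `[[`, numeric(length(features)),
                         "importance"))
  names(imp) <- features

  predictable <- if (classification) {
    max(lasso_metric, rf_metric) > balanced_acc_gate
  } else {
    dev_ratio >= dev_ratio_gate || rf_oob >= var_explained_gate
  }
  structure(list(classification = classification,
                 dev_ratio = dev_ratio,
                 lasso_test = lasso_metric,
                 rf_oob = rf_oob,
                 rf_test = rf_metric,
                 predictable = predictable,
                 selection_count = sel,
                 importance = imp,
                 n_repeats = length(lasso),
                 n_used_lasso = sum(lok),
                 n_used_forest = sum(fok)),
            class = "model_summary")
}
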