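make_xy <- function(n = 60, p = 30, informative = 3, noise = 0, seed = 71) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("p%02d", 1:n), sprintf("f%02d", 1:p)))
    beta <- rep(0, p); beta[seq_len(informative)] <- 2
    y <- drop(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y, true = colnames(X)[seq_len(informative)])
  })
}

test_that("split plans are disjoint, exhaustive, sized, and reproducible", {
  ids <- sprintf("p%03d", 1:100)
  plan <- make_split_plan(ids, outer_repeats = 20, test_frac = 0.2, seed = 5)
  expect_length(plan, 20)
  for (s in plan) {
    expect_length(s$test, 20)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), ids)
  }
  plan2 <- make_split_plan(ids, outer_repeats = 20, test_frac = 0.2, seed = 5)
  expect_identical(plan, plan2)
  expect_error(make_split_plan(ids, 5, test_frac = 0.001), "empty")
})

test_that("balanced accuracy follows the confusion-matrix arithmetic", {
  # TP=8 FN=2 TN=5 FP=5 -> (0.8 + 0.5)/2 = 0.65
  truth <- c(rep("pos", 10), rep("neg", 10))
  pred <- c(rep("pos", 8), rep("neg", 2), rep("pos", 5), rep("neg", 5))
  expect_equal(balanced_accuracy(truth, pred), 0.65)
  expect_equal(balanced_accuracy(truth, truth), 1)
})

test_that("noiseless planted signal gives R2 ~ 1 with true support recovered", {
  d <- make_xy(noise = 0)
  plan <- make_split_plan(rownames(d$X), 10, 0.2, seed = 6)
  fits <- fit_lasso_nested(d$X, d$y, plan, inner_repeats = 3, seed = 6)
  r2 <- vapply(fits, `[[`, numeric(1), "test_metric")
  expect_gte(mean(r2), 0.99)
  hit <- vapply(fits, function(f) all(d$true %in% f$selected), logical(1))
  expect_true(all(hit))
  # dev ratio ~ 1 on a perfect fit
  expect_gt(mean(vapply(fits, `[[`, numeric(1), "dev_ratio")), 0.95)
})

test_that("no test id ever enters penalty selection or tuning", {
  d <- make_xy(noise = 1)
  plan <- make_split_plan(rownames(d$X), 8, 0.2, seed = 7)
  lf <- fit_lasso_nested(d$X, d$y, plan, inner_repeats = 2, seed = 7)
  ff <- fit_forest(d$X, d$y, plan, n_trees = 100, seed = 7)
  for (i in seq_along(plan)) {
    expect_length(intersect(lf[[i]]$ids_seen, plan[[i]]$test), 0)
    expect_length(intersect(ff[[i]]$ids_seen, plan[[i]]$test), 0)
  }
})

test_that("degenerate training responses are skipped, not fit", {
  d <- make_xy(noise = 1)
  plan <- make_split_plan(rownames(d$X), 3, 0.2, seed = 8)
  y_const <- rep(1, nrow(d$X))
  fits <- fit_lasso_nested(d$X, y_const, plan, inner_repeats = 2, seed = 8)
  expect_true(all(vapply(fits, `[[`, logical(1), "skipped")))
  ff <- fit_forest(d$X, y_const, plan, n_trees = 100, seed = 8)
  expect_true(all(vapply(ff, `[[`, logical(1), "skipped")))
  expect_error(summarize_models(fits, ff), "no successful repeat")
})

test_that("forests rank a planted feature above noise and are seed-stable", {
  d <- make_xy(n = 80, p = 20, informative = 1, noise = 0.5, seed = 72)
  plan <- make_split_plan(rownames(d$X), 5, 0.2, seed = 9)
  ff <- fit_forest(d$X, d$y, plan, n_trees = 300, seed = 9)
  for (f in ff) expect_equal(names(which.max(f$importance)), "f01")
  ff2 <- fit_forest(d$X, d$y, plan, n_trees = 300, seed = 9)
  expect_identical(lapply(ff, `[[`, "importance"),
                   lapply(ff2, `[[`, "importance"))
  expect_warning(fit_forest(d$X, d$y, plan[1], n_trees = 50, seed = 9),
                 "unstable")
})

test_that("W1 classifiers separate separable classes and respect the labels", {
  withr::with_seed(73, {
    n <- 60
    w1 <- c(runif(n / 2, 1, 4), runif(n / 2, 6, 9))
    X <- cbind(sig = (w1 >= 5) * 3 + rnorm(n, 0, 0.3),
               matrix(rnorm(n * 10), n, 10))
    colnames(X)[-1] <- paste0("n", 1:10)
    rownames(X) <- sprintf("p%02d", 1:n)
  })
  plan <- make_split_plan(rownames(X), 5, 0.2, seed = 10)
  fits <- fit_w1_classifiers(X, w1, plan, threshold = 5, inner_repeats = 2,
                             n_trees = 200, seed = 10)
  s <- summarize_models(fits$lasso, fits$forest)
  expect_true(s$classification)
  expect_gte(s$lasso_test, 0.95)
  expect_gte(s$rf_test, 0.95)
  expect_true(s$predictable)
  expect_error(fit_w1_classifiers(X, rep(1, n), plan), "one avidity class")
})

test_that("predictability gates follow the 50% either-method rules", {
  mk_lasso <- function(devs) {
    fits <- lapply(devs, function(d)
      list(skipped = FALSE, dev_ratio = d, test_metric = 0.4,
           selected = "f1", coef = c(f1 = 1)))
    attr(fits, "family") <- "gaussian"
    attr(fits, "features") <- c("f1", "f2")
    class(fits) <- "lasso_fits"
    fits
  }
  mk_forest <- function(oobs) {
    fits <- lapply(oobs, function(o)
      list(skipped = FALSE, oob_metric = o, test_metric = 0.4,
           importance = c(f1 = 1, f2 = 0)))
    attr(fits, "classification") <- FALSE
    attr(fits, "features") <- c("f1", "f2")
    class(fits) <- "forest_fits"
    fits
  }
  expect_false(summarize_models(mk_lasso(c(0.49, 0.49)),
                                mk_forest(c(0.49, 0.49)))$predictable)
  expect_true(summarize_models(mk_lasso(c(0.8, 0.8)),
                               mk_forest(c(0.2, 0.2)))$predictable)
  expect_true(summarize_models(mk_lasso(c(0.2, 0.2)),
                               mk_forest(c(0.6, 0.6)))$predictable)
  # selection counts accumulate over repeats
  s <- summarize_models(mk_lasso(c(0.8, 0.8)), mk_forest(c(0.2, 0.2)))
  expect_equal(s$selection_count, c(f1 = 2L, f2 = 0L))

  # classification: balanced accuracy exactly at the gate is not predictable
  mk_cl <- function(bas, family = "binomial") {
    fits <- lapply(bas, function(b)
      list(skipped = FALSE, dev_ratio = 0.9, test_metric = b, selected = "f1",
           n_correct = 1))
    attr(fits, "family") <- family
    attr(fits, "features") <- c("f1", "f2")
    class(fits) <- "lasso_fits"
    fits
  }
  mk_clf <- function(bas) {
    fits <- lapply(bas, function(b)
      list(skipped = FALSE, oob_metric = b, test_metric = b,
           importance = c(f1 = 1, f2 = 0)))
    attr(fits, "classification") <- TRUE
    attr(fits, "features") <- c("f1", "f2")
    class(fits) <- "forest_fits"
    fits
  }
  expect_false(summarize_models(mk_cl(c(0.5, 0.5)), mk_clf(c(0.5, 0.5)))$predictable)
  expect_true(summarize_models(mk_cl(c(0.7, 0.7)), mk_clf(c(0.5, 0.5)))$predictable)
})
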