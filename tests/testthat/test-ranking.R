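test_that("cluster correction averages within clusters and preserves sums", {
  cl <- data.frame(feature = c("a", "b", "c", "d"),
                   cluster = c(1, 1, 2, 3),
                   representative = c(TRUE, FALSE, TRUE, TRUE))
  imp <- c(a = 4, b = 2, c = 7, d = 0)
  out <- correct_importances(imp, cl)
  expect_equal(out, c(a = 3, b = 3, c = 7, d = 0))
  # per-cluster sums preserved exactly
  for (k in unique(cl$cluster)) {
    mem <- cl$feature[cl$cluster == k]
    expect_equal(sum(out[mem]), sum(imp[mem]), tolerance = 1e-12)
  }
  expect_error(correct_importances(c(z = 1), cl), "absent")
})

test_that("dense ranks are gapless, tie-sharing, and match the sort oracle", {
  expect_equal(dense_rank(c(5, 5, 3)), c(1L, 1L, 2L))
  expect_equal(dense_rank(c(2, 2, 2)), c(1L, 1L, 1L))
  expect_equal(dense_rank(c(1, 3, 2), descending = FALSE), c(1L, 3L, 2L))
  set.seed(81)
  for (rep in 1:100) {
    v <- sample(0:5, sample(3:12, 1), replace = TRUE) + 0
    expect_identical(dense_rank(v), oracle_dense_rank(v))
    expect_identical(sort(unique(dense_rank(v))),
                     seq_along(unique(v)))
  }
})

test_that("rank aggregation averages and standardises to mean 0 / sd 1", {
  l <- c(a = 1L, b = 2L, c = 3L)
  r <- c(a = 3L, b = 2L, c = 1L)
  out <- aggregate_ranks(l, r)
  expect_equal(out$combined, c(2, 2, 2))
  out2 <- aggregate_ranks(l, c(a = 1L, b = 2L, c = 3L))
  expect_lt(abs(mean(out2$standardized)), 1e-10)
  expect_lt(abs(sqrt(mean(out2$standardized^2)) - 1), 1e-10)
  # identical rankings -> standardized equals the z-scored rank vector
  z <- (l - mean(l)) / sqrt(mean((l - mean(l))^2))
  expect_equal(out2$standardized, as.numeric(z))
  expect_error(aggregate_ranks(l, c(a = 1L, x = 2L, c = 3L)), "universes")
})

test_that("rank agreement hits the Spearman extremes and the null", {
  l <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(rank_agreement(l, l), 1)
  expect_equal(rank_agreement(l, rev(4:1) * 0 + c(a = 4, b = 3, c = 2, d = 1)), -1)
  expect_warning(out <- rank_agreement(l, c(a = 1, b = 1, c = 1, d = 1)),
                 "constant")
  expect_true(is.na(out))
  set.seed(82)
  rhos <- replicate(100, {
    a <- setNames(sample(100), paste0("f", 1:100))
    b <- setNames(sample(100), paste0("f", 1:100))
    rank_agreement(a, b)
  })
  expect_gte(mean(abs(rhos) < 0.3), 0.95)
})

test_that("correction precedes ranking and is order invariant end to end", {
  set.seed(83)
  feats <- paste0("f", 1:10)
  cl <- data.frame(feature = feats,
                   cluster = c(1, 1, 2:9),
                   representative = c(TRUE, FALSE, rep(TRUE, 8)))
  imp <- setNames(rpois(10, 5) + 0, feats)
  sel <- setNames(rpois(10, 3) + 0, feats)
  mk <- function(ord) {
    s <- structure(list(classification = FALSE,
                        selection_count = sel[ord], importance = imp[ord]),
                   class = "model_summary")
    rank_predictors(s, cl)
  }
  a <- mk(feats)
  b <- mk(rev(feats))
  b <- b[match(a$predictor, b$predictor), ]
  expect_equal(a$combined, b$combined)
  # singleton-only map leaves values unchanged
  cl1 <- data.frame(feature = feats, cluster = 1:10,
                    representative = TRUE)
  expect_identical(correct_importances(imp, cl1), imp)
})

test_that("top-k unions: identical lists collapse, disjoint lists add", {
  mk_ranking <- function(perm) {
    data.frame(predictor = paste0("f", perm),
               lasso_rank = seq_along(perm), rf_rank = seq_along(perm),
               combined = seq_along(perm),
               standardized = scale(seq_along(perm))[, 1])
  }
  same <- list("a|t1" = mk_ranking(1:10), "b|t1" = mk_ranking(1:10))
  u <- top_k_union(same, k = 3)
  expect_length(u$predictors, 3)
  expect_true(all(u$counts == 2))
  disj <- list("a|t1" = mk_ranking(1:10), "b|t1" = mk_ranking(c(6:10, 1:5)))
  u2 <- top_k_union(disj, k = 3)
  expect_length(u2$predictors, 6)
  expect_equal(dim(u2$membership), c(6L, 2L))
  expect_error(top_k_union(same, k = 0), "k must be")
})
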