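test_that("probe collapse keeps the max-mean probe per gene", {
  expr <- rbind(p1 = c(7, 7.4), p2 = c(5, 5), p3 = c(1, 2), p4 = c(9, 9))
  colnames(expr) <- c("s1", "s2")
  ann <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                    symbol = c("G", "G", "H", NA))
  out <- collapse_probes(expr, ann)
  expect_equal(rownames(out), c("G", "H"))
  expect_equal(out["G", ], expr["p1", ])   # 7.2 > 5.0
  expect_equal(out["H", ], expr["p3", ])   # single probe unchanged
  expect_false("p4" %in% rownames(out))    # no symbol -> dropped
  expect_error(collapse_probes(expr, data.frame(probe = "x", symbol = "Y")),
               "overlap")
})

test_that("probe collapse matches a brute-force argmax on random instances", {
  set.seed(21)
  for (rep in 1:20) {
    n_probe <- sample(5:12, 1)
    expr <- matrix(rnorm(n_probe * 4), n_probe, 4,
                   dimnames = list(paste0("p", 1:n_probe), paste0("s", 1:4)))
    ann <- data.frame(probe = rownames(expr),
                      symbol = sample(c("A", "B", "C"), n_probe, replace = TRUE))
    out <- collapse_probes(expr, ann)
    for (g in unique(ann$symbol)) {
      probes <- ann$probe[ann$symbol == g]
      best <- probes[which.max(rowMeans(expr[probes, , drop = FALSE]))]
      expect_equal(out[g, ], expr[best, ], ignore_attr = TRUE)
    }
    expect_lte(nrow(out), length(unique(ann$symbol)))
  }
})

test_that("IQR filter uses strict > with type-7 quantiles and is idempotent", {
  m <- rbind(const = rep(1, 4),
             ramp = c(1, 2, 3, 4),        # type-7 IQR = 1.5
             edge = c(0, 0.25, 0.5, 0.75)) # type-7 IQR = 0.375
  colnames(m) <- paste0("s", 1:4)
  out <- iqr_filter(m, 0.75)
  expect_equal(rownames(out), "ramp")
  # boundary: IQR exactly at the threshold is removed
  m2 <- rbind(x = c(1, 2, 3, 4))
  colnames(m2) <- paste0("s", 1:4)
  expect_equal(nrow(iqr_filter(m2, 1.5)), 0)
  # brute-force type-7 quantile check for the kept row
  xs <- sort(c(1, 2, 3, 4))
  q <- function(p) { h <- (4 - 1) * p + 1
                     xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)]) }
  expect_equal(q(0.75) - q(0.25), 1.5)
  expect_identical(iqr_filter(out, 0.75), out)
})

test_that("LOQ imputation respects truncation bounds and the truncated mean", {
  vals <- matrix(c(0.5, 3, 2, 8), 2, 2,
                 dimnames = list(c("IL6", "total_Ig"), c("p1", "p2")))
  spec <- data.frame(analyte = c("IL6", "total_Ig"), unit = c("pg/mL", "mIU/mL"),
                     log2_mean = 0, log2_sd = 1, resp_shift = 0,
                     threshold = c(0.822, 6.2))
  panel <- structure(list(values = vals,
                          censored = matrix(FALSE, 2, 2, dimnames = dimnames(vals)),
                          thresholds = setNames(spec$threshold, spec$analyte),
                          units = setNames(spec$unit, spec$analyte)),
                     class = "analyte_panel")
  panel <- apply_censoring(panel)
  expect_true(panel$censored["IL6", "p1"])     # 0.5 < 0.822
  expect_true(panel$censored["total_Ig", "p1"])# 2 < 6.2
  suppressMessages(imp <- impute_below_loq(panel, seed = 2))
  expect_true(imp$values["IL6", "p1"] > 0 && imp$values["IL6", "p1"] <= 0.822)
  expect_true(imp$values["total_Ig", "p1"] >= 1 &&
              imp$values["total_Ig", "p1"] <= 6.2)
  suppressMessages(imp2 <- impute_below_loq(panel, seed = 2))
  expect_identical(imp$values, imp2$values)

  # empirical mean over 1e4 draws matches the numerically integrated
  # truncated-normal mean within 3 SE, for both truncation regimes
  for (thr in c(6.2, 0.822)) {
    lower <- if (thr > 1) 1 else 0
    big <- matrix(rep(thr / 10, 1e4), 1, dimnames = list("A", paste0("p", 1:1e4)))
    pn <- structure(list(values = big,
                         censored = matrix(TRUE, 1, 1e4, dimnames = dimnames(big)),
                         thresholds = c(A = thr), units = c(A = "pg/mL")),
                    class = "analyte_panel")
    suppressMessages(draws <- impute_below_loq(pn, seed = 3)$values)
    m_oracle <- oracle_truncnorm_mean(thr / 2, 1, lower, thr)
    expect_lt(abs(mean(draws) - m_oracle), 3 * sd(draws) / sqrt(length(draws)))
    expect_true(all(draws >= lower & draws <= thr))
  }
})

test_that("log fold change is the difference of log values", {
  pre <- matrix(c(1, 2, 3, 4), 2, 2,
                dimnames = list(c("a", "b"), c("p1", "p2")))
  post <- pre + c(2, 0)
  expect_equal(log_fold_change(post, pre), post - pre)
  expect_true(all(log_fold_change(pre, pre) == 0))
  post2 <- cbind(post, p3 = c(1, 1))
  expect_warning(out <- log_fold_change(post2, pre), "p3")
  expect_equal(colnames(out), c("p1", "p2"))
  expect_error(log_fold_change(post, `colnames<-`(pre, c("x", "y"))),
               "no participant")
})

test_that("scaling rules: log10, log2, reverse, and errors", {
  m <- rbind(serology = c(100, 1000), cytokine = c(8, 2), W1 = c(4, 6))
  colnames(m) <- c("p1", "p2")
  rules <- c(serology = "log10", cytokine = "log2", W1 = "reverse")
  out <- scale_features(m, rules)
  expect_equal(out["serology", ], c(p1 = 2, p2 = 3))
  expect_equal(out["cytokine", ], c(p1 = 3, p2 = 1))
  expect_equal(out["W1", ], c(p1 = -4, p2 = -6))
  m2 <- m; m2["serology", 1] <- -1
  expect_error(scale_features(m2, rules), "serology")
  expect_error(scale_features(m, c(rules[-1])), "no scaling rule")
})

test_that("participant filter drops strictly above the threshold", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("f", 1:10), paste0("p", 1:4)))
  m[1:6, 1] <- NA  # 60% missing
  m[1:5, 2] <- NA  # exactly 50%
  suppressMessages(out <- filter_participants(m, 0.5))
  expect_equal(colnames(out), c("p2", "p3", "p4"))
  expect_equal(attr(out, "dropped"), "p1")
  m[] <- NA
  expect_error(filter_participants(m, 0.5), "every participant")
})

test_that("KNN imputation: identity, single-neighbour case, symmetry", {
  m <- matrix(rnorm(30), 5, 6,
              dimnames = list(paste0("f", 1:5), paste0("p", 1:6)))
  expect_identical(knn_impute(m, 2), m)

  # 3 participants, one missing cell, k = 1 -> value of the nearest
  m3 <- cbind(p1 = c(0, 0, NA), p2 = c(0.1, 0.1, 5), p3 = c(4, 4, 9))
  rownames(m3) <- paste0("f", 1:3)
  expect_equal(knn_impute(m3, 1)["f3", "p1"], 5)  # p2 is nearest

  # duplicated participant, k = 2: weights exp(0) for the duplicate dominate
  m4 <- cbind(p1 = c(1, 2, NA), p2 = c(1, 2, 7), p3 = c(1, 2, 7), p4 = c(50, 60, 1))
  rownames(m4) <- paste0("f", 1:3)
  expect_equal(knn_impute(m4, 2)["f3", "p1"], 7)

  expect_error(knn_impute(m3, 5), "fewer than k")
})

test_that("KNN imputation agrees with the exhaustive oracle on small tables", {
  set.seed(31)
  for (rep in 1:15) {
    nf <- sample(4:10, 1); np <- sample(5:10, 1)
    m <- matrix(rnorm(nf * np), nf, np,
                dimnames = list(paste0("f", 1:nf), paste0("p", 1:np)))
    m[sample(length(m), round(0.1 * length(m)))] <- NA
    # keep every feature observed enough for k
    k <- 2
    if (any(rowSums(!is.na(m)) < k)) next
    expect_equal(knn_impute(m, k), oracle_knn_impute(m, k), tolerance = 1e-12)
  }
})

test_that("integration keeps innate participants, z-scales, and completes", {
  set.seed(41)
  innate <- matrix(rnorm(60), 6, 10,
                   dimnames = list(paste0("i", 1:6), paste0("p", 1:10)))
  antibody <- matrix(rnorm(33), 3, 11,
                     dimnames = list(paste0("a", 1:3), paste0("p", 1:11)))
  antibody[1, 2] <- NA
  out <- integrate_features(innate, antibody, knn_k = 3)
  expect_false("p11" %in% colnames(out))   # antibody-only participant absent
  expect_false(anyNA(out))
  # z-scaling holds exactly for fully observed features
  complete_feats <- setdiff(rownames(out), "a1")
  expect_true(all(abs(rowMeans(out[complete_feats, ])) < 1e-10))
  expect_true(all(abs(apply(out[complete_feats, ], 1, sd) - 1) < 1e-10))
  expect_error(integrate_features(innate,
                                  `colnames<-`(antibody, paste0("q", 1:11))),
               "share no participants")
})
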