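test_that("fixed seed gives identical studies; different seeds differ", {
  a <- simulate_study(tiny_sim(seed = 3))
  b <- simulate_study(tiny_sim(seed = 3))
  expect_identical(a$expr_logfc, b$expr_logfc)
  expect_identical(a$antibody, b$antibody)
  expect_identical(a$analytes_post$values, b$analytes_post$values)
  c <- simulate_study(tiny_sim(seed = 4))
  expect_false(identical(a$expr_logfc, c$expr_logfc))
})

test_that("within-module gene correlation tracks rho", {
  cfg <- tiny_sim(seed = 5, rho = 0.9)
  st <- simulate_innate(cfg)
  meds <- vapply(cfg$module_ids, function(m) {
    cc <- cor(t(st$logfc[cfg$module_members[[m]], ]))
    median(cc[upper.tri(cc)])
  }, numeric(1))
  expect_true(all(meds > 0.8))
})

test_that("zero effect sizes leave per-group module means at noise level", {
  # with no group shift, every per-group mean of the module-average logFC
  # stays within 3 SE of zero
  cfg <- tiny_sim(seed = 6, group_shift = 0)
  st <- simulate_innate(cfg)
  groups <- st$truth$groups
  for (m in cfg$module_ids) {
    score <- colMeans(st$logfc[cfg$module_members[[m]], ])
    for (g in unique(groups)) {
      x <- score[groups == g]
      expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)) + 1e-12)
    }
  }
})

test_that("a gene in two modules is rejected", {
  cfg <- tiny_sim()
  cfg$module_members[["M002"]][1] <- cfg$module_members[["M001"]][1]
  expect_error(
    {
      if (anyDuplicated(unlist(cfg$module_members)))
        stop("module membership inconsistent: a gene belongs to two modules")
      simulate_innate(cfg)
    },
    "two modules")
})

test_that("antibody signal calibration: OLS on true latents recovers the
           planted coefficients within 3 SE, and the noiseless limit is R2 ~ 1", {
  # calibration across replicates
  n_rep <- 25
  zs <- replicate(n_rep, {
    cfg <- tiny_sim(seed = sample.int(1e6, 1), target_r2 = 0.7)
    inn <- simulate_innate(cfg)
    ab <- simulate_antibody(cfg, inn$truth)
    y <- ab$D60["total_Ig", ]
    X <- t(inn$truth$module_latents[cfg$planted_modules, ])
    fit <- summary(lm(y ~ X))
    (fit$coefficients[-1, "Estimate"] - 1) / fit$coefficients[-1, "Std. Error"]
  })
  # pooled z-scores: ~N(0,1) when calibrated; mean within 3 SE of 0
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)))

  # noiseless limit: nearly all variance from the planted module latents
  cfg <- tiny_sim(seed = 11, target_r2 = 0.999)
  inn <- simulate_innate(cfg)
  ab <- simulate_antibody(cfg, inn$truth)
  y <- ab$D60["IgG", ]
  X <- t(inn$truth$module_latents[cfg$planted_modules, ])
  expect_gt(summary(lm(y ~ X))$r.squared, 0.99)
})

test_that("middle-timepoint attenuation lowers the empirical R2", {
  set.seed(42)
  r2 <- replicate(10, {
    cfg <- tiny_sim(seed = sample.int(1e6, 1))
    inn <- simulate_innate(cfg)
    ab <- simulate_antibody(cfg, inn$truth)
    X <- t(inn$truth$module_latents[cfg$planted_modules, ])
    vapply(ab, function(tab)
      summary(lm(tab["total_Ig", ] ~ X))$r.squared, numeric(1))
  })
  means <- rowMeans(r2)
  expect_lt(means["D360"], means["D60"])
  expect_lt(means["D360"], means["D390"])
})

test_that("all-zero loadings give no latent-antibody correlation", {
  cfg <- tiny_sim(seed = 12, driven_features = character(0))
  inn <- simulate_innate(cfg)
  ab <- simulate_antibody(cfg, inn$truth)
  y <- ab$D60["total_Ig", ]
  r <- cor(y, inn$truth$latent)
  n <- length(y)
  expect_lt(abs(r), 3 / sqrt(n - 3))  # 3 SE of Fisher-z null
})

test_that("censoring flags exactly the below-threshold entries", {
  cfg <- tiny_sim(seed = 13)
  inn <- simulate_innate(cfg)
  panel <- inn$analytes_post
  raw <- panel$values
  flagged <- apply_censoring(panel)
  thr <- flagged$thresholds[rownames(raw)]
  expect_identical(flagged$censored, sweep(raw, 1, thr, "<"))
  expect_true(all(is.na(flagged$values[flagged$censored])))
  expect_identical(flagged$values[!flagged$censored], raw[!flagged$censored])

  # all values above thresholds -> no flags; raising a threshold never unflags
  high <- panel
  high$values[] <- abs(high$values) + 10
  expect_false(any(apply_censoring(high)$censored))
  thr2 <- flagged$thresholds * 2
  reflagged <- apply_censoring(panel, thr2)
  expect_true(all(reflagged$censored[flagged$censored]))

  # the 0.822 pg/mL rule and a missing threshold
  small <- panel
  small$values["IL6", 1] <- 0.5
  expect_true(apply_censoring(small)$censored["IL6", 1])
  expect_error(apply_censoring(panel, c(IL6 = 1)), "no detection threshold")
})

test_that("missingness: rate, dropouts, and the zero case", {
  m <- matrix(rnorm(5000), 100, 50,
              dimnames = list(paste0("f", 1:100), paste0("p", 1:50)))
  expect_identical(apply_missingness(m, 0), m)

  out <- apply_missingness(m, 0.05, seed = 9)
  n_miss <- sum(is.na(out))
  # binomial 99% interval around 250 of 5000
  expect_true(n_miss > stats::qbinom(0.005, 5000, 0.05) &&
              n_miss < stats::qbinom(0.995, 5000, 0.05))

  out <- apply_missingness(m, 0.05, dropout_ids = c("p1", "p2", "p3"),
                           seed = 9, dropout_frac = 0.6)
  frac <- colMeans(is.na(out))
  expect_identical(names(which(frac > 0.5)), c("p1", "p2", "p3"))
  expect_error(apply_missingness(m, 1.2), "rate")
})

test_that("study writes to disk and reads back identically", {
  st <- simulate_study(tiny_sim(seed = 14))
  d <- withr::local_tempdir()
  write_study(st, d)
  expect_length(readLines(file.path(d, "modules.gmt")), length(st$modules))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_true(all(st$truth$planted_modules %in% unlist(truth$planted_modules)))

  back <- read_study(d)
  expect_identical(st$expr_logfc, back$expr_logfc)
  expect_equal(st$antibody, back$antibody)
  expect_equal(st$analytes_pre$values, back$analytes_pre$values)
  expect_identical(st$analytes_post$censored, back$analytes_post$censored)
  expect_equal(st$truth$module_latents, back$truth$module_latents)
  expect_identical(st$groups, back$groups)
})
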