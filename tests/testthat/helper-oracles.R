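# Independent, literal oracle implementations used to cross-check the
# package's vectorised code. Deliberately written as plain loops straight
# from the published formula descriptions; slow but unambiguous.

# Per-sample gene-set variation score, step by step:
# gene-wise Gaussian-kernel ECDF (bandwidth sd/4), sample-wise symmetric
# rank statistic |p/2 - rank|, weighted KS walk, max.diff score.
oracle_gsva <- function(expr, sets, tau = 1) {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) {
    h <- sd(expr[i, ]) / 4
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + pnorm((expr[i, j] - expr[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rk <- integer(p); rk[ord] <- seq_len(p)
    for (si in seq_along(sets)) {
      inset <- rownames(expr) %in% sets[[si]]
      denom_in <- 0
      for (i in seq_len(p)) if (inset[i]) denom_in <- denom_in + abs(p / 2 - rk[i])^tau
      denom_out <- p - sum(inset)
      v <- numeric(p); cum_in <- 0; cum_out <- 0
      for (pos in seq_len(p)) {
        gene <- ord[pos]
        if (inset[gene]) cum_in <- cum_in + abs(p / 2 - rk[gene])^tau
        else cum_out <- cum_out + 1
        v[pos] <- cum_in / denom_in - cum_out / denom_out
      }
      out[si, j] <- max(0, max(v)) + min(0, min(v))
    }
  }
  out
}

# Exhaustive KNN imputation: for each missing cell, scan all other
# participants, order by Euclidean distance over co-observed features,
# take the k nearest observing the feature, weight by exp(-d).
oracle_knn_impute <- function(mat, k) {
  out <- mat
  for (j in seq_len(ncol(mat))) {
    for (f in which(is.na(mat[, j]))) {
      cand <- data.frame(l = integer(0), d = numeric(0))
      for (l in seq_len(ncol(mat))) {
        if (l == j || is.na(mat[f, l])) next
        co <- !is.na(mat[, j]) & !is.na(mat[, l])
        if (!any(co)) next
        cand <- rbind(cand,
                      data.frame(l = l, d = sqrt(sum((mat[co, j] - mat[co, l])^2))))
      }
      cand <- cand[order(cand$d, cand$l), ]
      nb <- head(cand, k)
      w <- exp(-nb$d)
      if (sum(w) == 0) w <- rep(1, nrow(nb))
      out[f, j] <- sum(w * mat[f, nb$l]) / sum(w)
    }
  }
  out
}

# Dense rank by explicit sort-unique lookup.
oracle_dense_rank <- function(values, descending = TRUE) {
  u <- sort(unique(values), decreasing = descending)
  vapply(values, function(v) which(u == v), integer(1))
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[ord[i]] * n / i)
    adj[ord[i]] <- running
  }
  adj
}

# Truncated-normal mean by numerical integration (independent of the
# closed form used in the package).
oracle_truncnorm_mean <- function(mean, sd, lower, upper) {
  f <- function(x) x * dnorm(x, mean, sd)
  stats::integrate(f, lower, upper)$value /
    (pnorm(upper, mean, sd) - pnorm(lower, mean, sd))
}

# Small fast simulation config used across tests.
tiny_sim <- function(seed = 1, ...) {
  sim_config(n_genes = 120L, n_modules = 12L, module_size = 10L,
             planted_modules = 1:3, down_modules = 4:6, seed = seed, ...)
}
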