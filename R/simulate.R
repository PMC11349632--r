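#' Configuration for a synthetic vaccine study
#'
#' Builds the full parameterisation of a synthetic five-arm adjuvanted
#' vaccine study with known ground truth. The defaults emulate the design of
#' the motivating trial: five adjuvant groups of sizes 15/19/25/19/20 (98
#' retained participants), a gene log fold-change (post/pre dose-2) matrix
#' organised in within-module correlated blocks, modules up-shifted in the
#' AS01/AS03-like arms and a block down-shifted in those arms (an NK-like
#' counter-signal), censored lognormal serum analytes (8 cytokines + CRP),
#' and antibody features at three timepoints (D60 peak, D360 persistence,
#' D390 post-challenge) linearly driven by a planted subset of module
#' latents, with the middle-timepoint signal attenuated.
#'
#' Antibody features are generated directly on analysis (log) scale; only
#' analytes are generated on raw scale, because they are the inputs that the
#' limit-of-quantification censoring and imputation rules act on.
#'
#' @param group_sizes named integer vector of participants per adjuvant arm.
#' @param responder_groups arms carrying the innate up-shift (AS01/AS03-like).
#' @param n_genes total genes; module members are allocated first, the rest
#'   are independent background noise.
#' @param n_modules number of gene modules (blood-transcriptional-module
#'   analogues).
#' @param module_size genes per module.
#' @param rho within-module pairwise correlation target, in \[0, 1).
#' @param planted_modules indices (into modules) of the modules whose latents
#'   drive the antibody response.
#' @param down_modules indices of modules down-shifted in responder arms
#'   (group-associated distractors with no effect on antibodies).
#' @param group_shift innate mean shift of planted (+) and down (-) module
#'   latents in responder arms, in latent SD units.
#' @param target_r2 population fraction of antibody-feature variance explained
#'   by the planted module latents at attenuation 1.
#' @param attenuation multiplicative factors on the planted effect sizes per
#'   timepoint; the middle value < 1 reproduces the drop in predictable
#'   features at the persistence timepoint.
#' @param driven_features antibody features receiving the planted signal;
#'   the remainder are pure noise.
#' @param noise_sd noise standard deviation for undriven antibody features.
#' @param missing_rate per-cell missingness probability for analyte and
#'   antibody tables.
#' @param n_dropout number of additional participants generated with >50\%
#'   of innate features missing (they are appended beyond `group_sizes`, so
#'   the configured arm sizes are what survives the missingness filter).
#' @param seed master seed; a fixed seed makes the study byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(AS01B = 15L, AS01E = 19L, AS03 = 25L,
                                       AS04 = 19L, Alum = 20L),
                       responder_groups = c("AS01B", "AS01E", "AS03"),
                       n_genes = 1200L,
                       n_modules = 103L,
                       module_size = 10L,
                       rho = 0.7,
                       planted_modules = 1:10,
                       down_modules = 11:20,
                       group_shift = 0.5,
                       target_r2 = 0.7,
                       attenuation = c(D60 = 1.0, D360 = 0.3, D390 = 0.9),
                       driven_features = c("total_Ig", "IgG", "IgG1",
                                           "FcGR2AH", "FcGR3AV", "C1q",
                                           "ADCP", "ADNK_IFNG", "FI1"),
                       noise_sd = 1.0,
                       missing_rate = 0.02,
                       n_dropout = 2L,
                       seed = 1L) {
  stopifnot(all(group_sizes > 0), !is.null(names(group_sizes)),
            rho >= 0, rho < 1,
            n_modules * module_size <= n_genes,
            target_r2 > 0, target_r2 < 1,
            is.finite(group_shift),
            missing_rate >= 0, missing_rate < 1,
            n_dropout >= 0,
            length(attenuation) == 3L, all(is.finite(attenuation)))
  if (!all(responder_groups %in% names(group_sizes)))
    stop("responder_groups must be a subset of names(group_sizes)", call. = FALSE)

  module_ids <- sprintf("M%03d", seq_len(n_modules))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  members <- split(gene_ids[seq_len(n_modules * module_size)],
                   rep(seq_len(n_modules), each = module_size))
  names(members) <- module_ids
  if (anyDuplicated(unlist(members)))
    stop("module membership inconsistent: a gene belongs to two modules",
         call. = FALSE)

  # per-module latent shift in responder arms
  shift <- stats::setNames(rep(0, n_modules), module_ids)
  shift[planted_modules] <- group_shift
  shift[down_modules] <- -group_shift

  antibody_features <- c(
    "total_Ig", "FI1",
    "IgA1", "IgA2", "IgG", "IgG1", "IgG2", "IgG3", "IgG4", "IgM",
    "FcGR2AH", "FcGR2AR", "FcGR2B", "FcGR3AF", "FcGR3AV", "FcGR3B",
    "FcRn", "FcAR", "C1q",
    "ADCC3D", "ADCP", "ADDCP", "ADNP",
    "ADDCP_IFNA2", "ADDCP_IL10", "ADDCP_IL12B", "ADDCP_IL1B", "ADDCP_IL6",
    "ADDCP_IL8", "ADDCP_IP10", "ADDCP_TNF",
    "ADNK_CD107a", "ADNK_IFNG", "ADNK_MIP1B")
  bad <- setdiff(driven_features, antibody_features)
  if (length(bad) > 0L)
    stop("unknown driven feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  # loading matrix: driven features load equally on every planted module
  loadings <- matrix(0, nrow = length(antibody_features), ncol = n_modules,
                     dimnames = list(antibody_features, module_ids))
  loadings[driven_features, planted_modules] <- 1

  # lognormal serum analytes; LOQ thresholds on the raw measurement scale
  analyte_spec <- data.frame(
    analyte   = c("CRP", "IFNg", "TNFa", "IP10", "MCP1",
                  "IL1B", "IL5", "IL6", "IL10"),
    unit      = c("mg/dL", rep("pg/mL", 8)),
    log2_mean = c(0.5, 3, 3.5, 7, 8, 0.5, 1, 1.2, 2),
    log2_sd   = c(1, 0.8, 0.6, 0.9, 0.5, 0.9, 0.7, 1.1, 0.8),
    # post/pre log2 shift in responder arms (CRP/IP-10/IL-6 rise most)
    resp_shift = c(2, 0.5, 0.5, 1.5, 0.5, 0.5, 0.2, 1.5, 0.5),
    threshold = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.822, 0.01, 0.822, 0.01),
    stringsAsFactors = FALSE)

  cfg <- list(group_sizes = group_sizes,
              responder_groups = responder_groups,
              n_genes = n_genes, gene_ids = gene_ids,
              module_ids = module_ids, module_members = members,
              rho = rho,
              planted_modules = module_ids[planted_modules],
              down_modules = module_ids[down_modules],
              module_shift = shift,
              target_r2 = target_r2,
              attenuation = attenuation,
              antibody_features = antibody_features,
              driven_features = driven_features,
              loadings = loadings,
              noise_sd = noise_sd,
              w1_threshold = 5,
              analyte_spec = analyte_spec,
              missing_rate = missing_rate,
              n_dropout = as.integer(n_dropout),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Population covariance of the planted module latents, implied by the
# group-shift structure and the group proportions.
latent_covariance <- function(cfg) {
  pr <- cfg$group_sizes / sum(cfg$group_sizes)
  resp <- as.numeric(names(cfg$group_sizes) %in% cfg$responder_groups)
  shifts <- outer(cfg$module_shift, resp)   # modules x groups
  mu <- drop(shifts %*% pr)
  centered <- shifts - mu
  between <- centered %*% (pr * t(centered))
  diag(length(cfg$module_ids)) + between
}

participant_ids <- function(cfg) {
  n <- sum(cfg$group_sizes) + cfg$n_dropout
  sprintf("P%03d", seq_len(n))
}

participant_groups <- function(cfg) {
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  if (cfg$n_dropout > 0L) {
    extra <- rep_len(names(cfg$group_sizes), cfg$n_dropout)
    groups <- c(groups, extra)
  }
  stats::setNames(groups, participant_ids(cfg))
}

#' Generate the innate response of a synthetic study
#'
#' Draws per-module latent factors (standard normal plus the configured
#' responder-arm shifts), gene log fold-changes as
#' `sqrt(rho) * latent + sqrt(1 - rho) * noise` within each module (the
#' single-latent-factor construction gives pairwise within-module correlation
#' `rho`), background genes as independent noise, and pre/post serum analytes
#' as lognormal values with responder-arm post shifts. Returns the ground
#' truth needed for recovery testing.
#'
#' @param cfg a [sim_config()].
#' @return list with `logfc` (genes x participants), `analytes_pre` /
#'   `analytes_post` (analyte panels, see [apply_censoring()]), and `truth`
#'   (groups, planted module ids, module latents, latent innate signal,
#'   loadings, per-timepoint coefficients, noise SDs, dropout ids).
#' @export
simulate_innate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    ids <- participant_ids(cfg)
    groups <- participant_groups(cfg)
    n <- length(ids)
    m <- length(cfg$module_ids)
    resp <- as.numeric(groups %in% cfg$responder_groups)

    latents <- matrix(stats::rnorm(m * n), m, n,
                      dimnames = list(cfg$module_ids, ids))
    latents <- latents + outer(cfg$module_shift, resp)

    logfc <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                    dimnames = list(cfg$gene_ids, ids))
    sr <- sqrt(cfg$rho); se <- sqrt(1 - cfg$rho)
    for (mod in cfg$module_ids) {
      g <- cfg$module_members[[mod]]
      logfc[g, ] <- sr * matrix(latents[mod, ], length(g), n, byrow = TRUE) +
        se * logfc[g, , drop = FALSE]
    }

    spec <- cfg$analyte_spec
    na <- nrow(spec)
    pre_log <- spec$log2_mean + spec$log2_sd * matrix(stats::rnorm(na * n), na, n)
    post_log <- pre_log + outer(spec$resp_shift, resp) +
      0.5 * matrix(stats::rnorm(na * n), na, n)
    dn <- list(spec$analyte, ids)
    analytes_pre <- new_analyte_panel(2^pre_log, spec, dn)
    analytes_post <- new_analyte_panel(2^post_log, spec, dn)

    # signal variance implied by loadings and latent covariance; noise SD
    # solves for the configured population R^2 at attenuation 1
    sigma <- latent_covariance(cfg)
    sig_var <- diag(cfg$loadings %*% sigma %*% t(cfg$loadings))
    noise_sd <- ifelse(sig_var > 0,
                       sqrt(sig_var * (1 - cfg$target_r2) / cfg$target_r2),
                       cfg$noise_sd)
    names(noise_sd) <- cfg$antibody_features

    planted_latents <- latents[cfg$planted_modules, , drop = FALSE]
    truth <- list(
      groups = groups,
      latent = colMeans(planted_latents),
      module_latents = latents,
      planted_modules = cfg$planted_modules,
      down_modules = cfg$down_modules,
      loadings = cfg$loadings,
      attenuation = cfg$attenuation,
      coefficients = lapply(cfg$attenuation, function(a) a * cfg$loadings),
      noise_sd = noise_sd,
      driven_features = cfg$driven_features,
      dropout_ids = if (cfg$n_dropout > 0L) utils::tail(ids, cfg$n_dropout)
                    else character(0))
    list(logfc = logfc, analytes_pre = analytes_pre,
         analytes_post = analytes_post, truth = truth)
  })
}

new_analyte_panel <- function(values, spec, dimnames) {
  dimnames(values) <- dimnames
  structure(list(values = values,
                 censored = matrix(FALSE, nrow(values), ncol(values),
                                   dimnames = dimnames),
                 thresholds = stats::setNames(spec$threshold, spec$analyte),
                 units = stats::setNames(spec$unit, spec$analyte)),
            class = "analyte_panel")
}

#' Generate antibody-feature tables for the three timepoints
#'
#' Each antibody feature is `loading . module latents * attenuation(t)` plus
#' Gaussian noise on analysis scale; the noise SD is set so driven features
#' reach the configured population R-squared at attenuation 1. The avidity
#' parameter W1 is generated continuous around the class threshold 5 so both
#' avidity classes are present.
#'
#' @param cfg a [sim_config()].
#' @param truth the ground truth from [simulate_innate()] on the same config.
#' @return named list of features x participants matrices, one per timepoint,
#'   each with an additional `W1` row.
#' @export
simulate_antibody <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!identical(rownames(cfg$loadings), cfg$antibody_features) ||
      !identical(colnames(cfg$loadings), cfg$module_ids))
    stop("loading matrix dimensions do not match features/modules", call. = FALSE)
  if (!identical(rownames(truth$module_latents), cfg$module_ids))
    stop("truth does not match config: module ids differ", call. = FALSE)
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    ids <- colnames(truth$module_latents)
    n <- length(ids)
    signal <- cfg$loadings %*% truth$module_latents  # features x participants
    w1_signal <- colMeans(truth$module_latents[cfg$planted_modules, , drop = FALSE])
    w1_scale <- 1.5 / stats::sd(w1_signal)
    out <- lapply(seq_along(cfg$attenuation), function(ti) {
      a <- cfg$attenuation[[ti]]
      noise <- matrix(stats::rnorm(nrow(signal) * n), nrow(signal), n) *
        truth$noise_sd
      y <- 6 + a * signal + noise
      w1 <- cfg$w1_threshold + a * w1_scale * w1_signal + stats::rnorm(n, 0, 1)
      rbind(y, W1 = w1)
    })
    names(out) <- names(cfg$attenuation)
    for (t in names(out)) dimnames(out[[t]]) <-
      list(c(cfg$antibody_features, "W1"), ids)
    out
  })
}

#' Flag analyte values below their detection threshold
#'
#' Values strictly below the per-analyte threshold are flagged censored and
#' their raw values withheld (set missing); values at or above the threshold
#' are unchanged.
#'
#' @param panel an `analyte_panel` (list with `values`, `censored`,
#'   `thresholds`, `units`).
#' @param thresholds optional named vector overriding the panel thresholds;
#'   every analyte in the panel must have one.
#' @return the panel with updated `censored` flags and withheld values.
#' @export
apply_censoring <- function(panel, thresholds = NULL) {
  stopifnot(inherits(panel, "analyte_panel"))
  thr <- if (is.null(thresholds)) panel$thresholds else thresholds
  missing_thr <- setdiff(rownames(panel$values), names(thr))
  if (length(missing_thr) > 0L)
    stop("no detection threshold for analyte(s): ",
         paste(missing_thr, collapse = ", "), call. = FALSE)
  if (any(thr[rownames(panel$values)] <= 0))
    stop("detection thresholds must be positive", call. = FALSE)
  thr <- thr[rownames(panel$values)]
  flag <- !is.na(panel$values) & panel$values < thr
  panel$censored <- panel$censored | flag
  panel$values[flag] <- NA_real_
  panel$thresholds <- thr
  panel
}

#' Introduce missingness into a feature-by-participant table
#'
#' Non-dropout cells go missing independently with probability `rate`
#' (capped at half the features per participant so that only designated
#' dropouts can exceed the 50\% missingness filter); each of the `dropout_ids`
#' participants gets `dropout_frac` of features set missing.
#'
#' @param mat features x participants numeric matrix.
#' @param rate per-cell missingness probability in \[0, 1).
#' @param dropout_ids participant (column) ids designated as dropouts.
#' @param seed integer seed.
#' @param dropout_frac fraction of features missing for dropouts (> 0.5).
#' @return the matrix with `NA`s inserted.
#' @export
apply_missingness <- function(mat, rate, dropout_ids = character(0), seed = 1L,
                              dropout_frac = 0.6) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  stopifnot(dropout_frac > 0.5, dropout_frac <= 1)
  bad <- setdiff(dropout_ids, colnames(mat))
  if (length(bad) > 0L)
    stop("dropout id(s) not in table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  withr::with_seed(seed, {
    p <- nrow(mat)
    cap <- floor(p / 2)
    for (j in seq_len(ncol(mat))) {
      if (colnames(mat)[j] %in% dropout_ids) {
        k <- ceiling(dropout_frac * p)
        mat[sample.int(p, k), j] <- NA_real_
      } else if (rate > 0) {
        miss <- which(stats::runif(p) < rate)
        if (length(miss) > cap) miss <- sample(miss, cap)
        mat[miss, j] <- NA_real_
      }
    }
    mat
  })
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_innate()], [apply_censoring()] on both analyte panels,
#' [simulate_antibody()], then inserts missingness: designated dropout
#' participants lose their entire expression assay plus most analytes (so
#' they exceed the 50\% innate-missingness filter), and analyte/antibody
#' cells go missing at the configured rate.
#'
#' @param cfg a [sim_config()].
#' @return list of class `vs_study` with elements `config`, `expr_logfc`,
#'   `analytes_pre`, `analytes_post`, `antibody` (list per timepoint),
#'   `modules` (gene-set collection), `groups`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  innate <- simulate_innate(cfg)
  innate$analytes_pre <- apply_censoring(innate$analytes_pre)
  innate$analytes_post <- apply_censoring(innate$analytes_post)
  antibody <- simulate_antibody(cfg, innate$truth)

  drop_ids <- innate$truth$dropout_ids
  logfc <- innate$logfc
  logfc[, drop_ids] <- NA_real_
  innate$analytes_post$values <- apply_missingness(
    innate$analytes_post$values, cfg$missing_rate, drop_ids,
    seed = derive_seed(cfg$seed, 3L), dropout_frac = 0.8)
  innate$analytes_pre$values <- apply_missingness(
    innate$analytes_pre$values, cfg$missing_rate, drop_ids,
    seed = derive_seed(cfg$seed, 4L), dropout_frac = 0.8)
  for (i in seq_along(antibody)) {
    antibody[[i]] <- apply_missingness(
      antibody[[i]], cfg$missing_rate, character(0),
      seed = derive_seed(cfg$seed, 4L + i))
  }

  modules <- cfg$module_members
  attr(modules, "description") <- stats::setNames(
    ifelse(names(modules) %in% cfg$planted_modules, "planted",
           ifelse(names(modules) %in% cfg$down_modules, "down-shifted",
                  "background")),
    names(modules))
  class(modules) <- "gene_set_collection"

  structure(list(config = cfg,
                 expr_logfc = logfc,
                 analytes_pre = innate$analytes_pre,
                 analytes_post = innate$analytes_post,
                 antibody = antibody,
                 modules = modules,
                 groups = innate$truth$groups,
                 truth = innate$truth),
            class = "vs_study")
}

#' Write a synthetic study to a directory
#'
#' Writes `expr_logfc.tsv`, `analytes_pre.tsv`/`analytes_post.tsv`,
#' `antibody_<timepoint>.tsv`, `modules.gmt`, `truth.json`, and
#' `config.json`. [read_study()] on the directory reproduces the study.
#'
#' @param study a `vs_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "vs_study"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir, call. = FALSE)
  wm <- function(m, f, id) write_matrix_tsv(m, file.path(dir, f), id)
  wm(study$expr_logfc, "expr_logfc.tsv", "gene")
  wm(study$analytes_pre$values, "analytes_pre.tsv", "analyte")
  wm(study$analytes_post$values, "analytes_post.tsv", "analyte")
  for (t in names(study$antibody))
    wm(study$antibody[[t]], paste0("antibody_", t, ".tsv"), "feature")
  write_gmt(study$modules, file.path(dir, "modules.gmt"))

  truth <- study$truth
  tr <- list(groups = as.list(truth$groups),
             latent = as.list(truth$latent),
             module_latents = matrix_to_list(truth$module_latents),
             planted_modules = truth$planted_modules,
             down_modules = truth$down_modules,
             loadings = matrix_to_list(truth$loadings),
             attenuation = as.list(truth$attenuation),
             noise_sd = as.list(truth$noise_sd),
             driven_features = truth$driven_features,
             dropout_ids = truth$dropout_ids,
             censored_pre = matrix_to_list(study$analytes_pre$censored * 1),
             censored_post = matrix_to_list(study$analytes_post$censored * 1))
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- study$config
  cfg_out <- unclass(cfg)
  cfg_out$module_members <- NULL       # reconstructed from modules.gmt
  cfg_out$loadings <- matrix_to_list(cfg$loadings)
  cfg_out$analyte_spec <- as.list(cfg$analyte_spec)
  # jsonlite drops names of atomic vectors; keep them as objects
  for (f in c("group_sizes", "module_shift", "attenuation"))
    cfg_out[[f]] <- as.list(cfg[[f]])
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

matrix_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m),
       values = apply(m, 1, function(x) unname(as.list(x)), simplify = FALSE))
}

list_to_matrix <- function(l) {
  vals <- do.call(rbind, lapply(l$values, function(r)
    vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))))
  dimnames(vals) <- list(unlist(l$rows), unlist(l$cols))
  vals
}

#' Read a synthetic study back from a directory
#' @param dir directory written by [write_study()].
#' @return a `vs_study` list.
#' @export
read_study <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  for (f in c("group_sizes", "module_shift", "attenuation"))
    cfg_raw[[f]] <- unlist(cfg_raw[[f]])
  modules <- read_gmt(file.path(dir, "modules.gmt"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))

  cfg <- sim_config(
    group_sizes = stats::setNames(as.integer(cfg_raw$group_sizes),
                                  names(cfg_raw$group_sizes)),
    responder_groups = cfg_raw$responder_groups,
    n_genes = cfg_raw$n_genes,
    n_modules = length(cfg_raw$module_ids),
    module_size = length(modules[[1]]),
    rho = cfg_raw$rho,
    planted_modules = match(cfg_raw$planted_modules, cfg_raw$module_ids),
    down_modules = match(cfg_raw$down_modules, cfg_raw$module_ids),
    group_shift = max(abs(cfg_raw$module_shift)),
    target_r2 = cfg_raw$target_r2,
    attenuation = unlist(cfg_raw$attenuation),
    driven_features = cfg_raw$driven_features,
    noise_sd = cfg_raw$noise_sd,
    missing_rate = cfg_raw$missing_rate,
    n_dropout = cfg_raw$n_dropout,
    seed = cfg_raw$seed)

  spec <- cfg$analyte_spec
  mk_panel <- function(values_file, censored) {
    v <- read_matrix_tsv(file.path(dir, values_file))
    p <- new_analyte_panel(v, spec, dimnames(v))
    p$censored <- matrix(as.logical(censored), nrow(v), ncol(v),
                         dimnames = dimnames(v))
    p
  }
  tp_files <- sort(list.files(dir, pattern = "^antibody_.*\\.tsv$"))
  tps <- sub("^antibody_(.*)\\.tsv$", "\\1", tp_files)
  antibody <- lapply(tp_files, function(f) read_matrix_tsv(file.path(dir, f)))
  names(antibody) <- tps
  antibody <- antibody[intersect(names(cfg$attenuation), tps)]

  truth <- list(
    groups = unlist(tr$groups),
    latent = unlist(tr$latent),
    module_latents = list_to_matrix(tr$module_latents),
    planted_modules = unlist(tr$planted_modules),
    down_modules = unlist(tr$down_modules),
    loadings = list_to_matrix(tr$loadings),
    attenuation = unlist(tr$attenuation),
    noise_sd = unlist(tr$noise_sd),
    driven_features = unlist(tr$driven_features),
    dropout_ids = as.character(unlist(tr$dropout_ids)))
  truth$coefficients <- lapply(truth$attenuation, function(a) a * truth$loadings)

  structure(list(config = cfg,
                 expr_logfc = read_matrix_tsv(file.path(dir, "expr_logfc.tsv")),
                 analytes_pre = mk_panel("analytes_pre.tsv",
                                         list_to_matrix(tr$censored_pre)),
                 analytes_post = mk_panel("analytes_post.tsv",
                                          list_to_matrix(tr$censored_post)),
                 antibody = antibody,
                 modules = modules,
                 groups = unlist(tr$groups),
                 truth = truth),
            class = "vs_study")
}
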