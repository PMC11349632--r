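#' Run the full innate-to-antibody pipeline
#'
#' Orchestrates all stages over a synthetic or on-disk study: analyte
#' limit-of-quantification imputation and log2 fold changes, IQR filtering
#' of the gene log fold-change matrix, per-sample module enrichment scoring,
#' participant missingness filtering, integration with each timepoint's
#' antibody features (z-scale then KNN-impute), nested-CV LASSO and random
#' forest per antibody feature with predictability gating, W1 avidity
#' classification, correlation-cluster-corrected rank aggregation, top-k
#' unions, association analyses (module clusters, group tests, PCA), and the
#' adjuvant-group classifier. All randomness derives from `config$seed`.
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param config a [vs_config()]; `outer_repeats` is the main cost dial.
#' @param input_dir optional directory of study files as written by
#'   [write_study()]; when `NULL` a synthetic study is generated from `sim`
#'   and written under `output_dir/study`.
#' @param sim a [sim_config()] used when simulating (its seed defaults to
#'   the run seed).
#' @param antibody_features antibody features to model (default: all
#'   regression features in the study tables; `"W1"` adds the avidity
#'   classifier).
#' @param timepoints timepoints to model (default: all in the study).
#' @param classify run the adjuvant-group classifier stage (default `TRUE`).
#' @param associate run the association stage (default `TRUE`).
#' @param verbose log stage progress.
#' @return (invisibly) a list of class `vs_run` with all stage results;
#'   side effect: TSV/JSON artifacts plus `manifest.json` in `output_dir`.
#' @export
run_study <- function(output_dir, config = vs_config(), input_dir = NULL,
                      sim = NULL, antibody_features = NULL,
                      timepoints = NULL, classify = TRUE, associate = TRUE,
                      verbose = TRUE) {
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, stage) {
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), start,
                                                   units = "secs")), 3)
    if (verbose) message(sprintf("[%s] done in %.1fs", stage,
                                 timings[[stage]]))
  }
  if (!dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE))
    stop("cannot create output directory: ", output_dir, call. = FALSE)

  # -- stage: study ---------------------------------------------------------
  s <- tic()
  if (is.null(input_dir)) {
    if (is.null(sim)) sim <- sim_config(seed = config$seed)
    study <- simulate_study(sim)
    write_study(study, file.path(output_dir, "study"))
    input_dir <- file.path(output_dir, "study")
  } else {
    required <- c("expr_logfc.tsv", "analytes_pre.tsv", "analytes_post.tsv",
                  "modules.gmt")
    missing <- required[!file.exists(file.path(input_dir, required))]
    if (length(missing) > 0L)
      stop("missing input file(s) in ", input_dir, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    study <- read_study(input_dir)
  }
  toc(s, "study")

  # -- stage: preprocess ----------------------------------------------------
  s <- tic()
  pre <- impute_below_loq(study$analytes_pre, seed = derive_seed(config$seed, 11L))
  post <- impute_below_loq(study$analytes_post, seed = derive_seed(config$seed, 12L))
  analyte_logfc <- log_fold_change(log2(post$values), log2(pre$values))

  expr <- study$expr_logfc
  complete_cols <- colSums(is.na(expr)) < nrow(expr)
  expr_obs <- expr[, complete_cols, drop = FALSE]
  expr_obs <- expr_obs[stats::complete.cases(expr_obs), , drop = FALSE]
  expr_f <- iqr_filter(expr_obs, config$iqr_threshold)
  if (nrow(expr_f) == 0L) stop("IQR filter removed every gene", call. = FALSE)
  toc(s, "preprocess")

  # -- stage: enrichment ----------------------------------------------------
  s <- tic()
  sets <- filter_gene_sets(study$modules, rownames(expr_f),
                           config$set_size_min, config$set_size_max)
  enr_obs <- enrichment_scores(expr_f, sets)
  # participants without an expression assay carry missing module scores
  enr <- matrix(NA_real_, nrow(enr_obs), ncol(expr),
                dimnames = list(rownames(enr_obs), colnames(expr)))
  enr[, colnames(enr_obs)] <- enr_obs
  toc(s, "enrichment")

  # -- stage: integrate -----------------------------------------------------
  s <- tic()
  innate <- rbind(enr, analyte_logfc[, colnames(enr), drop = FALSE])
  innate <- filter_participants(innate, config$missing_frac_max)
  kept <- colnames(innate)
  innate_z <- knn_impute(z_scale(innate), k = config$knn_k)

  if (is.null(timepoints)) timepoints <- names(study$antibody)
  all_features <- setdiff(rownames(study$antibody[[1]]), "W1")
  if (is.null(antibody_features)) antibody_features <- all_features
  model_w1 <- "W1" %in% antibody_features
  antibody_features <- setdiff(intersect(antibody_features,
                                         c(all_features, "W1")), "W1")
  integrated <- lapply(timepoints, function(tp) {
    integrate_features(innate, study$antibody[[tp]], knn_k = config$knn_k)
  })
  names(integrated) <- timepoints
  toc(s, "integrate")

  # -- stage: clusters ------------------------------------------------------
  s <- tic()
  fclust <- kmeans_functional_clusters(enr_obs, k = config$kmeans_k,
                                       seed = derive_seed(config$seed, 21L),
                                       k_range = config$kmeans_k_range,
                                       nstart = config$kmeans_nstart)
  cclust <- correlation_clusters(innate_z, config$corr_threshold)
  toc(s, "clusters")

  # -- stage: model ---------------------------------------------------------
  s <- tic()
  plan <- make_split_plan(kept, config$outer_repeats, config$test_frac,
                          seed = derive_seed(config$seed, 31L))
  innate_names <- rownames(innate)
  models <- list()
  for (tp in timepoints) {
    X <- t(integrated[[tp]][innate_names, , drop = FALSE])
    for (feat in antibody_features) {
      y <- integrated[[tp]][feat, ]
      seed_ft <- derive_seed(config$seed, 1000L + length(models))
      lf <- fit_lasso_nested(X, y, plan, config$inner_repeats,
                             config$inner_folds, config$n_lambda,
                             config$lambda_min_ratio, seed = seed_ft)
      ff <- fit_forest(X, y, plan, config$n_trees, config$mtry_step,
                       config$mtry_improve, config$tune_trees, seed = seed_ft)
      models[[paste0(feat, "|", tp)]] <-
        summarize_models(lf, ff, config$dev_ratio_gate,
                         config$var_explained_gate, config$balanced_acc_gate)
    }
    if (model_w1) {
      w1_raw <- study$antibody[[tp]]["W1", kept]
      obs <- names(w1_raw)[!is.na(w1_raw)]
      if (length(obs) >= 10 &&
          length(unique(w1_raw[obs] < config$w1_threshold)) == 2) {
        plan_w1 <- make_split_plan(obs, config$outer_repeats, config$test_frac,
                                   seed = derive_seed(config$seed, 32L))
        wf <- fit_w1_classifiers(X[obs, , drop = FALSE], w1_raw[obs], plan_w1,
                                 threshold = config$w1_threshold,
                                 inner_repeats = config$inner_repeats,
                                 inner_folds = config$inner_folds,
                                 n_lambda = config$n_lambda,
                                 n_trees = config$n_trees,
                                 mtry_step = config$mtry_step,
                                 mtry_improve = config$mtry_improve,
                                 tune_trees = config$tune_trees,
                                 seed = derive_seed(config$seed, 33L))
        models[[paste0("W1|", tp)]] <-
          summarize_models(wf$lasso, wf$forest, config$dev_ratio_gate,
                           config$var_explained_gate, config$balanced_acc_gate)
      } else {
        message("W1 classification skipped at ", tp,
                ": too few observed values or a single class")
      }
    }
  }
  toc(s, "model")

  # -- stage: rank ----------------------------------------------------------
  s <- tic()
  innate_clusters <- cclust[cclust$feature %in% innate_names, ]
  rankings <- lapply(models, rank_predictors, clusters = innate_clusters)
  predictable <- vapply(models, `[[`, logical(1), "predictable")
  topk <- if (any(predictable)) {
    top_k_union(rankings[predictable], k = config$top_k)
  } else NULL
  toc(s, "rank")

  # -- stage: associate -----------------------------------------------------
  s <- tic()
  assoc <- if (!associate) NULL else list(
    correlation = pearson_matrix(enr[, kept, drop = FALSE],
                                 study$antibody[[timepoints[1]]][, kept,
                                                                 drop = FALSE]),
    pca = lapply(integrated, pca_with_contributions),
    group_tests = group_difference_tests(enr_obs[, intersect(colnames(enr_obs),
                                                             kept),
                                                 drop = FALSE],
                                         study$groups, config$bh_alpha))
  toc(s, "associate")

  # -- stage: classify ------------------------------------------------------
  s <- tic()
  classifier <- NULL
  if (classify) {
    responder <- study$config$responder_groups %||% c("AS01B", "AS01E", "AS03")
    super <- factor(ifelse(study$groups[kept] %in% responder,
                           "AS01_AS03", "AS04_Alum"))
    classifier <- classify_groups(t(innate_z), super, plan,
                                  clusters = innate_clusters,
                                  inner_repeats = config$inner_repeats,
                                  inner_folds = config$inner_folds,
                                  n_lambda = config$n_lambda,
                                  seed = derive_seed(config$seed, 41L))
  }
  toc(s, "classify")

  run <- structure(list(config = config, study = study,
                        enrichment = enr, innate = innate_z,
                        integrated = integrated,
                        functional_clusters = fclust,
                        correlation_clusters = cclust,
                        models = models, rankings = rankings,
                        predictable = predictable, top_k = topk,
                        association = assoc, classifier = classifier,
                        timepoints = timepoints,
                        timings = timings),
                   class = "vs_run")
  write_run_artifacts(run, output_dir, input_dir, t0)
  invisible(run)
}

write_run_artifacts <- function(run, output_dir, input_dir, t0) {
  wm <- function(m, f, id) write_matrix_tsv(m, file.path(output_dir, f), id)
  wm(run$enrichment, "enrichment.tsv", "module")
  wm(run$innate, "innate_features.tsv", "feature")
  for (tp in run$timepoints)
    wm(run$integrated[[tp]], paste0("integrated_", tp, ".tsv"), "feature")

  ms <- do.call(rbind, lapply(names(run$models), function(key) {
    m <- run$models[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    data.frame(feature = parts[1], timepoint = parts[2],
               classification = m$classification,
               dev_ratio = m$dev_ratio, lasso_test = m$lasso_test,
               rf_oob = m$rf_oob, rf_test = m$rf_test,
               predictable = m$predictable, stringsAsFactors = FALSE)
  }))
  utils::write.table(ms, file.path(output_dir, "model_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rk <- do.call(rbind, lapply(names(run$rankings), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cbind(data.frame(feature = parts[1], timepoint = parts[2],
                     stringsAsFactors = FALSE), run$rankings[[key]])
  }))
  utils::write.table(rk, file.path(output_dir, "rankings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$top_k)) {
    wm(run$top_k$membership, "topk_membership.tsv", "predictor")
    utils::write.table(
      data.frame(predictor = run$top_k$predictors, n_top_k = run$top_k$counts),
      file.path(output_dir, "topk_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  utils::write.table(run$correlation_clusters,
                     file.path(output_dir, "correlation_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fc <- data.frame(module = names(run$functional_clusters$assignment),
                   cluster = as.integer(run$functional_clusters$assignment))
  utils::write.table(fc, file.path(output_dir, "functional_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$functional_clusters$elbow,
                     file.path(output_dir, "elbow.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$association))
    utils::write.table(run$association$group_tests$tests,
                       file.path(output_dir, "group_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$classifier)) {
    utils::write.table(report_discriminators(run$classifier),
                       file.path(output_dir, "classifier_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = run$classifier$accuracy,
           null_accuracy = run$classifier$null_accuracy,
           p_value = run$classifier$p_value,
           balanced_accuracy = run$classifier$balanced_accuracy),
      file.path(output_dir, "classifier_report.json"),
      auto_unbox = TRUE, digits = NA)
  }

  inputs <- list.files(input_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vaxsig")),
    config = unclass(run$config),
    seed = run$config$seed,
    input_digests = as.list(tools::md5sum(inputs)),
    stage_timings_s = run$timings,
    total_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
    timepoints = run$timepoints,
    n_models = length(run$models))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Summarise a completed run as markdown
#'
#' Counts of predictable antibody features per timepoint, the top-k union
#' table, the adjuvant-classifier summary, and (when the run was simulated
#' and ground truth is available) planted-predictor recovery metrics.
#'
#' @param output_dir directory written by [run_study()].
#' @param path output file (default `report.md` inside `output_dir`).
#' @return the report lines, invisibly; side effect: the markdown file.
#' @export
study_report <- function(output_dir, path = file.path(output_dir, "report.md")) {
  ms_file <- file.path(output_dir, "model_summary.tsv")
  if (!file.exists(ms_file))
    stop("incomplete run: missing ", ms_file, call. = FALSE)
  ms <- utils::read.delim(ms_file)
  lines <- c("# Pipeline run summary", "",
             "## Predictable antibody features per timepoint", "")
  for (tp in unique(ms$timepoint)) {
    sub <- ms[ms$timepoint == tp, ]
    lines <- c(lines, sprintf("- %s: %d of %d (%s)", tp,
                              sum(sub$predictable), nrow(sub),
                              paste(sub$feature[sub$predictable],
                                    collapse = ", ")))
  }
  tk_file <- file.path(output_dir, "topk_counts.tsv")
  if (file.exists(tk_file)) {
    tk <- utils::read.delim(tk_file)
    lines <- c(lines, "", "## Top-k predictor union", "",
               sprintf("- %s (top-k for %d antibody feature/timepoint pairs)",
                       tk$predictor, tk$n_top_k))
  }
  cl_file <- file.path(output_dir, "classifier_report.json")
  if (file.exists(cl_file)) {
    cl <- jsonlite::read_json(cl_file)
    lines <- c(lines, "", "## Adjuvant-group classifier", "",
               sprintf("- accuracy %.3f vs null (majority-class) %.3f, one-sided binomial p = %.3g",
                       cl$accuracy, cl$null_accuracy, cl$p_value))
  }
  truth_file <- file.path(output_dir, "study", "truth.json")
  if (file.exists(truth_file) && file.exists(tk_file)) {
    truth <- jsonlite::read_json(truth_file)
    planted <- unlist(truth$planted_modules)
    tk <- utils::read.delim(tk_file)
    rec <- sum(planted %in% tk$predictor)
    lines <- c(lines, "", "## Ground-truth recovery", "",
               sprintf("- %d of %d planted predictive modules in the top-k union",
                       rec, length(planted)))
  }
  writeLines(lines, path)
  invisible(lines)
}
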