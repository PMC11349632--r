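#' Default run configuration
#'
#' All tunable constants of the pipeline with their default values. Defaults
#' reproduce the source workflow: probe rows with interquartile range
#' \eqn{\le} 0.75 are removed; gene sets are kept when 5--500 members are
#' expressed; functional module clusters use K-means with K = 5; predictors
#' with pairwise Pearson correlation > 0.8 form correlation clusters;
#' K-nearest-neighbour imputation uses K = 10; models are evaluated on 100
#' outer 80:20 train/test splits with an inner 10 x 5-fold cross-validation
#' for the LASSO penalty; forests use 1000 trees with `mtry` tuned by OOB
#' error (step factor 1.5, relative improvement 0.01); an antibody feature
#' counts as predictable when the mean LASSO deviance ratio or the mean
#' forest explained variance reaches 50\% (balanced accuracy strictly above
#' 50\% for the avidity classifier); avidity W1 is dichotomised at 5;
#' participants missing more than 50\% of the innate features are dropped;
#' group tests use Benjamini-Hochberg adjustment at 0.05.
#'
#' @param ... named overrides of individual fields.
#' @return A named list of class `vs_config`.
#' @export
#' @examples
#' cfg <- vs_config(knn_k = 3)
#' cfg$knn_k
vs_config <- function(...) {
  cfg <- list(
    iqr_threshold     = 0.75,
    set_size_min      = 5,
    set_size_max      = 500,
    kmeans_k          = 5,
    kmeans_k_range    = 2:10,
    kmeans_nstart     = 25,
    corr_threshold    = 0.8,
    knn_k             = 10,
    outer_repeats     = 100,
    test_frac         = 0.2,
    inner_repeats     = 10,
    inner_folds       = 5,
    n_lambda          = 100,
    lambda_min_ratio  = 0.01,
    n_trees           = 1000,
    mtry_step         = 1.5,
    mtry_improve      = 0.01,
    tune_trees        = 50,
    dev_ratio_gate    = 0.5,
    var_explained_gate = 0.5,
    balanced_acc_gate = 0.5,
    w1_threshold      = 5,
    missing_frac_max  = 0.5,
    bh_alpha          = 0.05,
    top_k             = 10,
    seed              = 1L
  )
  apply_overrides(cfg, list(...), "vs_config()")
}

apply_overrides <- function(cfg, overrides, where) {
  if (length(overrides) == 0L) {
    class(cfg) <- "vs_config"
    return(validate_config(cfg))
  }
  keys <- names(overrides)
  if (is.null(keys) || any(!nzchar(keys)))
    stop(where, ": all overrides must be named", call. = FALSE)
  unknown <- setdiff(keys, names(cfg))
  if (length(unknown) > 0L) {
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(cfg))
      names(cfg)[which.min(d)]
    }, character(1))
    stop(where, ": unknown config key(s): ",
         paste0("'", unknown, "' (did you mean '", hints, "'?)",
                collapse = ", "), call. = FALSE)
  }
  cfg[keys] <- overrides
  class(cfg) <- "vs_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$iqr_threshold >= 0,
    cfg$set_size_min >= 1, cfg$set_size_max >= cfg$set_size_min,
    cfg$kmeans_k >= 2,
    cfg$corr_threshold > 0, cfg$corr_threshold < 1,
    cfg$knn_k >= 1,
    cfg$outer_repeats >= 1,
    cfg$test_frac > 0, cfg$test_frac < 1,
    cfg$inner_repeats >= 1, cfg$inner_folds >= 2,
    cfg$n_trees >= 1,
    cfg$mtry_step > 1,
    cfg$mtry_improve >= 0,
    cfg$missing_frac_max > 0, cfg$missing_frac_max < 1,
    cfg$bh_alpha > 0, cfg$bh_alpha <= 1
  )
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Unspecified fields take the defaults of [vs_config()]; unknown keys are
#' rejected with a nearest-key hint so that typos never silently fall back
#' to a default.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the full default configuration.
#' @return A `vs_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  overrides <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(overrides)) overrides <- list()
  apply_overrides(unclass(vs_config()), as.list(overrides), path)
}

#' Write a run configuration to YAML
#' @param cfg a `vs_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$kmeans_k_range <- as.integer(out$kmeans_k_range)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.vs_config <- function(x, ...) {
  cat("<vs_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}

# Derive a stage seed from the master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483587)
}
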