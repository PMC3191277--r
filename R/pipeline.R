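#' Configuration for an end-to-end run
#'
#' Bundles every choice of one analysis run: feature kind (whole-brain
#' voxels vs atlas regions), which group is the modelled positive class,
#' the hyperparameter grid, the number of label permutations, and one root
#' seed from which every stochastic stage (cohort simulation, permutations,
#' pre-image restarts) derives a named substream.
#'
#' Exactly one input source is used: `input_dir` (a directory written by
#' [write_fixtures()]) or `spec` (a [cohort_spec()] simulated on the fly;
#' its seed is derived from `seed` unless the spec is given explicitly).
#'
#' @param feature_kind `"voxel"` or `"region"`.
#' @param positive_class `"control"` or `"patient"`.
#' @param grid A [search_grid()].
#' @param permutations Number of label permutations (0 disables the test).
#' @param fast_null,plus_one Passed to [permutation_test()].
#' @param seed Integer root seed.
#' @param input_dir Optional cohort directory.
#' @param spec Optional [cohort_spec()]; default one is derived from `seed`.
#' @param output_dir Optional directory for the JSON summary, per-fold TSV
#'   and NIfTI maps; nothing is written when `NULL`.
#' @param correlations Compute severity correlations (requires severity in
#'   the cohort table; only meaningful with controls as positive class).
#' @param maps Compute weight and t-maps.
#' @param mode Search mode, see [two_step_search()].
#' @return A validated `run_config`.
#' @export
run_config <- function(feature_kind = c("voxel", "region"),
                       positive_class = c("control", "patient"),
                       grid = search_grid(),
                       permutations = 0L,
                       fast_null = FALSE,
                       plus_one = FALSE,
                       seed = 1L,
                       input_dir = NULL,
                       spec = NULL,
                       output_dir = NULL,
                       correlations = TRUE,
                       maps = TRUE,
                       mode = c("two_step", "joint")) {
  cfg <- list(
    feature_kind = match.arg(feature_kind),
    positive_class = match.arg(positive_class),
    grid = grid,
    permutations = as.integer(permutations),
    fast_null = isTRUE(fast_null),
    plus_one = isTRUE(plus_one),
    seed = as.integer(seed),
    input_dir = input_dir,
    spec = spec,
    output_dir = output_dir,
    correlations = isTRUE(correlations),
    maps = isTRUE(maps),
    mode = match.arg(mode)
  )
  stopifnot(inherits(grid, "search_grid"))
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(sprintf("input_dir '%s' does not exist.", input_dir),
          class = "ocb_config_error")
  }
  if (is.null(cfg$spec) && is.null(cfg$input_dir)) {
    cfg$spec <- cohort_spec(seed = derive_seed(cfg$seed, "cohort-root"))
  }
  structure(cfg, class = "run_config")
}

stage_log <- function(stage, t0) {
  message(sprintf("[ocboundary] %-14s %.2fs", stage,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full normality-boundary pipeline
#'
#' Executes features, nested leave-one-out cross-validation, the final
#' refit on all positives, evaluation (severity correlations,
#' response-by-outlier table, optional permutation test) and spatial maps,
#' and assembles a JSON-serializable summary whose fields mirror the
#' standard reporting layout (TP/TN ratios, responder percentages among
#' outliers and non-outliers, support-vector count, severity correlations).
#' Identical config and seed produce byte-identical summaries.
#'
#' @param config A [run_config()].
#' @return An `ocb_run` object: list with `cohort`, `features`, `cv`,
#'   `model`, `report` (patient decision values), `correlations`,
#'   `subgroups`, `permutation`, `maps`, `summary` and `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(proc.time()["elapsed"])

  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    simulate_cohort(config$spec)
  }
  stage_log("cohort", t0)

  feats <- if (config$feature_kind == "voxel") {
    voxel_features(cohort$volumes, cohort$mask)
  } else {
    region_features(cohort$volumes, cohort$atlas, cohort$mask)
  }
  stage_log("features", t0)

  if (config$correlations && any(is.na(cohort$table$severity))) {
    abort("severity correlations requested but the cohort table has missing severity values.",
          class = "ocb_config_error")
  }

  cv <- nested_loo(feats, cohort$table, config$grid,
                   positive_class = config$positive_class,
                   mode = config$mode)
  stage_log("nested-cv", t0)

  pos_class <- config$positive_class
  neg_class <- setdiff(c("control", "patient"), pos_class)
  pos_ids <- cohort$table$subject_id[cohort$table$group == pos_class]
  neg_ids <- cohort$table$subject_id[cohort$table$group == neg_class]
  model <- final_model(features_subset(feats, pos_ids), cv)
  report <- decision_values(model, features_subset(feats, neg_ids))
  stage_log("final-model", t0)

  correlations <- NULL
  subgroups <- NULL
  if (pos_class == "control") {
    if (config$correlations) {
      correlations <- dplyr::bind_rows(
        severity_correlation(report, cohort$table, "all"),
        severity_correlation(report, cohort$table, "responders"),
        severity_correlation(report, cohort$table, "non-responders"))
    }
    subgroups <- subgroup_table(report, cohort$table)
  }

  permutation <- NULL
  if (config$permutations > 0) {
    permutation <- permutation_test(
      feats, cohort$table, config$grid,
      n_permutations = config$permutations,
      seed = derive_seed(config$seed, "permutation-root"),
      positive_class = pos_class,
      fast_null = config$fast_null,
      plus_one = config$plus_one,
      mode = config$mode,
      observed = cv)
    stage_log("permutation", t0)
  }

  maps <- NULL
  if (config$maps) {
    wmap <- weight_map(model, cohort$mask, cohort$atlas,
                       seed = derive_seed(config$seed, "preimage-root"))
    maps <- list(weight = wmap,
                 weight_rescaled = rescale_map(wmap),
                 t = one_sample_tmap(features_subset(feats, pos_ids),
                                     cohort$mask, cohort$atlas))
    stage_log("maps", t0)
  }

  summary <- build_summary(config, cv, model, correlations, subgroups,
                           permutation)
  validate_summary(summary)

  files <- NULL
  if (!is.null(config$output_dir)) {
    files <- write_run_outputs(config$output_dir, summary, cv, maps)
    stage_log("outputs", t0)
  }

  structure(
    list(cohort = cohort, features = feats, cv = cv, model = model,
         report = report, correlations = correlations,
         subgroups = subgroups, permutation = permutation, maps = maps,
         summary = summary, files = files, config = config),
    class = "ocb_run"
  )
}

build_summary <- function(config, cv, model, correlations, subgroups,
                          permutation) {
  pos <- config$positive_class
  s <- list(
    positive_class = pos,
    feature_kind = config$feature_kind,
    kernel = "RBF",
    nu_range = range(config$grid$nu_values),
    gamma_range = range(config$grid$gamma_values),
    n_folds = nrow(cv$folds),
    averaged_gamma = cv$averaged_gamma,
    averaged_nu = cv$averaged_nu,
    n_support_vectors = length(model$support_indices)
  )
  if (pos == "control") {
    s$true_negative_pct <- cv$positive_inlier_pct
    s$true_positive_pct <- cv$negative_outlier_pct
  } else {
    s$pct_patients_nonoutlier <- cv$positive_inlier_pct
    s$pct_controls_outlier <- cv$negative_outlier_pct
  }
  if (!is.null(permutation)) {
    s$p_true_positive <- permutation$p_tp
    s$p_true_negative <- permutation$p_tn
    s$n_permutations <- permutation$n_permutations
  }
  if (!is.null(subgroups)) {
    s$pct_outliers_responded <-
      subgroups$pct_responders[subgroups$outlier]
    s$pct_nonoutliers_responded <-
      subgroups$pct_responders[!subgroups$outlier]
  }
  if (!is.null(correlations)) {
    s$correlation_all <- correlations$r[correlations$subset == "all"]
    s$correlation_responders <-
      correlations$r[correlations$subset == "responders"]
    s$correlation_nonresponders <-
      correlations$r[correlations$subset == "non-responders"]
    s$correlation_all_p <- correlations$p_value[correlations$subset == "all"]
  }
  s
}

validate_summary <- function(s) {
  required <- c("positive_class", "feature_kind", "kernel", "n_folds",
                "averaged_gamma", "averaged_nu", "n_support_vectors")
  missing <- setdiff(required, names(s))
  if (length(missing) > 0) {
    abort(sprintf("summary is missing field(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "ocb_schema_error")
  }
  num_fields <- intersect(names(s), c("n_folds", "averaged_gamma",
                                      "averaged_nu", "n_support_vectors",
                                      "true_negative_pct",
                                      "true_positive_pct"))
  bad <- num_fields[!vapply(s[num_fields],
                            function(v) is.numeric(v) && all(is.finite(v)),
                            logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("summary field(s) not finite numeric: %s.",
                  paste(bad, collapse = ", ")),
          class = "ocb_schema_error")
  }
  invisible(s)
}

write_run_outputs <- function(output_dir, summary, cv, maps) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sf <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ff <- file.path(output_dir, "folds.tsv")
  utils::write.table(as.data.frame(tidy(cv)), ff, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(summary = sf, folds = ff)
  if (!is.null(maps)) {
    write_map(maps$weight, output_dir, prefix = "weight")
    write_map(maps$weight_rescaled, output_dir, prefix = "weight_rescaled")
    write_map(maps$t, output_dir, prefix = "tmap")
  }
  files
}

#' @export
print.ocb_run <- function(x, ...) {
  cat("Normality-boundary pipeline run\n")
  print(x$cv)
  if (!is.null(x$correlations)) {
    cat("Severity correlations:\n")
    print(x$correlations)
  }
  invisible(x)
}
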