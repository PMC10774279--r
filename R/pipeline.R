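#' Assemble a full run configuration
#'
#' Single configuration object for the end-to-end analysis: simulate the
#' training and testing cohorts, build seed-connectivity features, select
#' regions on the training sample, train and cross-validate the classifier,
#' test on the holdout, and run the group statistics. All seeds live in the
#' config; nothing is seeded from the clock.
#'
#' @param train_cohort a [cohort_spec()] for the training sample (two
#'   groups; default 30 unipolar + 30 bipolar).
#' @param test_cohort a [cohort_spec()] for the independent testing sample
#'   (default 15 unipolar + 15 converted-bipolar on the same grid).
#' @param selection a [selection_config()].
#' @param classifier a [classifier_config()].
#' @param trim initial frames to drop per run.
#' @param bandpass passband in Hz, or `NULL`.
#' @param top_k regions carried into the group statistics (default 10).
#' @return A `run_config`.
#' @export
run_config <- function(train_cohort = cohort_spec(),
                       test_cohort = cohort_spec(
                         n_per_group = c(UD = 15L, tBD = 15L),
                         rng_seed = train_cohort$rng_seed + 1000L),
                       selection = selection_config(),
                       classifier = classifier_config(),
                       trim = 10L, bandpass = c(0.01, 0.08), top_k = 10L) {
  for (field in c("grid_shape", "n_regions", "seed_region_ids")) {
    if (!identical(train_cohort[[field]], test_cohort[[field]]))
      stop("config error: train and test cohorts disagree on '", field, "'")
  }
  structure(list(train_cohort = train_cohort, test_cohort = test_cohort,
                 selection = selection, classifier = classifier,
                 trim = as.integer(trim), bandpass = bandpass,
                 top_k = as.integer(top_k)),
            class = "run_config")
}

#' Write a run configuration to JSON
#'
#' Named maps (group counts, group couplings) are written as JSON objects so
#' they round-trip through [read_run_config()].
#'
#' @param config a [run_config()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  as_plain <- function(cs) {
    out <- unclass(cs)
    out$n_per_group <- as.list(out$n_per_group)
    if (!is.null(out$coupling_by_group))
      out$coupling_by_group <- as.list(out$coupling_by_group)
    out
  }
  jsonlite::write_json(
    list(train_cohort = as_plain(config$train_cohort),
         test_cohort = as_plain(config$test_cohort),
         selection = unclass(config$selection),
         classifier = unclass(config$classifier),
         trim = config$trim, bandpass = config$bandpass,
         top_k = config$top_k),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with fields mirroring [run_config()]; cohort specs
#'   as plain objects.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("config error: missing field '", field, "' in ", where)
    x[[field]]
  }
  mk_cohort <- function(cs, where) {
    args <- cs[intersect(names(cs), names(formals(cohort_spec)))]
    args$n_per_group <- unlist(need(cs, "n_per_group", where))
    if (!is.null(cs$coupling_by_group))
      args$coupling_by_group <- unlist(cs$coupling_by_group)
    do.call(cohort_spec, args)
  }
  tr <- mk_cohort(need(raw, "train_cohort", "config"), "train_cohort")
  te <- mk_cohort(need(raw, "test_cohort", "config"), "test_cohort")
  sel <- do.call(selection_config, as.list(
    raw$selection[intersect(names(raw$selection),
                            names(formals(selection_config)))]))
  cls_fields <- raw$classifier[intersect(names(raw$classifier),
                                         names(formals(classifier_config)))]
  cls <- do.call(classifier_config, as.list(cls_fields))
  run_config(tr, te, sel, cls,
             trim = if (is.null(raw$trim)) 10L else raw$trim,
             bandpass = if (is.null(raw$bandpass)) c(0.01, 0.08)
                        else unlist(raw$bandpass),
             top_k = if (is.null(raw$top_k)) 10L else raw$top_k)
}

# content hash of an R object: 32-bit polynomial rolling checksum over the
# version-pinned serialized bytes (double arithmetic stays exact below 2^53)
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 4294967291
  sprintf("%010.0f", h)
}

#' Execute the full analysis pipeline
#'
#' Stages, in order: simulate (training + testing cohorts), fc (feature
#' matrices), select (region-based selection on the training sample), train
#' (penalty grid search + final fit + stratified eightfold CV with selection
#' re-run inside each fold), test (frozen classifier on the holdout), stats
#' (three-group regional comparisons and scale correlations on all
#' subjects). Writes stage outputs and a manifest to `out_dir`; the manifest
#' contains seeds, versions and content hashes but no timestamps, so a rerun
#' with the same config is bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param n_permutations permutations for the CV significance test; 0 (the
#'   default here) skips the permutation stage component.
#' @return Invisibly, a list with the manifest and the main stage objects.
#' @export
run_full_pipeline <- function(config, out_dir, n_permutations = 0L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate ------------------------------------------------------------
  atlas <- stage("simulate", build_toy_atlas(
    config$train_cohort$grid_shape, config$train_cohort$n_regions,
    config$train_cohort$seed_region_ids, config$train_cohort$rng_seed))
  train <- stage("simulate", simulate_cohort(config$train_cohort, atlas))
  test <- stage("simulate", simulate_cohort(config$test_cohort, atlas))

  # -- fc ------------------------------------------------------------------
  fc_args <- list(atlas = atlas, trim = config$trim,
                  bandpass = config$bandpass)
  feat_tr <- stage("fc", do.call(build_feature_matrix,
                                 c(list(train$runs), fc_args)))
  feat_te <- stage("fc", do.call(build_feature_matrix,
                                 c(list(test$runs), fc_args)))

  # -- select + train ------------------------------------------------------
  clf <- stage("train", train_classifier(
    feat_tr$values, train$subjects$group, feat_tr$registry,
    config$selection, config$classifier, atlas$region_names))
  sel_hook <- selection_hook(feat_tr$registry, config$selection)
  cv <- stage("train", stratified_kfold_eval(
    feat_tr$values, train$subjects$group, config$classifier,
    selection_hook = if (config$classifier$refit_selection_per_fold)
      sel_hook else NULL,
    C = clf$chosen_C))
  perm <- NULL
  if (n_permutations > 0L) {
    pcfg <- config$classifier
    pcfg$n_permutations <- as.integer(n_permutations)
    hook <- cv_accuracy_hook(feat_tr$registry, config$selection, pcfg,
                             C = clf$chosen_C)
    perm <- stage("train", permutation_significance(
      feat_tr$values, train$subjects$group, pcfg, hook))
  }

  # -- test ----------------------------------------------------------------
  test_positive <- intersect(c("tBD", "BD"), unique(test$subjects$group))[1]
  test_eval <- stage("test", holdout_test(
    clf, feat_te$values, test$subjects$group, feat_te$registry,
    positive_class = test_positive))

  # -- stats ---------------------------------------------------------------
  all_values <- rbind(feat_tr$values, feat_te$values)
  all_subjects <- rbind(train$subjects, test$subjects)
  stats_out <- NULL
  if (length(unique(all_subjects$group)) == 3L) {
    stats_out <- stage("stats", list(
      table2 = table2_analysis(all_values, feat_tr$registry,
                               all_subjects$group, clf$selection,
                               config$top_k),
      correlations = fc_scale_correlations(all_values, feat_tr$registry,
                                           all_subjects, clf$selection,
                                           k = config$top_k)))
  }

  # -- outputs -------------------------------------------------------------
  sel_path <- file.path(out_dir, "region_selection.tsv")
  write_region_table(clf$selection, sel_path)
  eval_path <- file.path(out_dir, "eval_report.json")
  report <- list(
    cv = list(per_fold = cv$per_fold, mean_accuracy = cv$mean_accuracy,
              mean_sensitivity = cv$mean_sensitivity,
              mean_specificity = cv$mean_specificity, auc = cv$auc,
              chosen_C = cv$chosen_C,
              permutation_p = if (is.null(perm)) NULL else perm$p_value),
    test = list(accuracy = test_eval$mean_accuracy,
                sensitivity = test_eval$mean_sensitivity,
                specificity = test_eval$mean_specificity,
                auc = test_eval$auc, positive_class = test_positive))
  jsonlite::write_json(report, eval_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  pred_path <- file.path(out_dir, "test_predictions.tsv")
  utils::write.table(
    data.frame(subject_id = test$subjects$subject_id,
               group = test$subjects$group,
               prediction = test_eval$predictions,
               score = sprintf("%.12g", test_eval$scores)),
    pred_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(stats_out)) {
    utils::write.table(format(stats_out$table2, digits = 10, trim = TRUE),
                       file.path(out_dir, "table2_regional_anova.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(format(stats_out$correlations, digits = 10,
                              trim = TRUE),
                       file.path(out_dir, "fc_scale_correlations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("limbicscreen")),
    stages = c("simulate", "fc", "select", "train", "test", "stats"),
    seeds = list(train_cohort = config$train_cohort$rng_seed,
                 test_cohort = config$test_cohort$rng_seed,
                 selection = config$selection$rng_seed,
                 classifier = config$classifier$rng_seed),
    config_hash = content_hash(unclass(config)),
    input_hashes = list(train_features = content_hash(feat_tr$values),
                        test_features = content_hash(feat_te$values)),
    output_hashes = list(region_selection = content_hash(clf$selection),
                         eval_report = content_hash(report)),
    outputs = c("region_selection.tsv", "eval_report.json",
                "test_predictions.tsv",
                if (!is.null(stats_out)) c("table2_regional_anova.tsv",
                                           "fc_scale_correlations.tsv")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, classifier = clf, cv = cv,
                 test = test_eval, permutation = perm, stats = stats_out,
                 atlas = atlas,
                 features = list(train = feat_tr, test = feat_te),
                 subjects = list(train = train$subjects,
                                 test = test$subjects)))
}

#' Feature-selection hook for cross-validation
#'
#' Wraps [select_features()] as a `function(values, labels) -> voxel index
#' vector` bound to a fixed registry and selection config, for use inside
#' [stratified_kfold_eval()].
#'
#' @param registry a [voxel_registry()].
#' @param sel_config a [selection_config()].
#' @return A closure.
#' @export
selection_hook <- function(registry, sel_config = selection_config()) {
  force(registry); force(sel_config)
  function(values, labels)
    select_features(values, labels, registry, sel_config)$mask
}

#' Mean-CV-accuracy hook for permutation testing
#'
#' Builds the `pipeline_hook` used by [permutation_significance()]: each call
#' runs the leakage-free stratified K-fold evaluation (selection re-run per
#' fold) and returns the mean accuracy.
#'
#' @param registry a [voxel_registry()].
#' @param sel_config a [selection_config()].
#' @param config a [classifier_config()].
#' @param C penalty used in every fold.
#' @return A closure `function(values, labels) -> numeric`.
#' @export
cv_accuracy_hook <- function(registry, sel_config = selection_config(),
                             config = classifier_config(), C = 1) {
  force(registry); force(sel_config); force(config); force(C)
  hook <- selection_hook(registry, sel_config)
  function(values, labels)
    stratified_kfold_eval(values, labels, config, hook, C)$mean_accuracy
}
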