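#' Pipeline run configuration
#'
#' A fully serialisable description of one end-to-end run: a run is
#' reproducible from its manifest alone.
#'
#' @param seed integer RNG seed for the whole run.
#' @param sizes hands per grade A/B/C/D.
#' @param noise_scale multiplier on noise and drift (0 = analytic
#'   templates).
#' @param disagreement_rate fraction of hands with a clinically discordant
#'   label.
#' @param margin safety margin of the grade-conditional draws.
#' @param slope_threshold critical-point detection threshold.
#' @param problems,label_sources,feature_sets,classifiers evaluation scope
#'   (see [evaluate_all()]).
#' @param svm_cost,knn_k classifier parameters.
#' @param run_selection run the hybrid wrapper feature selection on the
#'   2-class NCS problem (the most expensive stage; disable for quick
#'   runs).
#' @return A list of class `ncs_run_config`.
#' @export
run_config <- function(seed = 1, sizes = c(A = 19, B = 10, C = 17, D = 19),
                       noise_scale = 1, disagreement_rate = 0,
                       margin = 0.1, slope_threshold = 0.05,
                       problems = c(2, 3), label_sources = c("ncs", "clinical"),
                       feature_sets = c("common", "novel", "all"),
                       classifiers = c("SVM", "kNN", "DT", "NB"),
                       svm_cost = 0.9, knn_k = 5, run_selection = FALSE) {
  structure(
    list(seed = as.integer(seed), sizes = sizes, noise_scale = noise_scale,
         disagreement_rate = disagreement_rate, margin = margin,
         slope_threshold = slope_threshold, problems = problems,
         label_sources = label_sources, feature_sets = feature_sets,
         classifiers = classifiers, svm_cost = svm_cost, knn_k = knn_k,
         run_selection = run_selection),
    class = "ncs_run_config"
  )
}

#' Run the full pipeline and write a report bundle
#'
#' Generate -> preprocess -> extract -> grade -> evaluate (-> select), then
#' write the cohort container, the critical-point annotations, the feature
#' table, the grades, the accuracy tables, the confusion matrices and a
#' JSON manifest (config + package version) into `out_dir`. Identical
#' configurations produce byte-identical bundles.
#'
#' @param config an [run_config()] object.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with `cohort`, `features`, `evaluation`,
#'   `selection` (or `NULL`) and `manifest_path`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("ncsrun")) {
  stopifnot(inherits(config, "ncs_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(sizes = config$sizes,
                            disagreement_rate = config$disagreement_rate,
                            seed = config$seed,
                            noise_scale = config$noise_scale,
                            margin = config$margin)
  write_cohort(cohort, file.path(out_dir, "cohort"))

  ann <- annotate_cohort(cohort, slope_threshold = config$slope_threshold)
  utils::write.csv(ann, file.path(out_dir, "annotations.csv"),
                   row.names = FALSE)

  features <- extract_features(cohort,
                               slope_threshold = config$slope_threshold)
  features <- grade_cohort(features)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(
    features[, c("hand_id", "true_grade", "clinical_label", "ncs_grade")],
    file.path(out_dir, "grades.csv"), row.names = FALSE)

  evaluation <- evaluate_all(features, problems = config$problems,
                             label_sources = config$label_sources,
                             feature_sets = config$feature_sets,
                             classifiers = config$classifiers,
                             svm_cost = config$svm_cost,
                             knn_k = config$knn_k)
  utils::write.csv(evaluation$accuracy,
                   file.path(out_dir, "accuracy.csv"), row.names = FALSE)
  conf_json <- lapply(evaluation$confusion, function(cm) {
    list(matrix = cm$matrix, row_rates = cm$row_rates,
         col_rates = cm$col_rates, accuracy = cm$accuracy, n = cm$n)
  })
  jsonlite::write_json(conf_json,
                       file.path(out_dir, "confusion_matrices.json"),
                       digits = NA, pretty = TRUE)

  selection <- NULL
  if (isTRUE(config$run_selection)) {
    y2 <- class_labels(features$ncs_grade, 2)
    X <- features[, feature_columns(features, "all"), drop = FALSE]
    selection <- hybrid_feature_selection(
      X, y2,
      knn_config = classifier_config("kNN", problem = 2,
                                     knn_k = config$knn_k),
      svm_config = classifier_config("SVM", problem = 2,
                                     svm_cost = config$svm_cost))
    jsonlite::write_json(
      list(selected = selection$selected,
           accuracy_knn = selection$accuracy_knn,
           accuracy_svm = selection$accuracy_svm,
           trace = selection$trace),
      file.path(out_dir, "selection_trace.json"), digits = NA,
      pretty = TRUE)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(config),
         package = "ncscts",
         version = as.character(utils::packageVersion("ncscts"))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, features = features,
                 evaluation = evaluation, selection = selection,
                 manifest_path = manifest_path))
}

#' Reload a run configuration from a manifest
#'
#' @param path path to a `manifest.json` written by [run_pipeline()].
#' @return The [run_config()] stored in the manifest; re-running it yields
#'   a byte-identical feature table.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  run_config(seed = cfg$seed, sizes = unlist(cfg$sizes),
             noise_scale = cfg$noise_scale,
             disagreement_rate = cfg$disagreement_rate,
             margin = cfg$margin, slope_threshold = cfg$slope_threshold,
             problems = cfg$problems, label_sources = cfg$label_sources,
             feature_sets = cfg$feature_sets,
             classifiers = cfg$classifiers, svm_cost = cfg$svm_cost,
             knn_k = cfg$knn_k, run_selection = cfg$run_selection)
}
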