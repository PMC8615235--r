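#' Confusion matrix with per-row and per-column rates
#'
#' Rows are actual classes, columns predicted classes. Row rates are
#' row-correct / row-total (per-class sensitivity/recall), column rates
#' column-correct / column-total (precision), and the overall accuracy is
#' the diagonal sum over the total count.
#'
#' @param y_true,y_pred equal-length label vectors; `y_pred` is coerced to
#'   the levels of `y_true`.
#' @return A list of class `ncs_confusion`: `matrix` (integer counts),
#'   `row_rates`, `col_rates`, `accuracy`, `n`.
#' @export
confusion_and_rates <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length")
  }
  y_true <- as.factor(y_true)
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  m <- table(actual = y_true, predicted = y_pred)
  diag_m <- diag(m)
  structure(
    list(matrix = unclass(m),
         row_rates = ifelse(rowSums(m) > 0, diag_m / rowSums(m), NA_real_),
         col_rates = ifelse(colSums(m) > 0, diag_m / colSums(m), NA_real_),
         accuracy = sum(diag_m) / sum(m),
         n = sum(m)),
    class = "ncs_confusion"
  )
}

#' @export
print.ncs_confusion <- function(x, digits = 3, ...) {
  m <- x$matrix
  out <- cbind(format(m), rate = format(round(x$row_rates, digits)))
  print(out, quote = FALSE)
  cat(" rate:", paste(format(round(x$col_rates, digits)), collapse = " "),
      sprintf("| accuracy %.4f (n = %d)\n", x$accuracy, x$n))
  invisible(x)
}

#' Evaluate all classifiers on the 2-, 3- and 4-class problems
#'
#' Runs LOOCV for the requested classifiers on every combination of
#' classification problem, label source and feature set. NCS labels (the
#' neurophysiological grades) support the 2-, 3- and 4-class problems;
#' clinical labels distinguish three groups only, so clinical 4-class
#' combinations are not evaluated.
#'
#' @param features a feature table from [extract_features()], optionally
#'   already carrying an `ncs_grade` column (else grades are computed with
#'   the default rules).
#' @param problems subset of `c(2, 3, 4)`.
#' @param label_sources subset of `c("ncs", "clinical")`.
#' @param feature_sets subset of `c("common", "novel", "all")`.
#' @param classifiers subset of `c("LR", "SVM", "kNN", "DT", "NB")`.
#' @param svm_cost,knn_k classifier parameters (see
#'   [classifier_config()]).
#' @param rules grading rules used if `ncs_grade` is absent.
#' @return A list of class `ncs_evaluation`: `accuracy` (long-format
#'   data.frame: problem, source, set, classifier, accuracy) and
#'   `confusion` (named list of `ncs_confusion`, keyed
#'   `problem.source.set.classifier`).
#' @export
evaluate_all <- function(features, problems = c(2, 3, 4),
                         label_sources = c("ncs", "clinical"),
                         feature_sets = c("common", "novel", "all"),
                         classifiers = c("LR", "SVM", "kNN", "DT", "NB"),
                         svm_cost = 0.9, knn_k = 5,
                         rules = grade_rules()) {
  label_sources <- match.arg(label_sources, several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (is.null(features$ncs_grade) && "ncs" %in% label_sources) {
    features <- grade_cohort(features, rules)
  }
  combos <- expand.grid(problem = problems, source = label_sources,
                        stringsAsFactors = FALSE)
  combos <- combos[!(combos$source == "clinical" & combos$problem == 4), ]
  if (nrow(combos) == 0L) {
    stop("clinical grading has three groups only; ",
         "the 4-class problem is not defined against clinical labels")
  }
  acc <- list()
  conf <- list()
  k <- 0L
  for (ci in seq_len(nrow(combos))) {
    p <- combos$problem[ci]
    src <- combos$source[ci]
    labels <- if (src == "ncs") {
      class_labels(features$ncs_grade, p)
    } else {
      clinical_class_labels(features$clinical_label, p)
    }
    for (set in feature_sets) {
      X <- features[, feature_columns(features, set), drop = FALSE]
      for (cl in classifiers) {
        cfg <- classifier_config(cl, problem = p, svm_cost = svm_cost,
                                 knn_k = knn_k)
        res <- loocv(X, labels, cfg)
        k <- k + 1L
        acc[[k]] <- data.frame(problem = p, source = src, set = set,
                               classifier = cl, accuracy = res$accuracy,
                               stringsAsFactors = FALSE)
        conf[[paste(p, src, set, cl, sep = ".")]] <- res$confusion
      }
    }
  }
  structure(list(accuracy = do.call(rbind, acc), confusion = conf),
            class = "ncs_evaluation")
}

#' @export
print.ncs_evaluation <- function(x, ...) {
  a <- x$accuracy
  for (p in unique(a$problem)) {
    for (src in unique(a$source[a$problem == p])) {
      sub <- a[a$problem == p & a$source == src, ]
      wide <- stats::reshape(sub[, c("classifier", "set", "accuracy")],
                             idvar = "classifier", timevar = "set",
                             direction = "wide")
      names(wide) <- sub("^accuracy\\.", "", names(wide))
      cat(sprintf("-- %d-class problem, %s labels --\n", p, src))
      print(wide, row.names = FALSE, digits = 4)
    }
  }
  invisible(x)
}
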