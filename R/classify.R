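#' Classifier configuration
#'
#' One of five classifier families: logistic regression (`"LR"`,
#' multinomial for more than two classes), support vector machine
#' (`"SVM"`; linear kernel for the 2-class problem, RBF with cost 0.9
#' otherwise), k-nearest neighbours (`"kNN"`, default 5 neighbours,
#' deterministic smallest-class tie-break), decision tree (`"DT"`, depth
#' cap 8) and Gaussian naive Bayes (`"NB"`). Features are median-imputed
#' and z-score standardised with training-fold statistics before
#' distance/kernel/linear methods.
#'
#' @param kind classifier family.
#' @param problem 2, 3 or 4; selects the default SVM kernel.
#' @param svm_cost SVM cost parameter (default 0.9).
#' @param svm_kernel `"linear"` or `"radial"`; defaults to linear for the
#'   2-class problem and radial otherwise.
#' @param knn_k number of neighbours (default 5).
#' @param maxdepth decision-tree depth cap.
#' @return A list of class `ncs_classifier_config`.
#' @export
classifier_config <- function(kind = c("SVM", "kNN", "LR", "DT", "NB"),
                              problem = 2, svm_cost = 0.9,
                              svm_kernel = NULL, knn_k = 5, maxdepth = 8) {
  kind <- match.arg(kind)
  if (is.null(svm_kernel)) {
    svm_kernel <- if (problem == 2) "linear" else "radial"
  }
  stopifnot(svm_cost > 0, knn_k >= 1)
  structure(list(kind = kind, problem = problem, svm_cost = svm_cost,
                 svm_kernel = svm_kernel, knn_k = as.integer(knn_k),
                 maxdepth = maxdepth),
            class = "ncs_classifier_config")
}

# median-impute and z-score both folds with training-fold statistics
.prep_fold <- function(Xtr, Xte) {
  Xtr <- as.matrix(Xtr)
  Xte <- as.matrix(Xte)
  med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(Xtr))) {
    Xtr[is.na(Xtr[, j]), j] <- med[j]
    Xte[is.na(Xte[, j]), j] <- med[j]
  }
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

# exact small-n Euclidean kNN with deterministic tie-breaking:
# neighbour distance ties resolved by row index, vote ties by smallest
# class level
.knn_predict <- function(Xtr, ytr, Xte, k) {
  k <- min(k, nrow(Xtr))
  lev <- levels(ytr)
  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d <- sqrt(rowSums(sweep(Xtr, 2, Xte[i, ])^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(ytr[nb], levels = lev))
    out[i] <- lev[which.max(votes)]
  }
  factor(out, levels = lev)
}

# fit on (Xtr, ytr), predict labels for Xte; deterministic for every kind
.fit_predict <- function(config, Xtr, ytr, Xte) {
  lev <- levels(ytr)
  if (length(unique(ytr)) < 2L) {
    # degenerate training fold: predict the only class present
    return(factor(rep(as.character(ytr[1]), nrow(Xte)), levels = lev))
  }
  pr <- .prep_fold(Xtr, Xte)
  pred <- switch(
    config$kind,
    SVM = {
      fit <- e1071::svm(x = pr$tr, y = ytr, kernel = config$svm_kernel,
                        cost = config$svm_cost, scale = FALSE)
      stats::predict(fit, pr$te)
    },
    kNN = .knn_predict(pr$tr, ytr, pr$te, config$knn_k),
    LR = {
      df <- data.frame(pr$tr, check.names = FALSE)
      df$.cls <- ytr
      fit <- nnet::multinom(.cls ~ ., data = df, trace = FALSE,
                            maxit = 200, MaxNWts = 100000, decay = 1e-4)
      nd <- data.frame(pr$te, check.names = FALSE)
      p <- stats::predict(fit, newdata = nd)
      factor(as.character(p), levels = lev)
    },
    DT = {
      df <- data.frame(pr$tr, check.names = FALSE)
      df$.cls <- ytr
      fit <- rpart::rpart(.cls ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = config$maxdepth, xval = 0))
      nd <- data.frame(pr$te, check.names = FALSE)
      p <- stats::predict(fit, newdata = nd, type = "class")
      factor(as.character(p), levels = lev)
    },
    NB = {
      fit <- e1071::naiveBayes(pr$tr, ytr)
      # variance floor: zero within-class variance would give degenerate
      # Gaussian densities on noiseless synthetic data
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      stats::predict(fit, pr$te)
    }
  )
  factor(as.character(pred), levels = lev)
}

#' Leave-one-out cross-validation of one classifier
#'
#' Trains on N - 1 rows and predicts the held-out row, N times. Imputation
#' and standardisation statistics are recomputed inside every training
#' fold, so no information from the held-out row leaks into training.
#' Deterministic: every classifier in the package is itself deterministic
#' and ties are broken by fixed rules.
#'
#' @param X feature matrix or data.frame (rows = hands).
#' @param y class labels (factor or coercible).
#' @param config an [classifier_config()] object.
#' @return A list of class `ncs_loocv`: `accuracy`, `predicted`, `truth`,
#'   `confusion` (an `ncs_confusion`, see [confusion_and_rates()]).
#' @export
loocv <- function(X, y, config) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  if (n < 2L || nlevels(y) < 2L) {
    stop("LOOCV needs at least two rows and two classes")
  }
  if (any(apply(X, 1, function(r) all(is.na(r))))) {
    stop("rows with all-missing features cannot be evaluated")
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    pred[i] <- .fit_predict(config, X[-i, , drop = FALSE], y[-i],
                            X[i, , drop = FALSE])
  }
  structure(list(accuracy = mean(pred == y), predicted = pred, truth = y,
                 confusion = confusion_and_rates(y, pred)),
            class = "ncs_loocv")
}

#' @export
print.ncs_loocv <- function(x, ...) {
  cat(sprintf("<ncs_loocv> accuracy %.4f on %d instances\n",
              x$accuracy, length(x$truth)))
  invisible(x)
}

#' LOOCV accuracy
#'
#' @inheritParams loocv
#' @return The leave-one-out accuracy (correct / N).
#' @export
loocv_accuracy <- function(X, y, config) {
  loocv(X, y, config)$accuracy
}

#' Single-feature parameter tuning
#'
#' For every value of the parameter grid, runs single-feature LOOCV for
#' every feature column and scores the value by the number of features
#' whose accuracy comes within `tol` of that feature's best accuracy over
#' the grid; the value reaching the highest count wins (ties go to the
#' smallest value). This operationalises picking the parameter "with many
#' features presenting high accuracy".
#'
#' @param X feature matrix or data.frame.
#' @param y class labels.
#' @param kind `"SVM"` (tunes cost over 0.1..3 by 0.1) or `"kNN"` (tunes
#'   the neighbour count over 1..11).
#' @param grid optional explicit parameter grid.
#' @param problem 2, 3 or 4 (selects the SVM kernel).
#' @param tol closeness tolerance on accuracy (default 0.01).
#' @return A list of class `ncs_tuning`: `best`, `counts` (per grid
#'   value), `accuracy` (features x grid matrix).
#' @export
tune_parameter <- function(X, y, kind = c("SVM", "kNN"), grid = NULL,
                           problem = 2, tol = 0.01) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- if (kind == "SVM") seq(0.1, 3, by = 0.1) else 1:11
  }
  stopifnot(length(grid) >= 1L)
  X <- as.matrix(X)
  acc <- matrix(NA_real_, nrow = ncol(X), ncol = length(grid),
                dimnames = list(colnames(X), as.character(grid)))
  for (g in seq_along(grid)) {
    cfg <- if (kind == "SVM") {
      classifier_config("SVM", problem = problem, svm_cost = grid[g])
    } else {
      classifier_config("kNN", problem = problem, knn_k = grid[g])
    }
    for (f in seq_len(ncol(X))) {
      acc[f, g] <- loocv_accuracy(X[, f, drop = FALSE], y, cfg)
    }
  }
  best_per_feature <- apply(acc, 1, max)
  counts <- colSums(acc >= best_per_feature - tol)
  best <- grid[which.max(counts)]   # which.max takes the first = smallest
  structure(list(best = best, counts = counts, accuracy = acc,
                 grid = grid, kind = kind),
            class = "ncs_tuning")
}

#' @export
print.ncs_tuning <- function(x, ...) {
  cat(sprintf("<ncs_tuning> %s: best value %g (%d/%d features near their max)\n",
              x$kind, x$best, max(x$counts), nrow(x$accuracy)))
  invisible(x)
}
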