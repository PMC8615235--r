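#' Two-phase hybrid wrapper feature selection
#'
#' A custom combination of sequential backward and forward selection,
#' wrapped around two classifiers (kNN and SVM by default). Phase 1 scans
#' the features in fixed column order; each feature is tentatively removed
#' and both wrappers' LOOCV accuracies are recomputed. By default a feature
#' is permanently dropped iff its removal degrades neither classifier
#' (both accuracies stay at or above their current values); with
#' `literal = TRUE` the rule is instead "drop iff neither classifier
#' improved", which can discard accuracy-critical features and is kept
#' only as an alternative reading. Phase 2 starts from the phase-1
#' survivors and re-adds each dropped feature, in the same scan order,
#' keeping it iff at least one wrapper's accuracy strictly increases.
#'
#' @param X feature matrix or data.frame with named columns.
#' @param y class labels.
#' @param knn_config,svm_config the two wrapper configurations.
#' @param literal use the literal phase-1 drop rule (see above).
#' @return A list of class `ncs_selection`: `selected` (column names in
#'   original order), `accuracy_knn`, `accuracy_svm` (of the final set),
#'   `trace` (one row per tentative decision: phase, step, feature,
#'   action, acc_knn, acc_svm).
#' @export
hybrid_feature_selection <- function(X, y,
                                     knn_config = classifier_config("kNN"),
                                     svm_config = classifier_config("SVM"),
                                     literal = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 2L) {
    if (ncol(X) == 0L) stop("no features to select from")
  }
  y <- droplevels(as.factor(y))
  cols <- colnames(X)
  keep <- rep(TRUE, length(cols))
  acc2 <- function(mask) {
    if (!any(mask)) return(c(0, 0))
    Xm <- X[, mask, drop = FALSE]
    c(loocv_accuracy(Xm, y, knn_config), loocv_accuracy(Xm, y, svm_config))
  }
  cur <- acc2(keep)
  trace <- list()
  step <- 0L
  note <- function(phase, feature, action, a) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(step = step, phase = phase,
                                 feature = feature, action = action,
                                 acc_knn = a[1], acc_svm = a[2],
                                 stringsAsFactors = FALSE)
  }

  dropped <- character(0)
  for (j in seq_along(cols)) {
    if (sum(keep) <= 1L) { note(1L, cols[j], "skip", cur); next }
    cand <- keep
    cand[j] <- FALSE
    a <- acc2(cand)
    drop_it <- if (literal) {
      a[1] <= cur[1] && a[2] <= cur[2]
    } else {
      a[1] >= cur[1] && a[2] >= cur[2]
    }
    if (drop_it) {
      keep <- cand
      cur <- a
      dropped <- c(dropped, cols[j])
      note(1L, cols[j], "drop", a)
    } else {
      note(1L, cols[j], "keep", a)
    }
  }

  for (f in dropped) {
    j <- match(f, cols)
    cand <- keep
    cand[j] <- TRUE
    a <- acc2(cand)
    if (a[1] > cur[1] || a[2] > cur[2]) {
      keep <- cand
      cur <- a
      note(2L, f, "add", a)
    } else {
      note(2L, f, "reject", a)
    }
  }

  if (!any(keep)) stop("no significant features: selection emptied the set")
  structure(
    list(selected = cols[keep], accuracy_knn = cur[1], accuracy_svm = cur[2],
         trace = do.call(rbind, trace)),
    class = "ncs_selection"
  )
}

#' @export
print.ncs_selection <- function(x, ...) {
  cat(sprintf(
    "<ncs_selection> %d feature(s) selected; kNN %.4f, SVM %.4f\n",
    length(x$selected), x$accuracy_knn, x$accuracy_svm))
  utils::head(x$selected, 10) |> paste(collapse = ", ") |> cat("\n")
  invisible(x)
}

#' Replay a selection trace
#'
#' Applies the logged drop/add decisions to the full column set and returns
#' the resulting feature set; replaying the trace of
#' [hybrid_feature_selection()] reproduces its `selected` set exactly.
#'
#' @param trace the `trace` data.frame of an `ncs_selection`.
#' @param columns full column-name vector, in original order.
#' @return Character vector of selected column names.
#' @export
replay_selection <- function(trace, columns) {
  keep <- rep(TRUE, length(columns))
  names(keep) <- columns
  for (i in seq_len(nrow(trace))) {
    f <- trace$feature[i]
    if (trace$action[i] == "drop") keep[f] <- FALSE
    if (trace$action[i] == "add") keep[f] <- TRUE
  }
  columns[keep]
}
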