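#' Grading rule thresholds
#'
#' The Bland-modified four-grade neurophysiological rule set: sensory
#' conduction velocity threshold (index finger to wrist), the two distal
#' motor latency thresholds (wrist to abductor pollicis brevis), and the
#' SNAP-absence amplitude floor.
#'
#' @param cv_threshold sensory CV threshold, m/s (default 40).
#' @param latency_mild_max DML below which motor conduction is considered
#'   preserved, ms (default 4.5).
#' @param latency_severe_min DML above which the hand is severe regardless
#'   of the SNAP, ms (default 6.5).
#' @param snap_absent_amp SNAP amplitude floor, uV (default 2).
#' @return A list of class `grade_rules`.
#' @export
grade_rules <- function(cv_threshold = 40, latency_mild_max = 4.5,
                        latency_severe_min = 6.5, snap_absent_amp = 2) {
  stopifnot(latency_mild_max < latency_severe_min,
            cv_threshold > 0, latency_mild_max > 0, snap_absent_amp > 0)
  structure(list(cv_threshold = cv_threshold,
                 latency_mild_max = latency_mild_max,
                 latency_severe_min = latency_severe_min,
                 snap_absent_amp = snap_absent_amp),
            class = "grade_rules")
}

#' Assign the neurophysiological severity grade
#'
#' Bland-modified four-group rule. With DML the median motor distal (take
#' off) latency, CV the median digit-2 sensory conduction velocity and
#' SNAP the presence flag of the digit-2 sensory response:
#' grade D (severe) if the SNAP is absent with DML at or above 4.5 ms, or
#' DML exceeds 6.5 ms; grade C (moderate) if DML lies in 4.5-6.5 ms with a
#' preserved SNAP; grade B (mild) if DML is below 4.5 ms with slowed
#' (CV < 40 m/s) or absent sensory conduction; otherwise grade A (none).
#' A DML of exactly 4.5 ms goes to C (SNAP present) or D (SNAP absent).
#'
#' @param sensory_cv median digit-2 sensory CV, m/s (may be `NA` when the
#'   SNAP is absent).
#' @param motor_latency median motor distal onset latency, ms.
#' @param snap_present logical: is the digit-2 SNAP detectable?
#' @param rules a [grade_rules()] object.
#' @return Character vector of grades `"A"`..`"D"`. Vectorised over the
#'   three inputs.
#' @export
ncs_grade <- function(sensory_cv, motor_latency, snap_present,
                      rules = grade_rules()) {
  n <- max(length(sensory_cv), length(motor_latency), length(snap_present))
  cv <- rep_len(sensory_cv, n)
  lat <- rep_len(motor_latency, n)
  snap <- rep_len(snap_present, n)
  if (anyNA(lat)) stop("motor latency is required for grading")
  if (anyNA(snap)) stop("the SNAP presence flag is required for grading")
  if (anyNA(cv[snap])) {
    stop("sensory CV is required for grading when the SNAP is present")
  }
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <-
      if ((!snap[i] && lat[i] >= rules$latency_mild_max) ||
          lat[i] > rules$latency_severe_min) {
        "D"
      } else if (snap[i] && lat[i] >= rules$latency_mild_max &&
                 lat[i] <= rules$latency_severe_min) {
        "C"
      } else if (lat[i] < rules$latency_mild_max &&
                 (!snap[i] || cv[i] < rules$cv_threshold)) {
        "B"
      } else {
        "A"
      }
  }
  out
}

#' Grade every hand of a feature table
#'
#' Applies [ncs_grade()] to the measured quantities stored by
#' [extract_features()].
#'
#' @param features a feature table from [extract_features()].
#' @param rules a [grade_rules()] object.
#' @return `features` with an added `ncs_grade` column.
#' @export
grade_cohort <- function(features, rules = grade_rules()) {
  features$ncs_grade <- ncs_grade(features$sensory_cv, features$dml_ms,
                                  features$snap_present, rules)
  features
}

#' Map grades onto the 2-, 3- or 4-class label scheme
#'
#' The 4-class problem keeps A/B/C/D; the 3-class problem merges B and C
#' into BC; the 2-class problem merges every symptomatic grade into BCD
#' (patients vs controls). Each coarser scheme is a deterministic
#' coarsening of the finer one.
#'
#' @param grades character vector of grades `"A"`..`"D"`.
#' @param problem 2, 3 or 4.
#' @return Factor of class labels with the scheme's levels.
#' @export
class_labels <- function(grades, problem = c(4, 3, 2)) {
  problem <- as.integer(problem[1])
  if (!problem %in% c(2L, 3L, 4L)) stop("`problem` must be 2, 3 or 4")
  stopifnot(all(grades %in% c("A", "B", "C", "D")))
  if (problem == 4L) {
    factor(grades, levels = c("A", "B", "C", "D"))
  } else if (problem == 3L) {
    factor(ifelse(grades == "A", "A",
                  ifelse(grades == "D", "D", "BC")),
           levels = c("A", "BC", "D"))
  } else {
    factor(ifelse(grades == "A", "A", "BCD"), levels = c("A", "BCD"))
  }
}

#' Map clinical labels onto the 2- or 3-class scheme
#'
#' Clinical assessment distinguishes three groups only (control /
#' mild-to-moderate / severe), so the 4-class problem is not defined
#' against clinical labels and is rejected with an explicit message.
#'
#' @param labels character vector of `"control"`, `"mild_moderate"`,
#'   `"severe"`.
#' @param problem 2 or 3.
#' @return Factor of class labels.
#' @export
clinical_class_labels <- function(labels, problem = c(3, 2)) {
  problem <- as.integer(problem[1])
  stopifnot(all(labels %in% c("control", "mild_moderate", "severe")))
  if (problem == 4L) {
    stop("clinical grading has three groups only; ",
         "the 4-class problem is not defined against clinical labels")
  }
  if (!problem %in% c(2L, 3L)) stop("`problem` must be 2 or 3")
  if (problem == 3L) {
    factor(labels, levels = c("control", "mild_moderate", "severe"))
  } else {
    factor(ifelse(labels == "control", "control", "cts"),
           levels = c("control", "cts"))
  }
}
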