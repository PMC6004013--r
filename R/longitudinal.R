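#' Discriminant-score trajectory of one patient under surveillance
#'
#' Scores every STUDY sample of the patient with the fitted discriminant
#' model and orders the predictions by visit. A score rising toward the
#' positive (pre-resection, BC-like) side of the decision threshold over
#' successive visits is the monitoring signal of interest.
#'
#' @param fit A `discriminant_fit`.
#' @param x A corrected `peak_tbl`.
#' @param patient_id The patient to trace.
#' @param which Model to use, `"optimized"` or `"initial"`.
#' @return A `trajectory_series` tibble (`visit_index`, `sample_id`,
#'   `y_hat`, `class_label`) ordered by visit, with the threshold and
#'   patient in attributes.
#' @export
patient_trajectory <- function(fit, x, patient_id,
                               which = c("optimized", "initial")) {
  rows <- x$role == "STUDY" & !is.na(x$patient_id) &
    x$patient_id == patient_id
  if (!any(rows)) abort(paste0("unknown patient: ", patient_id))
  pred <- predict(fit, x, sample_ids = x$sample_id[rows],
                  which = match.arg(which))
  out <- pred[order(pred$visit_index),
              c("visit_index", "sample_id", "y_hat", "class_label")]
  structure(out, class = c("trajectory_series", class(out)),
            patient_id = patient_id, theta = fit$theta)
}

#' Flag a surveillance trajectory for a recurrence-like trend
#'
#' The trend statistic is the Spearman rank correlation of the predicted
#' score with visit order. A series is `rising_toward_BC` when the
#' correlation reaches `rho_cut` and the final score is within `margin`
#' below the decision threshold or above it; `stable` when the
#' correlation is weak and the score never crosses the threshold;
#' `inconsistent` otherwise (non-monotone series with crossings).
#'
#' @param series A [patient_trajectory()] result.
#' @param min_visits Minimum visits required; shorter series return flag
#'   `NA` (withheld).
#' @param rho_cut Rank-correlation cut for a rising trend.
#' @param margin Tolerance below the threshold still counted as reaching
#'   the BC side.
#' @return A `trend_flag` list: `patient_id`, `flag`, `rho`,
#'   `first_crossing` (visit of first `y_hat >= theta`, or `NA`).
#' @export
trend_flag <- function(series, min_visits = 3, rho_cut = 0.6,
                       margin = 0.1) {
  theta <- attr(series, "theta") %||% 0.5
  res <- list(patient_id = attr(series, "patient_id"),
              flag = NA_character_, rho = NA_real_,
              first_crossing = NA_integer_, theta = theta)
  if (nrow(series) < min_visits) {
    return(structure(res, class = "trend_flag"))
  }
  rho <- suppressWarnings(
    stats::cor(series$y_hat, series$visit_index, method = "spearman")
  )
  if (is.na(rho)) rho <- 0  # constant series
  crossings <- which(series$y_hat >= theta)
  res$rho <- rho
  res$first_crossing <- if (length(crossings) > 0)
    series$visit_index[crossings[1]] else NA_integer_
  last <- series$y_hat[nrow(series)]
  res$flag <- if (rho >= rho_cut && last >= theta - margin) {
    "rising_toward_BC"
  } else if (abs(rho) < rho_cut && length(crossings) == 0) {
    "stable"
  } else {
    "inconsistent"
  }
  structure(res, class = "trend_flag")
}

#' @export
print.trend_flag <- function(x, ...) {
  cat(sprintf("patient %s: %s (spearman rho = %.2f, first crossing: %s)\n",
              x$patient_id, x$flag, x$rho,
              ifelse(is.na(x$first_crossing), "none", x$first_crossing)))
  invisible(x)
}

#' Classification accuracy on labelled samples of monitored patients
#'
#' The fraction of correctly classified BC/CTRL-labelled samples among
#' patients who also have MONITOR samples — how well the model anchors
#' the known endpoints of the surveillance trajectories.
#'
#' @param fit A `discriminant_fit`.
#' @param x A corrected `peak_tbl`.
#' @param which Model to use.
#' @return Accuracy in `[0, 1]`.
#' @export
surveillance_accuracy <- function(fit, x,
                                  which = c("optimized", "initial")) {
  monitored <- unique(x$patient_id[x$role == "STUDY" &
                                     x$class_label %in% "MONITOR"])
  rows <- x$role == "STUDY" & x$patient_id %in% monitored &
    x$class_label %in% fit$classes
  if (!any(rows)) abort("no labelled samples among monitored patients")
  pred <- predict(fit, x, sample_ids = x$sample_id[rows],
                  which = match.arg(which))
  mean(pred$predicted == pred$class_label)
}
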