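#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline labs
#'   facet_wrap autoplot
NULL

#' RMSECV curve of a cross-validated PLS-DA model
#'
#' @param object A [plsda_cv()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plsda_cv <- function(object, ...) {
  ggplot(object, aes(x = .data$n_lv, y = .data$rmsecv)) +
    geom_line() + geom_point() +
    labs(x = "latent variables", y = "RMSECV (leave-one-patient-out)")
}

#' QC principal-component scores against injection order
#'
#' Visual check that, after correction, QC scores no longer track the
#' injection sequence.
#'
#' @param diag A [qc_trend_diagnostics()] result.
#' @param pc Score column to show (default `"PC1"`).
#' @return A ggplot.
#' @export
plot_qc_trend <- function(diag, pc = "PC1") {
  ggplot(diag$scores,
         aes(x = .data$injection_order, y = .data[[pc]],
             colour = factor(.data$batch))) +
    geom_point() + geom_line() +
    labs(x = "injection order", y = pc, colour = "batch")
}

#' Cumulative distribution of per-feature QC RSD
#'
#' @param rsd_tbl Tibble with a `rsd_qc` column (e.g. from
#'   [qc_trend_diagnostics()]), optionally a `stage` column to compare
#'   before/after correction.
#' @param threshold Reference RSD line in percent.
#' @return A ggplot.
#' @export
plot_rsd_cdf <- function(rsd_tbl, threshold = 15) {
  p <- ggplot(rsd_tbl, aes(x = .data$rsd_qc))
  if ("stage" %in% names(rsd_tbl)) {
    p <- p + ggplot2::stat_ecdf(aes(colour = .data$stage))
  } else {
    p <- p + ggplot2::stat_ecdf()
  }
  p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    labs(x = "QC RSD (%)", y = "cumulative fraction of features")
}

#' VIP scores with the screening threshold
#'
#' @param vip A [vip_scores()] result.
#' @param threshold Screening cut (default 3).
#' @return A ggplot.
#' @export
plot_vip <- function(vip, threshold = 3) {
  ggplot(vip, aes(x = seq_len(nrow(vip)), y = .data$vip)) +
    geom_point() +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    labs(x = "feature index", y = "VIP")
}

#' Surveillance trajectory of predicted discriminant scores
#'
#' @param series A [patient_trajectory()] result (or several row-bound,
#'   with a `patient_id` column for faceting).
#' @return A ggplot.
#' @export
plot_trajectory <- function(series) {
  theta <- attr(series, "theta") %||% 0.5
  p <- ggplot(series, aes(x = .data$visit_index, y = .data$y_hat)) +
    geom_line() +
    geom_point(aes(colour = .data$class_label)) +
    geom_hline(yintercept = theta, linetype = "dashed") +
    labs(x = "visit", y = "predicted y", colour = "class")
  if ("patient_id" %in% names(series)) {
    p <- p + facet_wrap(~patient_id)
  }
  p
}
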