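#' Multiplicative scatter correction of one profile
#'
#' Ordinary least squares of the sample profile on the reference over the
#' common finite features, `x = a + b * ref`, followed by
#' `(x - a) / b`. Removes per-sample additive offset and multiplicative
#' gain (here: urine dilution and injection-volume variation) relative to
#' the reference profile.
#'
#' @param sample_profile Numeric feature vector.
#' @param reference Reference feature vector (same length).
#' @return The corrected profile; if the fitted slope is numerically zero
#'   (`|b| < 1e-12`) the profile is returned uncorrected with a warning.
#' @export
msc_correct <- function(sample_profile, reference) {
  ok <- is.finite(sample_profile) & is.finite(reference)
  if (sum(ok) < 2) abort("need at least 2 common finite features for MSC")
  b <- stats::cov(reference[ok], sample_profile[ok]) /
    stats::var(reference[ok])
  a <- mean(sample_profile[ok]) - b * mean(reference[ok])
  if (!is.finite(b) || abs(b) < 1e-12) {
    warn("MSC slope ~ 0; sample returned uncorrected")
    return(sample_profile)
  }
  (sample_profile - a) / b
}

#' Per-feature median QC profile
#'
#' The multiplicative-scatter-correction reference: the median over the
#' (corrected) pooled-QC injections, per feature.
#'
#' @param x A `peak_tbl` containing QC samples.
#' @return Named numeric vector over features.
#' @export
msc_reference <- function(x) {
  qc <- which(x$role == "QC")
  if (length(qc) == 0) abort("no QC samples to build the MSC reference")
  apply(intensity_matrix(x)[qc, , drop = FALSE], 2, stats::median,
        na.rm = TRUE)
}

#' Apply MSC row-wise to an intensity matrix
#'
#' @param m Sample-by-feature matrix.
#' @param reference Reference profile (see [msc_reference()]).
#' @return Corrected matrix of the same shape.
#' @export
msc_apply <- function(m, reference) {
  out <- t(apply(m, 1, msc_correct, reference = reference))
  dimnames(out) <- dimnames(m)
  out
}

#' Fit Pareto scaling parameters on training rows
#'
#' Per feature: the train mean and train sample standard deviation; the
#' scale divisor is `sqrt(sd)`. Constant features (sd = 0) are flagged and
#' map to 0 when applied.
#'
#' @param m Train sample-by-feature matrix.
#' @return A `pareto_params` list with `mean`, `sd`, `scale`.
#' @export
pareto_fit <- function(m) {
  if (nrow(m) < 2) abort("need at least 2 train samples")
  mu <- colMeans(m, na.rm = TRUE)
  s <- apply(m, 2, stats::sd, na.rm = TRUE)
  structure(list(mean = mu, sd = s, scale = sqrt(s),
                 constant = s == 0),
            class = "pareto_params")
}

#' Apply Pareto scaling with frozen (train) parameters
#'
#' `z = (x - mean) / sqrt(sd)`; constant features map to 0. Validation
#' data must be scaled with the parameters fitted on the train set only.
#'
#' @param m Sample-by-feature matrix.
#' @param params A [pareto_fit()] result.
#' @return The scaled matrix.
#' @export
pareto_apply <- function(m, params) {
  z <- sweep(m, 2, params$mean, `-`)
  div <- ifelse(params$constant, 1, params$scale)
  z <- sweep(z, 2, div, `/`)
  z[, params$constant] <- 0
  z
}

#' Fit the scaling pipeline (MSC then Pareto) on train data
#'
#' The MSC reference is the per-feature median QC profile; Pareto
#' statistics are computed on the MSC-corrected train rows only, so
#' validation samples are scaled without leakage.
#'
#' @param train_m Train sample-by-feature matrix.
#' @param reference MSC reference profile.
#' @return A `preprocess_params` list.
#' @export
preprocess_fit <- function(train_m, reference) {
  corrected <- msc_apply(train_m, reference)
  structure(list(reference = reference,
                 pareto = pareto_fit(corrected)),
            class = "preprocess_params")
}

#' Apply the frozen scaling pipeline to new data
#'
#' @param m Sample-by-feature matrix (same feature columns as the fit).
#' @param params A [preprocess_fit()] result.
#' @return The MSC-corrected, Pareto-scaled matrix.
#' @export
preprocess_apply <- function(m, params) {
  if (!identical(colnames(m), names(params$reference))) {
    if (!all(names(params$reference) %in% colnames(m))) {
      abort("feature mismatch between data and preprocessing parameters")
    }
    m <- m[, names(params$reference), drop = FALSE]
  }
  pareto_apply(msc_apply(m, params$reference), params$pareto)
}
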