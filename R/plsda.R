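#' Fit a univariate-response PLS model (NIPALS)
#'
#' Partial least squares regression of a coded class membership on the
#' feature matrix, by NIPALS deflation. Per component: weight
#' `w = X'y / ||X'y||`, score `t = Xw`, x-loading `p = X't / t't`,
#' y-loading `q = y't / t't`, then `X <- X - t p'` and `y <- y - q t`.
#' The regression vector is recovered as `b = W (P'W)^-1 q`.
#'
#' @param x Preprocessed sample-by-feature matrix.
#' @param y Numeric coded response (e.g. CTRL = 0, BC = 1).
#' @param n_lv Number of latent variables; must not exceed the rank of the
#'   centered matrix.
#' @return A `plsda_model`: weights `W`, loadings `P`, y-loadings `q`,
#'   train scores `T` (columns mutually orthogonal), centers, coefficients
#'   `b`, `n_lv`.
#' @export
plsda_fit <- function(x, y, n_lv) {
  x <- as.matrix(x)
  if (n_lv < 1) abort("n_lv must be >= 1")
  x_center <- colMeans(x)
  y_center <- mean(y)
  E <- sweep(x, 2, x_center)
  f <- y - y_center
  rk <- qr(E)$rank
  if (n_lv > rk) {
    abort(paste0("n_lv (", n_lv, ") exceeds the rank of the centered ",
                 "train matrix (", rk, ")"))
  }
  p <- ncol(x)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, nrow(x), n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) abort("response deflated to zero")
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(
    W = W, P = P, q = q, T = Tm,
    x_center = x_center, y_center = y_center,
    coefficients = stats::setNames(b, colnames(x)),
    feature_ids = colnames(x), n_lv = n_lv
  ), class = "plsda_model")
}

#' Predict the continuous discriminant score
#'
#' `y_hat = (x - x_center) b + y_center`, deterministic given the model.
#'
#' @param object A `plsda_model`.
#' @param newdata Sample-by-feature matrix preprocessed with the train
#'   parameters; columns must cover the model's features.
#' @param ... Unused.
#' @return Numeric vector of predicted y per row.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    if (!all(object$feature_ids %in% colnames(newdata))) {
      abort("newdata is missing model features")
    }
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_ids)) {
    abort("newdata feature count does not match the model")
  }
  drop(sweep(newdata, 2, object$x_center) %*% object$coefficients) +
    object$y_center
}

#' Leave-one-patient-out cross-validation curve
#'
#' Folds are the distinct patients; every sample of the held-out patient
#' is excluded from fitting. Within each fold Pareto scaling statistics
#' are recomputed on the fold's training rows (the MSC reference comes
#' from QC injections, which contain no patient, so it is fixed upstream),
#' a model with `a_max` components is fitted once, and held-out
#' predictions are accumulated for every component count, giving
#' `RMSECV(A)` for `A = 1..a_max`.
#'
#' @param m MSC-corrected (unscaled) train sample-by-feature matrix.
#' @param y Coded response.
#' @param patient_id Patient label per row.
#' @param a_max Largest component count to evaluate; capped at
#'   `min(a_max, rank - 1)` per fold.
#' @param scale Recompute Pareto scaling inside each fold (default TRUE).
#' @return A `plsda_cv` tibble with columns `n_lv`, `rmsecv`; the fold
#'   composition is kept in the `"folds"` attribute for leakage auditing.
#' @export
plsda_cv <- function(m, y, patient_id, a_max = 15, scale = TRUE) {
  m <- as.matrix(m)
  patients <- unique(patient_id)
  if (length(patients) < 2) abort("leave-one-patient-out needs >= 2 patients")
  a_eff <- min(a_max, qr(scale(m, scale = FALSE))$rank - 1)
  if (a_eff < 1) abort("train matrix rank too low for cross-validation")
  err <- matrix(NA_real_, nrow(m), a_eff)
  folds <- purrr::map(patients, function(pt) {
    hold <- which(patient_id == pt)
    train <- which(patient_id != pt)
    mtr <- m[train, , drop = FALSE]
    mho <- m[hold, , drop = FALSE]
    if (scale) {
      pp <- pareto_fit(mtr)
      mtr <- pareto_apply(mtr, pp)
      mho <- pareto_apply(mho, pp)
    }
    a_fold <- min(a_eff, qr(scale(mtr, scale = FALSE))$rank)
    fit <- plsda_fit(mtr, y[train], a_fold)
    xc <- sweep(mho, 2, fit$x_center)
    for (a in seq_len(a_eff)) {
      aa <- min(a, a_fold)
      b_a <- drop(fit$W[, 1:aa, drop = FALSE] %*%
                    solve(crossprod(fit$P[, 1:aa, drop = FALSE],
                                    fit$W[, 1:aa, drop = FALSE]),
                          fit$q[1:aa]))
      err[hold, a] <<- drop(xc %*% b_a) + fit$y_center - y[hold]
    }
    list(patient = pt, held_out_rows = hold, train_rows = train)
  })
  curve <- tibble(
    n_lv = seq_len(a_eff),
    rmsecv = apply(err, 2, function(e) sqrt(mean(e^2)))
  )
  structure(curve, class = c("plsda_cv", class(curve)), folds = folds)
}

#' Choose the number of latent variables
#'
#' Global RMSECV minimum, ties broken toward the smaller model; an
#' explicit override (e.g. a fixed 3-component model) wins regardless of
#' the curve.
#'
#' @param curve A [plsda_cv()] result (or tibble with `n_lv`, `rmsecv`).
#' @param override Optional fixed component count.
#' @return Integer number of latent variables.
#' @export
select_n_lv <- function(curve, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  as.integer(curve$n_lv[which.min(curve$rmsecv)])
}

#' Variable Importance in Projection scores
#'
#' `VIP_j = sqrt( p * sum_a q_a^2 t_a't_a (w_ja / ||w_a||)^2 /`
#' `sum_a q_a^2 t_a't_a )`; the squares always average to 1 over the
#' features (`sum VIP^2 = p`).
#'
#' @param model A `plsda_model`.
#' @return A `vip_result` tibble with `feature_id`, `vip`, sorted by the
#'   model's feature order.
#' @export
vip_scores <- function(model) {
  p <- nrow(model$W)
  ssy <- model$q^2 * colSums(model$T^2)        # y-variance per component
  wnorm2 <- colSums(model$W^2)
  contrib <- sweep(model$W^2, 2, wnorm2, `/`)  # (w_ja/||w_a||)^2
  vip <- sqrt(p * drop(contrib %*% ssy) / sum(ssy))
  out <- tibble(feature_id = model$feature_ids %||% seq_len(p),
                vip = vip)
  structure(out, class = c("vip_result", class(out)))
}

#' Screen features by VIP threshold
#'
#' Strict inequality: a feature is selected when `VIP > threshold`.
#'
#' @param vip A [vip_scores()] result.
#' @param threshold VIP cut (default 3).
#' @return Character vector of selected feature ids.
#' @export
screen_features <- function(vip, threshold = 3) {
  sel <- vip$feature_id[vip$vip > threshold]
  if (length(sel) == 0) {
    abort(paste0("no feature exceeds VIP ", threshold,
                 "; lower the threshold"))
  }
  sel
}

#' Hard-classify continuous discriminant scores
#'
#' @param y_hat Predicted y values.
#' @param theta Decision threshold; scores at or above it take the
#'   positive label. Default 0.5, the midpoint of 0/1 coding.
#' @param labels Two labels, `c(negative, positive)`.
#' @return Character vector of class labels.
#' @export
classify <- function(y_hat, theta = 0.5, labels = c("CTRL", "BC")) {
  ifelse(y_hat >= theta, labels[2], labels[1])
}

#' Fit the full discriminant pipeline on a corrected peak table
#'
#' Train-set workflow: code the two classes 0/1, build the MSC reference
#' from the table's QC injections, MSC-correct the train rows, pick the
#' number of latent variables by leave-one-patient-out RMSECV (or use
#' `n_lv` as an override), fit the full-train model, compute VIP scores,
#' screen features at `vip_threshold`, and refit an optimized model on
#' the selected features with `refit_n_lv` components (preprocessing
#' refitted on the reduced feature set). Validation samples never enter
#' selection or fitting.
#'
#' @param x A corrected `peak_tbl` (QCs still present).
#' @param train_ids Sample ids of the training subset (STUDY samples).
#' @param classes Two class labels, `c(negative, positive)`; samples with
#'   other labels are ignored.
#' @param n_lv Optional fixed component count; when given, the CV scan is
#'   skipped (`cv` is `NULL` in the result).
#' @param a_max Largest component count scanned by CV.
#' @param vip_threshold VIP screening cut; `NULL` skips screening/refit.
#' @param refit_n_lv Components of the optimized (screened) model.
#' @param theta Decision threshold on predicted y.
#' @return A `discriminant_fit` list: preprocessing parameters, CV curve,
#'   full model, VIP result, selected features, optimized model, coding.
#' @export
fit_discriminant <- function(x, train_ids, classes = c("CTRL", "BC"),
                             n_lv = NULL, a_max = 15, vip_threshold = 3,
                             refit_n_lv = 3, theta = 0.5) {
  stopifnot(length(classes) == 2)
  rows <- x$sample_id %in% train_ids & x$role == "STUDY" &
    x$class_label %in% classes
  if (sum(rows) < 4) abort("too few labelled train samples")
  y <- as.numeric(x$class_label[rows] == classes[2])
  patient_id <- x$patient_id[rows]
  reference <- msc_reference(x)
  m_raw <- intensity_matrix(x)[rows, , drop = FALSE]
  m_msc <- msc_apply(m_raw, reference)

  cv <- NULL
  if (is.null(n_lv)) {
    cv <- plsda_cv(m_msc, y, patient_id, a_max = a_max)
    n_lv_used <- select_n_lv(cv)
  } else {
    n_lv_used <- as.integer(n_lv)
  }

  pareto <- pareto_fit(m_msc)
  model <- plsda_fit(pareto_apply(m_msc, pareto), y, n_lv_used)
  vip <- vip_scores(model)

  selected <- NULL; optimized <- NULL; pareto_opt <- NULL
  if (!is.null(vip_threshold)) {
    selected <- screen_features(vip, vip_threshold)
    m_sel <- m_raw[, selected, drop = FALSE]
    ref_sel <- reference[selected]
    m_sel_msc <- msc_apply(m_sel, ref_sel)
    pareto_opt <- pareto_fit(m_sel_msc)
    n_lv_opt <- min(refit_n_lv, qr(scale(m_sel_msc, scale = FALSE))$rank)
    optimized <- plsda_fit(pareto_apply(m_sel_msc, pareto_opt), y,
                           n_lv_opt)
  }
  structure(list(
    classes = classes, theta = theta,
    reference = reference, pareto = pareto,
    cv = cv, n_lv = n_lv_used, model = model, vip = vip,
    selected_features = selected,
    pareto_optimized = pareto_opt, optimized = optimized,
    train_ids = x$sample_id[rows]
  ), class = "discriminant_fit")
}

#' Predict discriminant scores for samples of a peak table
#'
#' Applies the fit's frozen preprocessing (MSC against the train-time QC
#' reference, train Pareto statistics) and the chosen model.
#'
#' @param object A `discriminant_fit`.
#' @param x A corrected `peak_tbl`.
#' @param sample_ids Samples to score (default: all STUDY samples).
#' @param which `"optimized"` (screened-feature refit, if present) or
#'   `"initial"` (full-feature model).
#' @param ... Unused.
#' @return Tibble `sample_id`, `patient_id`, `class_label`,
#'   `visit_index`, `y_hat`, `predicted`.
#' @export
predict.discriminant_fit <- function(object, x,
                                     sample_ids = NULL,
                                     which = c("optimized", "initial"),
                                     ...) {
  which <- match.arg(which)
  if (which == "optimized" && is.null(object$optimized)) which <- "initial"
  if (is.null(sample_ids)) sample_ids <- x$sample_id[x$role == "STUDY"]
  rows <- x$sample_id %in% sample_ids
  m <- intensity_matrix(x)[rows, , drop = FALSE]
  if (which == "optimized") {
    sel <- object$selected_features
    if (!all(sel %in% colnames(m))) abort("table lacks selected features")
    z <- pareto_apply(msc_apply(m[, sel, drop = FALSE],
                                object$reference[sel]),
                      object$pareto_optimized)
    y_hat <- predict(object$optimized, z)
  } else {
    z <- pareto_apply(msc_apply(m, object$reference), object$pareto)
    y_hat <- predict(object$model, z)
  }
  tibble(
    sample_id = x$sample_id[rows], patient_id = x$patient_id[rows],
    class_label = x$class_label[rows], visit_index = x$visit_index[rows],
    y_hat = unname(y_hat),
    predicted = classify(y_hat, object$theta, object$classes)
  )
}
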