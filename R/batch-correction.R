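#' Relative standard deviation in percent
#'
#' `sd/mean * 100` over the finite values, the repeatability metric used
#' on pooled-QC replicates for feature reliability filtering.
#'
#' @param values Numeric vector of intensities.
#' @return RSD in percent, or `NA` when fewer than two finite values
#'   remain or the mean is not positive (such features are flagged
#'   unreliable downstream).
#' @export
compute_rsd <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) return(NA_real_)
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(v) / m
}

#' Candidate RBF kernel widths for drift fitting
#'
#' @return The dyadic grid `2^-3, 2^-2, ..., 2^9` (13 candidates).
#' @export
svrc_gamma_grid <- function() 2^(-3:9)

# contiguous blocks over injection order keep the temporal structure of
# the QC series inside each CV fold
cv_fold_ids <- function(n, folds) {
  folds <- min(folds, n)
  sort(rep_len(seq_len(folds), n))
}

# Returns a prediction function. When the epsilon tube swallows every
# point libsvm has no support vectors and errors out; a constant at the
# mean response is then a valid zero-loss solution and is used instead.
svr_fit <- function(orders, values, epsilon, cost, gamma) {
  fit <- tryCatch(
    e1071::svm(x = matrix(orders, ncol = 1), y = values,
               type = "eps-regression", kernel = "radial",
               gamma = gamma, cost = cost, epsilon = epsilon,
               scale = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    const <- mean(values)
    return(function(o) rep(const, length(o)))
  }
  function(o) as.numeric(stats::predict(fit, matrix(o, ncol = 1)))
}

#' Select QC-SVRC hyperparameters for one feature and batch
#'
#' The epsilon-insensitive loss width is the expected instrumental
#' precision, 2.5% of the median QC intensity; the error penalty C is the
#' median QC intensity itself; the RBF width gamma is picked from
#' [svrc_gamma_grid()] by 10-fold root-mean-square cross-validation error
#' of the support-vector regression of intensity on injection order
#' (contiguous folds over injection order). Ties go to the smallest gamma,
#' the smoothest model. With fewer QCs than folds the CV degrades to
#' leave-one-out.
#'
#' @param qc_orders Injection orders of the QC replicates (one batch).
#' @param qc_values Their intensities.
#' @param gamma_grid Candidate gammas.
#' @param folds CV folds (default 10).
#' @return List with `epsilon`, `cost`, `gamma`, `rmsecv_by_gamma`.
#' @export
select_svrc_hyperparams <- function(qc_orders, qc_values,
                                    gamma_grid = svrc_gamma_grid(),
                                    folds = 10) {
  keep <- is.finite(qc_values)
  qc_orders <- qc_orders[keep]; qc_values <- qc_values[keep]
  if (length(qc_values) < 3) abort("need at least 3 QC points")
  med <- stats::median(qc_values)
  epsilon <- 0.025 * med
  cost <- med
  ord <- order(qc_orders)
  qc_orders <- qc_orders[ord]; qc_values <- qc_values[ord]
  fold_id <- cv_fold_ids(length(qc_values), folds)
  rmsecv <- vapply(gamma_grid, function(g) {
    sq <- unlist(lapply(unique(fold_id), function(k) {
      tr <- fold_id != k
      if (sum(tr) < 2) return(numeric(0))
      fit <- svr_fit(qc_orders[tr], qc_values[tr], epsilon, cost, g)
      (fit(qc_orders[!tr]) - qc_values[!tr])^2
    }))
    sqrt(mean(sq))
  }, numeric(1))
  gamma <- gamma_grid[which.min(rmsecv)]  # which.min takes first = smallest
  list(epsilon = epsilon, cost = cost, gamma = gamma,
       rmsecv_by_gamma = stats::setNames(rmsecv, as.character(gamma_grid)))
}

#' Fit a per-feature, per-batch QC drift model
#'
#' Support-vector regression (RBF kernel) of QC intensity on injection
#' order, evaluable at any order in the batch. Predictions are floored at
#' a small positive fraction of the QC reference so the correction factor
#' stays finite. Constant QC series (or degenerate fits whose predictions
#' are non-positive) fall back to the constant reference level, so the
#' correction is exactly the identity when there is no drift to model.
#'
#' @param qc_orders,qc_values QC injection orders and intensities.
#' @param hyperparams Optional list from [select_svrc_hyperparams()];
#'   selected automatically when `NULL`.
#' @param gamma_grid,folds Passed to the selector.
#' @return A `drift_model`: list with `predict(orders)`, `qc_reference`
#'   (median QC intensity), `hyperparams`, `fallback` flag.
#' @export
fit_drift_model <- function(qc_orders, qc_values, hyperparams = NULL,
                            gamma_grid = svrc_gamma_grid(), folds = 10) {
  keep <- is.finite(qc_values)
  qc_orders <- qc_orders[keep]; qc_values <- qc_values[keep]
  if (length(qc_values) < 3) abort("need at least 3 QC points")
  qc_reference <- stats::median(qc_values)
  floor_val <- 1e-6 * max(qc_reference, .Machine$double.eps)
  constant <- function(reason) {
    structure(list(
      predict = function(orders) rep(qc_reference, length(orders)),
      qc_reference = qc_reference, hyperparams = hyperparams,
      fallback = TRUE, fallback_reason = reason
    ), class = "drift_model")
  }
  if (stats::sd(qc_values) == 0 || qc_reference <= 0) {
    return(constant("constant_qc"))
  }
  if (is.null(hyperparams)) {
    hyperparams <- select_svrc_hyperparams(qc_orders, qc_values,
                                           gamma_grid, folds)
  }
  fit <- svr_fit(qc_orders, qc_values, hyperparams$epsilon,
                 hyperparams$cost, hyperparams$gamma)
  rng <- range(qc_orders)
  probe <- fit(seq(rng[1], rng[2]))
  if (all(probe <= 0)) {
    warn("degenerate drift fit; falling back to constant reference")
    return(constant("degenerate_fit"))
  }
  structure(list(
    predict = function(orders) pmax(fit(orders), floor_val),
    qc_reference = qc_reference, hyperparams = hyperparams,
    fallback = FALSE, fallback_reason = "none"
  ), class = "drift_model")
}

qc_rows <- function(x) which(x$role == "QC")

#' Within-batch QC-SVRC drift correction
#'
#' Fits one drift model per retained feature and batch on the pooled-QC
#' injections and rescales every sample (all roles) by
#' `qc_reference / f(order)`, so corrected QC intensities sit at the
#' feature's per-batch QC median up to the epsilon tube of the fit.
#' Missing intensities stay missing.
#'
#' @param x A `peak_tbl` (conditioning QCs already excluded).
#' @param gamma_grid,folds Passed to the hyperparameter selector.
#' @return List with `table` (corrected `peak_tbl`) and `models`, a tibble
#'   of per-feature/batch hyperparameters, QC reference levels and
#'   fallback flags (the fitted models in a list-column).
#' @export
correct_within_batch <- function(x, gamma_grid = svrc_gamma_grid(),
                                 folds = 10) {
  m <- intensity_matrix(x)
  fids <- colnames(m)
  batches <- sort(unique(x$batch))
  qc <- qc_rows(x)
  if (length(qc) == 0) abort("no QC samples present")
  models <- purrr::map(batches, function(b) {
    in_b <- x$batch == b
    qc_b <- intersect(qc, which(in_b))
    if (length(qc_b) < 3) {
      abort(paste0("batch ", b, " has fewer than 3 QC injections"))
    }
    purrr::map(fids, function(f) {
      dm <- fit_drift_model(x$injection_order[qc_b], m[qc_b, f],
                            gamma_grid = gamma_grid, folds = folds)
      factor <- dm$qc_reference / dm$predict(x$injection_order[in_b])
      m[in_b, f] <<- m[in_b, f] * factor
      tibble(feature_id = f, batch = b,
             epsilon = dm$hyperparams$epsilon %||% NA_real_,
             cost = dm$hyperparams$cost %||% NA_real_,
             gamma = dm$hyperparams$gamma %||% NA_real_,
             qc_reference = dm$qc_reference,
             fallback = dm$fallback, model = list(dm))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  list(table = set_intensities(x, m), models = models)
}

#' Between-batch QC-median equalization
#'
#' Per feature, intensities of batch k are multiplied by
#' `median(QC, all batches) / median(QC, batch k)`, which makes the
#' per-batch QC medians exactly equal across batches while preserving the
#' pooled intensity scale.
#'
#' @param x A `peak_tbl` with within-batch correction already applied.
#' @return List with `table` and `factors` (tibble feature/batch/factor).
#' @export
correct_between_batch <- function(x) {
  m <- intensity_matrix(x)
  qc <- qc_rows(x)
  if (length(qc) == 0) abort("no QC samples present")
  batches <- sort(unique(x$batch))
  pooled <- apply(m[qc, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  factors <- purrr::map(batches, function(b) {
    qc_b <- intersect(qc, which(x$batch == b))
    if (length(qc_b) == 0) abort(paste0("batch ", b, " has no QCs"))
    med_b <- apply(m[qc_b, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    fac <- ifelse(med_b > 0, pooled / med_b, 1)
    m[x$batch == b, ] <<- sweep(m[x$batch == b, , drop = FALSE], 2, fac,
                                `*`)
    tibble(feature_id = colnames(m), batch = b, factor = unname(fac))
  }) |> purrr::list_rbind()
  list(table = set_intensities(x, m), factors = factors)
}

#' Remove background features using blank injections
#'
#' A feature is background (source contaminant, plasticizer, solvent
#' impurity) when its median blank intensity reaches `blank_ratio` of its
#' median QC intensity.
#'
#' @param x A `peak_tbl`.
#' @param blank_ratio Blank-to-QC median ratio at or above which a feature
#'   is removed (default 1/3, i.e. sample-to-blank ratio 3).
#' @return List with `table` (background features dropped) and `report`
#'   tibble (`feature_id`, `blank_median`, `qc_median`, `removed`).
#' @export
filter_blank_features <- function(x, blank_ratio = 1 / 3) {
  blanks <- which(x$role == "BLANK")
  if (length(blanks) == 0) {
    warn("no blank samples; background filtering skipped")
    return(list(table = x, report = NULL))
  }
  m <- intensity_matrix(x)
  qc <- qc_rows(x)
  blank_med <- apply(m[blanks, , drop = FALSE], 2, stats::median,
                     na.rm = TRUE)
  qc_med <- apply(m[qc, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  removed <- is.finite(blank_med) & is.finite(qc_med) & qc_med > 0 &
    blank_med >= blank_ratio * qc_med
  report <- tibble(feature_id = colnames(m), blank_median = blank_med,
                   qc_median = qc_med, removed = removed)
  list(table = set_intensities(x, m[, !removed, drop = FALSE]),
       report = report)
}

#' Remove features with unreliable QC repeatability
#'
#' Features whose QC relative standard deviation exceeds the threshold
#' (strictly; exactly 15.0% is retained) are removed. Features whose RSD
#' is undefined (all-missing or non-positive mean) are removed as
#' unreliable.
#'
#' @param x A `peak_tbl` with QC samples.
#' @param threshold_percent RSD cut in percent (default 15).
#' @return List with `table` and `report` tibble
#'   (`feature_id`, `rsd_qc`, `removed`).
#' @export
filter_rsd <- function(x, threshold_percent = 15) {
  qc <- qc_rows(x)
  if (length(qc) == 0) abort("no QC samples present")
  m <- intensity_matrix(x)
  rsd <- apply(m[qc, , drop = FALSE], 2, compute_rsd)
  removed <- is.na(rsd) | rsd > threshold_percent
  report <- tibble(feature_id = colnames(m), rsd_qc = unname(rsd),
                   removed = unname(removed))
  list(table = set_intensities(x, m[, !removed, drop = FALSE]),
       report = report)
}

#' QC trend diagnostics
#'
#' Principal-component scores of the QC injections (singular value
#' decomposition of the mean-centered QC block, features with any missing
#' value dropped) keyed by injection order and batch, plus the per-feature
#' QC RSD distribution — the instrument-performance views used to judge
#' whether correction removed the association between QC profile and
#' injection order.
#'
#' @param x A `peak_tbl` with at least 3 QCs.
#' @param n_pc Number of score columns to keep.
#' @return List with `scores` (tibble: sample, batch, injection order,
#'   PC scores), `rsd` (per-feature QC RSD tibble) and `median_rsd`.
#' @export
qc_trend_diagnostics <- function(x, n_pc = 3) {
  qc <- qc_rows(x)
  if (length(qc) < 3) abort("need at least 3 QC samples")
  m <- intensity_matrix(x)[qc, , drop = FALSE]
  ok <- apply(is.finite(m), 2, all)
  mc <- scale(m[, ok, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(mc)
  k <- min(n_pc, ncol(sv$u))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rsd <- apply(intensity_matrix(x)[qc, , drop = FALSE], 2, compute_rsd)
  list(
    scores = dplyr::bind_cols(
      tibble(sample_id = x$sample_id[qc], batch = x$batch[qc],
             injection_order = x$injection_order[qc]),
      as_tibble(scores)
    ),
    rsd = tibble(feature_id = feature_ids(x), rsd_qc = unname(rsd)),
    median_rsd = stats::median(rsd, na.rm = TRUE)
  )
}

#' Full batch-effect correction stack
#'
#' Convenience pipeline: exclude conditioning injections, remove
#' background features against blanks, fit and apply within-batch QC-SVRC
#' drift correction, equalize per-feature QC medians between batches, and
#' drop features whose post-correction QC RSD exceeds the reliability
#' threshold.
#'
#' @param x A raw `peak_tbl`.
#' @param rsd_threshold RSD cut in percent.
#' @param blank_ratio Blank filter ratio; `NULL` skips the blank stage.
#' @param gamma_grid,folds Passed to the drift fitter.
#' @return List with `table` (corrected, filtered), `models`,
#'   `rsd_before`/`rsd_after` medians, and the stage `reports`.
#' @export
correct_batch_effects <- function(x, rsd_threshold = 15,
                                  blank_ratio = 1 / 3,
                                  gamma_grid = svrc_gamma_grid(),
                                  folds = 10) {
  x <- exclude_conditioning(x)
  pre_rsd <- apply(intensity_matrix(x)[qc_rows(x), , drop = FALSE], 2,
                   compute_rsd)
  blank_report <- NULL
  if (!is.null(blank_ratio) && any(x$role == "BLANK")) {
    st <- filter_blank_features(x, blank_ratio)
    x <- st$table; blank_report <- st$report
  }
  wb <- correct_within_batch(x, gamma_grid = gamma_grid, folds = folds)
  bb <- correct_between_batch(wb$table)
  fr <- filter_rsd(bb$table, rsd_threshold)
  list(
    table = fr$table,
    models = wb$models,
    rsd_before = pre_rsd,
    rsd_after = stats::setNames(fr$report$rsd_qc, fr$report$feature_id),
    reports = list(blank = blank_report, rsd = fr$report)
  )
}
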