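#' Confusion counts for a binary classification
#'
#' @param predicted,truth Equal-length label vectors drawn from the two
#'   classes.
#' @param positive The positive-class label.
#' @return A `confusion_counts` list: `tp`, `fn`, `tn`, `fp`, `n_pos`,
#'   `n_neg`, `positive`.
#' @export
confusion_counts <- function(predicted, truth, positive) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth differ in length")
  }
  classes <- unique(c(predicted, truth))
  if (length(classes) > 2) {
    abort(paste0("labels must be binary; got: ",
                 paste(classes, collapse = ", ")))
  }
  if (!positive %in% classes && length(truth) > 0) {
    warn("positive class absent from the data")
  }
  is_pos_t <- truth == positive
  is_pos_p <- predicted == positive
  out <- list(
    tp = sum(is_pos_t & is_pos_p), fn = sum(is_pos_t & !is_pos_p),
    tn = sum(!is_pos_t & !is_pos_p), fp = sum(!is_pos_t & is_pos_p),
    positive = positive
  )
  out$n_pos <- out$tp + out$fn
  out$n_neg <- out$tn + out$fp
  structure(out, class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial proportion with CI, in percent
#'
#' Bounds from beta quantiles: lower = `qbeta(alpha/2, k, n-k+1)`,
#' upper = `qbeta(1-alpha/2, k+1, n-k)`; 0 successes pin the lower bound
#' at 0 and `k = n` pins the upper at 100 (then the lower bound has the
#' closed form `100 * (alpha/2)^(1/n)`).
#'
#' @param k Successes (0..n).
#' @param n Trials (>= 1).
#' @param alpha Two-sided error rate (default 0.05 for 95% CI).
#' @return Tibble with `estimate`, `lower`, `upper` in percent.
#' @export
proportion_ci <- function(k, n, alpha = 0.05) {
  if (n < 1) abort("n must be >= 1")
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  tibble(estimate = 100 * k / n, lower = 100 * lower, upper = 100 * upper)
}

#' Likelihood ratios with log-method confidence intervals
#'
#' `PLR = sens / (1 - spec)`, `NLR = (1 - sens) / spec`, with
#' `exp(log LR +/- z * SE)` intervals where
#' `SE(log PLR) = sqrt((1-sens)/(n_pos*sens) + spec/(n_neg*(1-spec)))` and
#' `SE(log NLR) = sqrt(sens/(n_pos*(1-sens)) + (1-spec)/(n_neg*spec))`.
#' Degenerate tables are flagged rather than corrected: `fp = 0` gives an
#' infinite PLR, `fn = 0` a zero NLR, each with the corresponding CI side
#' undefined; when only one variance term degenerates (e.g. perfect
#' specificity), the vanishing term is dropped and the CI is still
#' reported.
#'
#' @param counts A [confusion_counts()].
#' @param alpha Two-sided error rate.
#' @return Tibble with rows `plr`, `nlr`: `estimate`, `lower`, `upper`,
#'   `degenerate` flag.
#' @export
likelihood_ratios <- function(counts, alpha = 0.05) {
  if (counts$n_pos == 0 || counts$n_neg == 0) {
    abort("both classes must be present")
  }
  sens <- counts$tp / counts$n_pos
  spec <- counts$tn / counts$n_neg
  z <- stats::qnorm(1 - alpha / 2)
  term <- function(num, den) if (den == 0) NA_real_ else num / den
  # PLR
  if (counts$fp == 0) {
    plr <- c(Inf, NA_real_, NA_real_); plr_deg <- TRUE
  } else if (counts$tp == 0) {
    plr <- c(0, NA_real_, NA_real_); plr_deg <- TRUE
  } else {
    est <- sens / (1 - spec)
    t1 <- (1 - sens) / (counts$n_pos * sens)
    t2 <- spec / (counts$n_neg * (1 - spec))
    se <- sqrt(t1 + t2)
    plr <- c(est, exp(log(est) - z * se), exp(log(est) + z * se))
    plr_deg <- FALSE
  }
  # NLR
  if (counts$fn == 0) {
    nlr <- c(0, NA_real_, NA_real_); nlr_deg <- TRUE
  } else if (counts$tn == 0) {
    nlr <- c(Inf, NA_real_, NA_real_); nlr_deg <- TRUE
  } else {
    est <- (1 - sens) / spec
    t1 <- sens / (counts$n_pos * (1 - sens))
    t2 <- if (counts$fp == 0) 0 else (1 - spec) / (counts$n_neg * spec)
    se <- sqrt(t1 + t2)
    nlr <- c(est, exp(log(est) - z * se), exp(log(est) + z * se))
    nlr_deg <- FALSE
  }
  tibble(
    metric = c("plr", "nlr"),
    estimate = c(plr[1], nlr[1]),
    lower = c(plr[2], nlr[2]),
    upper = c(plr[3], nlr[3]),
    degenerate = c(plr_deg, nlr_deg)
  )
}

#' Area under the ROC curve (rank-sum estimator)
#'
#' The probability that a random positive outscores a random negative,
#' ties counted one half — the Mann-Whitney formulation, equal to the
#' area under the empirical ROC traced by sweeping the decision
#' threshold.
#'
#' @param scores Continuous scores (higher = more positive).
#' @param truth Labels.
#' @param positive Positive-class label.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be present")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Predictive values at external prevalences
#'
#' Bayes' rule applied to a test's sensitivity and specificity at the
#' prior probability of disease in a target group (here: recurrence risk
#' strata):
#' `NPV = spec (1-p) / ((1-sens) p + spec (1-p))`,
#' `PPV = sens p / (sens p + (1-spec)(1-p))`.
#'
#' @param sens,spec Proportions in `[0, 1]`.
#' @param prevalence Prior probability (vectorized).
#' @return Tibble with `prevalence`, `ppv`, `npv` (proportions; `NaN`
#'   flags an undefined 0/0 case).
#' @export
predictive_values <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            all(prevalence >= 0), all(prevalence <= 1))
  npv_den <- (1 - sens) * prevalence + spec * (1 - prevalence)
  ppv_den <- sens * prevalence + (1 - spec) * (1 - prevalence)
  tibble(
    prevalence = prevalence,
    ppv = ifelse(ppv_den == 0, NaN, sens * prevalence / ppv_den),
    npv = ifelse(npv_den == 0, NaN, spec * (1 - prevalence) / npv_den)
  )
}

#' Assemble the figures of merit for a scored validation set
#'
#' Sensitivity, specificity and accuracy with exact binomial CIs,
#' likelihood ratios with log-method CIs, AUROC, and (optionally)
#' prevalence-adjusted predictive values.
#'
#' @param scores Continuous discriminant scores.
#' @param predicted,truth Hard labels.
#' @param positive Positive-class label.
#' @param alpha Two-sided error rate for the CIs.
#' @param prevalences Optional vector of prior prevalences.
#' @return A `discriminant_metrics` list: `counts`, `metrics` tibble
#'   (estimate/lower/upper), `auroc`, `predictive_values`.
#' @export
evaluate_discriminant <- function(scores, predicted, truth, positive,
                                  alpha = 0.05, prevalences = NULL) {
  counts <- confusion_counts(predicted, truth, positive)
  sens <- proportion_ci(counts$tp, counts$n_pos, alpha)
  spec <- proportion_ci(counts$tn, counts$n_neg, alpha)
  acc <- proportion_ci(counts$tp + counts$tn,
                       counts$n_pos + counts$n_neg, alpha)
  lr <- likelihood_ratios(counts, alpha)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(sens, metric = "sensitivity", .before = 1),
    dplyr::mutate(spec, metric = "specificity", .before = 1),
    dplyr::mutate(acc, metric = "accuracy", .before = 1),
    lr[c("metric", "estimate", "lower", "upper")]
  )
  pv <- NULL
  if (!is.null(prevalences)) {
    pv <- predictive_values(sens$estimate / 100, spec$estimate / 100,
                            prevalences)
  }
  structure(list(
    counts = counts, metrics = metrics,
    auroc = auroc(scores, truth, positive),
    predictive_values = pv
  ), class = "discriminant_metrics")
}

#' @export
print.discriminant_metrics <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("Confusion: tp=%d fn=%d tn=%d fp=%d (positive = %s)\n",
              c0$tp, c0$fn, c0$tn, c0$fp, c0$positive))
  cat(sprintf("AUROC: %.3f\n", x$auroc))
  print(x$metrics)
  if (!is.null(x$predictive_values)) print(x$predictive_values)
  invisible(x)
}
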