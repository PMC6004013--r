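random_problem <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("F", seq_len(p))))
  y <- as.numeric(stats::runif(n) > 0.5)
  list(x = x, y = y)
}

test_that("a single feature equal to y gives a perfect 1-LV model", {
  y <- c(0, 1, 0, 1, 1, 0)
  x <- matrix(y, ncol = 1, dimnames = list(NULL, "F1"))
  fit <- plsda_fit(x, y, 1)
  expect_equal(unname(predict(fit, x)), y, tolerance = 1e-12)
})

test_that("full-component PLS reproduces least-squares predictions", {
  pr <- random_problem(30, 5, seed = 41)
  fit <- plsda_fit(pr$x, pr$y, 5)
  ols <- unname(stats::fitted(stats::lm(pr$y ~ pr$x)))
  expect_equal(unname(predict(fit, pr$x)), ols, tolerance = 1e-8)
  expect_error(plsda_fit(pr$x, pr$y, 6), "rank")
})

test_that("score columns are mutually orthogonal", {
  pr <- random_problem(25, 10, seed = 42)
  fit <- plsda_fit(pr$x, pr$y, 4)
  g <- crossprod(fit$T)
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)) / max(diag(g)), 1e-8)
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  pr <- random_problem(20, 40, seed = 43)
  fit <- plsda_fit(pr$x, pr$y, 3)
  ref <- mixOmics::pls(pr$x, pr$y, ncomp = 3, mode = "regression",
                       scale = FALSE)
  ref_pred <- stats::predict(ref, pr$x)$predict[, 1, 3]
  expect_equal(unname(predict(fit, pr$x)), unname(ref_pred),
               tolerance = 1e-8)
})

test_that("leave-one-patient-out CV holds out whole patients", {
  set.seed(44)
  n <- 24
  patient <- rep(sprintf("P%d", 1:6), each = 4)
  x <- matrix(stats::rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("F", 1:8)))
  y <- rep(c(0, 1), each = 12)
  cv <- plsda_cv(x, y, patient, a_max = 4)
  folds <- attr(cv, "folds")
  expect_length(folds, 6)  # one fold per patient
  for (f in folds) {
    expect_length(intersect(f$held_out_rows, f$train_rows), 0)
    expect_setequal(patient[f$held_out_rows], f$patient)
    expect_false(f$patient %in% patient[f$train_rows])
  }
  # every sample is held out exactly once
  held <- sort(unlist(lapply(folds, `[[`, "held_out_rows")))
  expect_identical(held, 1:n)
  expect_error(plsda_cv(x, y, rep("P1", n), a_max = 2), "2 patients")
})

test_that("RMSECV drops to the generator's effective dimension", {
  # one informative direction: RMSECV at 1 LV should beat a 0-LV guess
  # and not improve materially with more components
  set.seed(45)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  signal <- outer(y - 0.5, c(2, -2, 1, rep(0, 5)))
  x <- signal + matrix(stats::rnorm(n * 8, sd = 0.3), n, 8)
  colnames(x) <- paste0("F", 1:8)
  cv <- plsda_cv(x, y, patient_id = sprintf("P%d", 1:n), a_max = 5,
                 scale = FALSE)
  expect_lt(cv$rmsecv[1], 0.5 * stats::sd(y))
  expect_equal(select_n_lv(cv), which.min(cv$rmsecv))
})

test_that("latent-variable selection: argmin, override, tie-break", {
  curve <- tibble::tibble(n_lv = 1:4, rmsecv = c(0.5, 0.3, 0.31, 0.4))
  expect_identical(select_n_lv(curve), 2L)
  expect_identical(select_n_lv(curve, override = 3), 3L)
  tie <- tibble::tibble(n_lv = 1:3, rmsecv = c(0.4, 0.3, 0.3))
  expect_identical(select_n_lv(tie), 2L)
})

test_that("VIP scores satisfy their algebraic identities", {
  # p = 1: normalization forces VIP = 1
  y <- c(0, 1, 0, 1, 1, 0)
  x1 <- matrix(stats::rnorm(6), ncol = 1, dimnames = list(NULL, "F1"))
  expect_equal(vip_scores(plsda_fit(x1, y, 1))$vip, 1)

  # 1-LV model where only one feature carries weight
  x <- cbind(F1 = y + stats::rnorm(6, sd = 1e-8), F2 = rep(1e-8, 6),
             F3 = rep(-1e-8, 6))
  x[, 2:3] <- x[, 2:3] + stats::rnorm(12, sd = 1e-10)
  vip <- vip_scores(plsda_fit(x, y, 1))
  expect_equal(vip$vip[1], sqrt(3), tolerance = 1e-3)

  # sum of squares equals p on random fits
  for (s in 1:5) {
    pr <- random_problem(20, 12, seed = 50 + s)
    fit <- plsda_fit(pr$x, pr$y, 3)
    v <- vip_scores(fit)$vip
    expect_equal(sum(v^2), 12, tolerance = 1e-6)
    expect_true(all(v >= 0))
  }
})

test_that("VIP screening is strict and monotone in the threshold", {
  pr <- random_problem(20, 12, seed = 61)
  vip <- vip_scores(plsda_fit(pr$x, pr$y, 2))
  s1 <- screen_features(vip, 0.5)
  s2 <- screen_features(vip, 1)
  expect_true(all(s2 %in% s1))
  expect_setequal(s1, vip$feature_id[vip$vip > 0.5])
  expect_error(screen_features(vip, max(vip$vip)), "lower the threshold")
})

test_that("classification threshold uses the boundary convention", {
  expect_identical(classify(c(0.49, 0.5, 0.51)),
                   c("CTRL", "BC", "BC"))
  # sweeping the threshold traces the ROC the rank estimator integrates
  set.seed(62)
  scores <- stats::runif(40)
  truth <- ifelse(stats::runif(40) < stats::plogis(6 * scores - 3),
                  "BC", "CTRL")
  if (length(unique(truth)) == 2) {
    ths <- sort(unique(scores))
    sens <- vapply(ths, function(t)
      mean(scores[truth == "BC"] >= t), numeric(1))
    fpr <- vapply(ths, function(t)
      mean(scores[truth == "CTRL"] >= t), numeric(1))
    ord <- order(fpr, sens)
    auc_trap <- sum(diff(c(0, fpr[ord], 1)) *
                      (c(0, sens[ord]) + c(sens[ord], 1)) / 2)
    expect_equal(auc_trap, auroc(scores, truth, "BC"), tolerance = 1e-10)
  }
})

test_that("predictions are deterministic and row-duplication stable", {
  pr <- random_problem(15, 6, seed = 63)
  fit <- plsda_fit(pr$x, pr$y, 2)
  y1 <- predict(fit, pr$x[c(1, 1, 2), ])
  expect_equal(y1[1], y1[2])
  expect_equal(predict(fit, pr$x), predict(fit, pr$x))
  expect_error(predict(fit, pr$x[, 1:3]), "feature")
})

test_that("the discriminant pipeline recovers injected features", {
  # ground-truth recovery, modest scale; the acceptance suite runs the
  # full-size version
  hits <- purrr::map_dbl(1:3, function(s) {
    ch <- generate_cohort(synthetic_config(
      n_features = 150, n_discriminant = 12, n_patients_bc = 16,
      n_background = 0, drift_amplitude = 0, between_batch_log2_range = 0,
      noise_rsd = 0.15, effect_log2fc = 1, qc_interval = 4, seed = 70 + s
    ))
    tbl <- exclude_conditioning(ch$table)
    ids <- tbl$sample_id[tbl$role == "STUDY"]
    fit <- fit_discriminant(tbl, ids, n_lv = 3, vip_threshold = 2)
    mean(ch$truth$discriminant$feature_id %in% fit$selected_features)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("screening and refit never touch validation samples", {
  ch <- small_cohort(seed = 77, n_features = 40, n_discriminant = 8,
                     n_patients_bc = 10, drift_amplitude = 0,
                     between_batch_log2_range = 0)
  tbl <- exclude_conditioning(ch$table)
  assignment <- alternate_split(tbl)
  plan <- split_by_patient(tbl, assignment)
  fit1 <- fit_discriminant(tbl, plan$train_sample_ids, n_lv = 2,
                           vip_threshold = 1)
  # scrambling the validation samples' intensities changes nothing in
  # the fitted pipeline
  tbl2 <- tbl
  vrows <- tbl2$sample_id %in% plan$validation_sample_ids
  for (f in feature_ids(tbl2)) {
    tbl2[[f]][vrows] <- rev(tbl2[[f]][vrows]) * 3
  }
  fit2 <- fit_discriminant(tbl2, plan$train_sample_ids, n_lv = 2,
                           vip_threshold = 1)
  expect_identical(fit1$selected_features, fit2$selected_features)
  expect_equal(fit1$model$coefficients, fit2$model$coefficients)
  expect_equal(fit1$optimized$coefficients, fit2$optimized$coefficients)
})
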