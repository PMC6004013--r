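test_that("compute_rsd matches hand arithmetic and flags bad input", {
  expect_equal(compute_rsd(c(5, 5, 5)), 0)
  expect_equal(compute_rsd(c(90, 100, 110)), 10)  # sd 10, mean 100
  expect_true(is.na(compute_rsd(c(NA, NA))))
  expect_true(is.na(compute_rsd(c(0, 0, 0))))
})

test_that("SVRC hyperparameters follow the QC-median rules", {
  set.seed(1)
  orders <- seq(1, 50, by = 5)
  values <- 1000 + stats::rnorm(length(orders), sd = 20)
  values <- values - stats::median(values) + 1000  # force median 1000
  hp <- select_svrc_hyperparams(orders, values)
  expect_equal(hp$epsilon, 25)
  expect_equal(hp$cost, 1000)
  expect_length(hp$rmsecv_by_gamma, 13)
  expect_true(hp$gamma %in% svrc_gamma_grid())
  expect_error(select_svrc_hyperparams(1:2, c(10, 12)), "3 QC")
})

test_that("RMSECV ties break toward the smallest gamma", {
  # constant QC series: every gamma yields the same flat fit, so the
  # RMSECV is tied across the whole grid and the smallest gamma wins
  hp <- select_svrc_hyperparams(seq(1, 46, by = 5), rep(500, 10))
  expect_equal(unname(diff(range(hp$rmsecv_by_gamma))), 0)
  expect_equal(hp$gamma, min(svrc_gamma_grid()))
})

test_that("drift fit tracks a known trend within the epsilon tube", {
  orders <- seq(1, 50, by = 5)
  trend <- 100 + (orders - 1) * 50 / 49      # linear 100 -> 150
  dm <- fit_drift_model(orders, trend)
  eps <- 0.025 * stats::median(trend)
  # allow libsvm's convergence tolerance on top of the tube width
  expect_true(all(abs(dm$predict(orders) - trend) <= eps * 1.05))
  expect_false(dm$fallback)

  # constant QC values short-circuit to an exact constant model
  dm2 <- fit_drift_model(orders, rep(42, length(orders)))
  expect_true(dm2$fallback)
  expect_equal(dm2$predict(c(1, 25, 50)), rep(42, 3))
})

test_that("within-batch correction flattens zero-noise drifting QCs", {
  ch <- generate_cohort(synthetic_config(
    n_features = 8, n_discriminant = 0, n_background = 0,
    n_patients_bc = 10, n_blanks = 0, drift_amplitude = 0.3,
    between_batch_log2_range = 0, noise_rsd = 0, qc_interval = 3,
    seed = 4
  ))
  tbl <- exclude_conditioning(ch$table)
  wb <- correct_within_batch(tbl)
  m <- intensity_matrix(wb$table)
  qc <- which(wb$table$role == "QC")
  for (f in feature_ids(wb$table)) {
    for (b in unique(tbl$batch)) {
      qcb <- intersect(qc, which(wb$table$batch == b))
      ref <- wb$models$qc_reference[wb$models$feature_id == f &
                                      wb$models$batch == b]
      eps <- 0.025 * ref
      expect_true(all(abs(m[qcb, f] - ref) <= ref * 0.05),
                  label = paste("QCs near reference for", f, "batch", b))
    }
  }
})

test_that("correction reduces QC RSD when drift dominates noise", {
  # drift amplitude at least 3x the technical CV, five independent seeds
  worse <- purrr::map_lgl(1:5, function(s) {
    ch <- small_cohort(seed = s, n_features = 12, n_patients_bc = 8,
                       drift_amplitude = 0.3, noise_rsd = 0.08,
                       n_background = 0, n_discriminant = 0)
    tbl <- exclude_conditioning(ch$table)
    pre <- apply(intensity_matrix(tbl)[tbl$role == "QC", ], 2,
                 compute_rsd)
    corr <- correct_between_batch(correct_within_batch(tbl)$table)$table
    post <- apply(intensity_matrix(corr)[corr$role == "QC", ], 2,
                  compute_rsd)
    stats::median(post, na.rm = TRUE) < stats::median(pre, na.rm = TRUE)
  })
  expect_true(all(worse))
})

test_that("between-batch scaling equalizes per-batch QC medians", {
  samples <- tibble::tibble(
    sample_id = sprintf("Q%d", 1:6),
    patient_id = NA_character_,
    batch = rep(1:2, each = 3),
    injection_order = rep(1:3, 2),
    role = "QC", class_label = NA_character_,
    visit_index = NA_integer_
  )
  m <- matrix(c(90, 100, 110, 290, 300, 310), ncol = 1,
              dimnames = list(NULL, "F1"))
  tbl <- peak_table(samples, m)
  out <- correct_between_batch(tbl)
  fac <- out$factors
  # pooled QC median 200: batch 1 scaled by 2, batch 2 by 2/3
  expect_equal(fac$factor[fac$batch == 1], 2)
  expect_equal(fac$factor[fac$batch == 2], 2 / 3, tolerance = 1e-12)
  mm <- intensity_matrix(out$table)
  expect_equal(stats::median(mm[1:3, 1]), 200)
  expect_equal(stats::median(mm[4:6, 1]), 200)

  # property: any input ends with equal per-feature per-batch QC medians
  ch <- small_cohort(seed = 8)
  tbl2 <- exclude_conditioning(ch$table)
  eq <- correct_between_batch(tbl2)$table
  med <- sapply(unique(eq$batch), function(b) {
    apply(intensity_matrix(eq)[eq$role == "QC" & eq$batch == b, ,
                               drop = FALSE], 2, stats::median)
  })
  expect_equal(med[, 1], med[, 2], tolerance = 1e-12)

  # single batch: identity
  one <- tbl[tbl$batch == 1, ]
  one <- peak_table(one[meta_cols()], intensity_matrix(tbl)[1:3, ,
                                                            drop = FALSE])
  expect_equal(intensity_matrix(correct_between_batch(one)$table),
               intensity_matrix(one))
})

test_that("blank filter removes background features, keeps the rest", {
  ch <- small_cohort(seed = 10, n_background = 5)
  tbl <- exclude_conditioning(ch$table)
  out <- filter_blank_features(tbl)
  expect_setequal(
    out$report$feature_id[out$report$removed],
    ch$truth$background_ids
  )
  expect_false(any(ch$truth$background_ids %in% feature_ids(out$table)))

  # desk cases: blank median 0 retained; ratio 0.5 >= 1/3 removed
  rep1 <- out$report[out$report$blank_median == 0, ]
  expect_true(all(!rep1$removed))
  samples <- tibble::tibble(
    sample_id = c("Q1", "Q2", "Q3", "B1"), patient_id = NA_character_,
    batch = 1L, injection_order = 1:4,
    role = c("QC", "QC", "QC", "BLANK"),
    class_label = NA_character_, visit_index = NA_integer_
  )
  m <- matrix(c(100, 100, 100, 50), ncol = 1,
              dimnames = list(NULL, "F1"))
  res <- filter_blank_features(peak_table(samples, m))
  expect_true(res$report$removed[1])
  expect_length(feature_ids(res$table), 0)
})

test_that("RSD filter uses a strict threshold and is monotone", {
  mk <- function(qc_values) {
    n <- length(qc_values)
    samples <- tibble::tibble(
      sample_id = sprintf("Q%d", 1:n), patient_id = NA_character_,
      batch = 1L, injection_order = 1:n, role = "QC",
      class_label = NA_character_, visit_index = NA_integer_
    )
    peak_table(samples, matrix(qc_values, ncol = 1,
                               dimnames = list(NULL, "F1")))
  }
  # rsd exactly 15.0%: retained (strict >); 16%: removed
  at15 <- c(100 - 15, 100, 100 + 15) * 100 / 100  # sd 15, mean 100
  expect_equal(compute_rsd(at15), 15)
  expect_length(feature_ids(filter_rsd(mk(at15))$table), 1)
  at16 <- c(84, 100, 116)
  expect_equal(compute_rsd(at16), 16)
  expect_length(feature_ids(filter_rsd(mk(at16))$table), 0)

  # retained set grows with the threshold
  ch <- small_cohort(seed = 12, noise_rsd = 0.15)
  tbl <- exclude_conditioning(ch$table)
  r15 <- feature_ids(filter_rsd(tbl, 15)$table)
  r20 <- feature_ids(filter_rsd(tbl, 20)$table)
  expect_true(all(r15 %in% r20))
})

test_that("QC PC1 loses its injection-order trend after correction", {
  # single batch so PC1 captures the within-batch drift, not the offset
  ch <- small_cohort(seed = 14, n_features = 15, drift_amplitude = 0.4,
                     noise_rsd = 0.05, n_background = 0, n_batches = 1,
                     n_patients_bc = 12)
  tbl <- exclude_conditioning(ch$table)
  before <- qc_trend_diagnostics(tbl)
  corr <- correct_between_batch(correct_within_batch(tbl)$table)$table
  after <- qc_trend_diagnostics(corr)
  cor_with_order <- function(d) {
    abs(stats::cor(d$scores$PC1, d$scores$injection_order))
  }
  expect_lt(cor_with_order(after), cor_with_order(before))
  expect_lt(after$median_rsd, before$median_rsd)

  # identical QCs give all-zero scores
  samples <- tibble::tibble(
    sample_id = sprintf("Q%d", 1:4), patient_id = NA_character_,
    batch = 1L, injection_order = 1:4, role = "QC",
    class_label = NA_character_, visit_index = NA_integer_
  )
  m <- matrix(rep(c(10, 20), each = 4), nrow = 4,
              dimnames = list(NULL, c("F1", "F2")))
  d0 <- qc_trend_diagnostics(peak_table(samples, m))
  expect_true(all(abs(as.matrix(d0$scores[, -(1:3)])) < 1e-12))
})

test_that("the full correction stack is the identity on a flat cohort", {
  ch <- flat_cohort(seed = 5)
  res <- correct_batch_effects(ch$table)
  tbl0 <- exclude_conditioning(ch$table)
  expect_equal(intensity_matrix(res$table), intensity_matrix(tbl0),
               tolerance = 0)
})

test_that("missing intensities pass through correction as missing", {
  ch <- small_cohort(seed = 16, n_features = 8, n_discriminant = 0,
                     n_background = 0)
  tbl <- exclude_conditioning(ch$table)
  f1 <- feature_ids(tbl)[1]
  study <- which(tbl$role == "STUDY")[1:3]
  tbl[[f1]][study] <- NA_real_
  corr <- correct_between_batch(correct_within_batch(tbl)$table)$table
  expect_true(all(is.na(corr[[f1]][study])))
  expect_false(anyNA(corr[[f1]][-study]))
})
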