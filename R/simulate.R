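#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the acquisition design the correction and
#' classification stages assume: two analytical batches with conditioning
#' QCs at the head of each, a pooled QC injected periodically among the
#' study stream, blanks, smooth within-batch intensity drift, a
#' multiplicative between-batch offset, multiplicative log-normal noise
#' with constant coefficient of variation, a subset of features shifted
#' between the pre-resection (BC) and post-resection (CTRL) states, and
#' per-patient MONITOR trajectories drifting from the CTRL toward the BC
#' profile before recurrence.
#'
#' Each patient contributes a BC sample (visit 1), a CTRL sample
#' (visit 2) and, when `n_monitor_visits > 0`, that many MONITOR visits.
#' A `recurrence_fraction` of patients relapse: their MONITOR class effect
#' interpolates linearly from the CTRL level (none) to the full BC level,
#' reached at the final monitored visit. All samples of a patient are
#' assigned to a single batch.
#'
#' @param n_features Number of LC-MS features.
#' @param n_discriminant Number of features carrying a BC-vs-CTRL effect.
#' @param n_patients_bc Number of patients (each with one BC and one CTRL
#'   sample).
#' @param n_batches Number of analytical batches.
#' @param qc_interval One pooled QC is injected before every block of this
#'   many study/blank injections.
#' @param n_conditioning_qc Conditioning QC replicates at the head of each
#'   batch (excluded from analysis).
#' @param n_blanks Total number of blank injections, spread over batches.
#' @param n_background Number of background (contaminant) features that
#'   blanks share with all other samples.
#' @param drift_amplitude Maximum relative deviation of the within-batch
#'   drift factor from 1 (fraction of baseline).
#' @param between_batch_log2_range Per-feature batch factor is
#'   `2^u`, `u ~ Uniform(-r, r)` with this `r`.
#' @param noise_rsd Coefficient of variation of the multiplicative
#'   log-normal technical noise.
#' @param effect_log2fc Absolute log2 fold change of discriminant features
#'   between BC and CTRL; the sign is random per feature.
#' @param n_monitor_visits MONITOR visits per patient.
#' @param recurrence_fraction Fraction of patients whose monitored course
#'   ends in recurrence.
#' @param seed Integer seed; same seed and config give bit-identical
#'   cohorts.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_features = 200,
                             n_discriminant = 20,
                             n_patients_bc = 20,
                             n_batches = 2,
                             qc_interval = 5,
                             n_conditioning_qc = 8,
                             n_blanks = 4,
                             n_background = 6,
                             drift_amplitude = 0.3,
                             between_batch_log2_range = 0.5,
                             noise_rsd = 0.10,
                             effect_log2fc = 1,
                             n_monitor_visits = 0,
                             recurrence_fraction = 0.5,
                             seed = 1L) {
  cfg <- list(
    n_features = n_features, n_discriminant = n_discriminant,
    n_patients_bc = n_patients_bc, n_batches = n_batches,
    qc_interval = qc_interval, n_conditioning_qc = n_conditioning_qc,
    n_blanks = n_blanks, n_background = n_background,
    drift_amplitude = drift_amplitude,
    between_batch_log2_range = between_batch_log2_range,
    noise_rsd = noise_rsd, effect_log2fc = effect_log2fc,
    n_monitor_visits = n_monitor_visits,
    recurrence_fraction = recurrence_fraction, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_discriminant + cfg$n_background <= cfg$n_features,
    cfg$qc_interval >= 2,
    cfg$drift_amplitude >= 0, cfg$drift_amplitude < 1,
    cfg$noise_rsd >= 0, cfg$noise_rsd < 1,
    cfg$recurrence_fraction >= 0, cfg$recurrence_fraction <= 1,
    cfg$n_patients_bc >= cfg$n_batches
  )
  structure(cfg, class = "synthetic_config")
}

#' Injection layout for a synthetic cohort
#'
#' Per batch: the conditioning QCs first, then the randomized study/blank
#' stream with one pooled QC opening every block of `qc_interval`
#' injections. Patients are randomized between batches; all samples of a
#' patient stay in one batch.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with one row per injection: `batch`, `injection_order`,
#'   `role`, `patient_id`, `class_label`, `visit_index`.
#' @export
inject_layout <- function(config) {
  set.seed(config$seed)
  n_visits <- 2L + config$n_monitor_visits
  patients <- sprintf("P%03d", seq_len(config$n_patients_bc))
  # balanced random assignment of patients to batches
  pbatch <- sample(rep_len(seq_len(config$n_batches), length(patients)))
  names(pbatch) <- patients

  samples <- tidyr::expand_grid(
    patient_id = patients,
    visit_index = seq_len(n_visits)
  ) |>
    dplyr::mutate(
      class_label = dplyr::case_when(
        .data$visit_index == 1L ~ "BC",
        .data$visit_index == 2L ~ "CTRL",
        TRUE ~ "MONITOR"
      ),
      role = "STUDY",
      batch = unname(pbatch[.data$patient_id])
    )
  blanks <- tibble(
    patient_id = NA_character_, visit_index = NA_integer_,
    class_label = NA_character_, role = "BLANK",
    batch = rep_len(seq_len(config$n_batches),
                    length.out = config$n_blanks)
  )
  stream <- dplyr::bind_rows(samples, blanks)

  out <- purrr::map(seq_len(config$n_batches), function(b) {
    in_b <- stream[stream$batch == b, ]
    if (nrow(in_b) == 0) abort(paste0("batch ", b, " has no injections"))
    in_b <- in_b[sample.int(nrow(in_b)), ]
    n_blocks <- ceiling(nrow(in_b) / config$qc_interval)
    pieces <- purrr::map(seq_len(n_blocks), function(k) {
      idx <- ((k - 1) * config$qc_interval + 1):
        min(k * config$qc_interval, nrow(in_b))
      dplyr::bind_rows(
        tibble(patient_id = NA_character_, visit_index = NA_integer_,
               class_label = NA_character_, role = "QC", batch = b),
        in_b[idx, ]
      )
    })
    cond <- tibble(
      patient_id = NA_character_, visit_index = NA_integer_,
      class_label = NA_character_, role = "CONDITIONING_QC", batch = b
    )[rep(1, config$n_conditioning_qc), ]
    batch_tbl <- dplyr::bind_rows(cond, pieces)
    batch_tbl$injection_order <- seq_len(nrow(batch_tbl))
    batch_tbl
  }) |>
    purrr::list_rbind()
  out[c("batch", "injection_order", "role", "patient_id",
        "class_label", "visit_index")]
}

# smooth positive drift factor: cubic in normalized order, scaled so that
# max |d - 1| over the batch equals the requested amplitude
make_drift_poly <- function(amplitude) {
  coefs <- stats::runif(3, -1, 1)
  function(t01) {
    dev <- coefs[1] * t01 + coefs[2] * t01^2 + coefs[3] * t01^3
    grid <- seq(0, 1, length.out = 101)
    devg <- coefs[1] * grid + coefs[2] * grid^2 + coefs[3] * grid^3
    m <- max(abs(devg))
    if (m < .Machine$double.eps || amplitude == 0) return(rep(1, length(t01)))
    1 + dev * (amplitude / m)
  }
}

#' Generate a synthetic surveillance cohort with ground truth
#'
#' Intensity model per study sample s and feature f in batch k at
#' injection order t:
#' `x = b_f * e_f(class) * d_fk(t) * g_fk * eta`, with log-normal baseline
#' `b_f`, class effect `e_f` (`2^(+/- effect_log2fc)` on discriminant
#' features, 1 elsewhere), smooth positive drift `d_fk`, batch factor
#' `g_fk = 2^u`, and mean-1 log-normal noise `eta` with CV `noise_rsd`.
#' Pooled QCs carry the feature baseline (no class effect) under the same
#' drift, batch and noise terms, mirroring physical pooling of the study
#' samples. Blanks carry only the designated background features.
#'
#' @param config A [synthetic_config()].
#' @return List with `table` (a `peak_tbl`) and `truth` (list:
#'   `discriminant` tibble of feature ids and signed log2 fold changes,
#'   `background_ids`, `batch_factors` feature-by-batch matrix, `drift`
#'   function `(feature_id, batch, order)` returning the drift factor,
#'   `drift_order_range` per batch, `recurrence` tibble of patient id and
#'   recurrence visit or `NA`).
#' @export
generate_cohort <- function(config) {
  layout <- inject_layout(config)  # seeds the RNG with config$seed

  n_f <- config$n_features
  fid <- sprintf("F%04d", seq_len(n_f))
  features <- tibble(
    feature_id = fid,
    mz = sort(stats::runif(n_f, 70, 1700)),
    rt = stats::runif(n_f, 0.3, 9.5)
  )
  # moderate cross-feature dynamic range (~1 order of magnitude between
  # the 5th and 95th percentile); under the magnitude-weighted Pareto
  # scaling used downstream, a much wider spread would make fixed-VIP
  # screening blind to low-abundance markers by construction
  baseline <- stats::rlnorm(n_f, meanlog = log(1e4), sdlog = 0.4)
  names(baseline) <- fid

  special <- sample(fid, config$n_discriminant + config$n_background)
  disc_ids <- special[seq_len(config$n_discriminant)]
  bg_ids <- setdiff(special, disc_ids)
  sign <- sample(c(-1, 1), config$n_discriminant, replace = TRUE)
  log2fc <- sign * config$effect_log2fc
  names(log2fc) <- disc_ids

  r <- config$between_batch_log2_range
  batch_factors <- matrix(
    2^stats::runif(n_f * config$n_batches, -r, r),
    nrow = n_f, dimnames = list(fid, NULL)
  )
  drift_funs <- purrr::map(seq_len(config$n_batches), function(b) {
    purrr::map(fid, function(f) make_drift_poly(config$drift_amplitude))
  })
  order_range <- layout |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(max_order = max(.data$injection_order))

  drift_factor <- function(feature_id, batch, order) {
    j <- match(feature_id, fid)
    t01 <- (order - 1) / max(order_range$max_order[batch] - 1, 1)
    drift_funs[[batch]][[j]](t01)
  }

  # class-effect exponent as a fraction of the full BC effect
  relapse <- stats::runif(config$n_patients_bc) < config$recurrence_fraction
  patients <- sprintf("P%03d", seq_len(config$n_patients_bc))
  last_visit <- 2L + config$n_monitor_visits
  recurrence <- tibble(
    patient_id = patients,
    recurrence_visit = ifelse(relapse & config$n_monitor_visits > 0,
                              last_visit, NA_integer_)
  )

  sd_log <- sqrt(log(1 + config$noise_rsd^2))

  rows <- purrr::pmap(layout, function(batch, injection_order, role,
                                       patient_id, class_label,
                                       visit_index) {
    t01 <- (injection_order - 1) /
      max(order_range$max_order[batch] - 1, 1)
    d <- vapply(seq_len(n_f),
                function(j) drift_funs[[batch]][[j]](t01), numeric(1))
    g <- batch_factors[, batch]
    eta <- if (sd_log == 0) rep(1, n_f) else
      stats::rlnorm(n_f, meanlog = -sd_log^2 / 2, sdlog = sd_log)
    if (role == "BLANK") {
      base <- stats::setNames(rep(0, n_f), fid)
      base[bg_ids] <- baseline[bg_ids]
      return(base * d * g * eta)
    }
    e <- rep(1, n_f)
    if (role == "STUDY" && length(disc_ids) > 0) {
      full <- 2^log2fc
      frac <- switch(class_label,
        BC = 1,
        CTRL = 0,
        MONITOR = {
          rec <- recurrence$recurrence_visit[recurrence$patient_id ==
                                               patient_id]
          if (is.na(rec)) 0 else
            min(1, (visit_index - 2) / max(rec - 2, 1))
        },
        0)
      e[match(disc_ids, fid)] <- 1 + frac * (full - 1)
    }
    baseline * e * d * g * eta
  })
  m <- do.call(rbind, rows)
  colnames(m) <- fid

  samples <- layout |>
    dplyr::mutate(sample_id = sprintf("S%03d_B%d", dplyr::row_number(),
                                      .data$batch))
  tbl <- peak_table(samples, m, features)

  truth <- list(
    discriminant = tibble(feature_id = disc_ids, log2fc = unname(log2fc)),
    background_ids = bg_ids,
    baseline = baseline,
    batch_factors = batch_factors,
    drift = drift_factor,
    drift_order_range = order_range,
    recurrence = recurrence
  )
  list(table = tbl, truth = truth)
}
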