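# Small synthetic cohorts used across the suite. Sizes are deliberately
# tiny: two batches, a handful of patients, tens of features.

small_cohort <- function(seed = 1, n_features = 30, n_discriminant = 6,
                         n_patients_bc = 8, noise_rsd = 0.08,
                         drift_amplitude = 0.3, qc_interval = 3, ...) {
  generate_cohort(synthetic_config(
    n_features = n_features, n_discriminant = n_discriminant,
    n_patients_bc = n_patients_bc, noise_rsd = noise_rsd,
    drift_amplitude = drift_amplitude, qc_interval = qc_interval,
    seed = seed, ...
  ))
}

# a cohort with every perturbation switched off: intensities are exactly
# the per-feature baselines
flat_cohort <- function(seed = 1, ...) {
  generate_cohort(synthetic_config(
    n_features = 20, n_discriminant = 0, n_background = 0,
    n_patients_bc = 8, qc_interval = 3, drift_amplitude = 0,
    between_batch_log2_range = 0, noise_rsd = 0, effect_log2fc = 0,
    n_blanks = 2, seed = seed, ...
  ))
}

# hand-built 3-sample, 2-feature table
tiny_table <- function() {
  samples <- tibble::tibble(
    sample_id = c("QC1", "S1", "S2"),
    patient_id = c(NA, "P1", "P1"),
    batch = 1L, injection_order = 1:3,
    role = c("QC", "STUDY", "STUDY"),
    class_label = c(NA, "BC", "CTRL"),
    visit_index = c(NA, 1L, 2L)
  )
  m <- matrix(c(100, 110, 95, 200, 190, 210), nrow = 3,
              dimnames = list(NULL, c("F1", "F2")))
  peak_table(samples, m,
             features = tibble::tibble(feature_id = c("F1", "F2"),
                                       mz = c(120.5, 310.2),
                                       rt = c(1.2, 4.5)))
}

# metadata-only table builder: one constant feature, explicit roles
meta_table <- function(samples) {
  m <- matrix(1, nrow = nrow(samples), dimnames = list(NULL, "F1"))
  peak_table(samples, m)
}

# train/validation split of a cohort's patients (odd/even)
alternate_split <- function(tbl) {
  pts <- sort(unique(tbl$patient_id[tbl$role == "STUDY"]))
  stats::setNames(
    ifelse(seq_along(pts) %% 2 == 1, "train", "validation"), pts
  )
}
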