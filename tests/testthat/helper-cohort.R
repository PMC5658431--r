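# Shared fixtures built in code.

# A tiny hand-written valid ROI table: 2 patients x 1 kind x 2 sessions.
tiny_roi_table <- function() {
  tibble::tibble(
    patient_id = rep(c("A", "B"), each = 2),
    roi_kind = "whole_3d",
    session = rep(c("test", "retest"), 2),
    n_voxels = c(400L, 410L, 900L, 880L),
    mean_adc = c(100, 104, 120, 118),
    adc_sd = c(20, 22, 30, 28),
    motion_flag = c(FALSE, FALSE, FALSE, TRUE)
  )
}

# Symmetric one-pair table for hand-checkable uncertainty arithmetic.
symmetric_pair <- function(d = 109, w = 50, n = 2000) {
  tibble::tibble(
    patient_id = "A", roi_kind = "whole_3d",
    n_1 = n, mean_adc_1 = d, adc_sd_1 = w, motion_1 = FALSE,
    n_2 = n, mean_adc_2 = d, adc_sd_2 = w, motion_2 = FALSE,
    sem_1 = w / sqrt(n), sem_2 = w / sqrt(n),
    motion = FALSE, r12 = 0, delta_vol_pct = 0
  )
}

study_params <- function() {
  error_model_params(beta = 4.87, sigma_fix = 69.35, epsilon_sys = 2.65)
}

no_motion_config <- function(seed, n_patients = 20,
                             kinds = roi_kinds(tumour_only = TRUE), ...) {
  synthetic_config(n_patients = n_patients, roi_kinds = kinds,
                   motion_fraction = 0, seed = seed, ...)
}

make_records <- function(config) {
  repeatability(pair_sessions(generate_cohort(config), quiet = TRUE))
}
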