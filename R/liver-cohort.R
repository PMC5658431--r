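#' Bundled multi-site liver-metastasis test-retest summary
#'
#' Per-patient summary of a prospective multi-site, multi-vendor test-retest
#' study of 20 patients with colorectal liver metastases, scanned twice
#' within 7 days on 1.5 T systems from three vendors.  For each patient's
#' whole-tumour 3D ROI the table records the voxel count and mean ADC
#' averaged over the two sessions, the symmetric percent change in tumour
#' volume (`delta_vol_pct`) and in mean ADC (`delta_adc_pct`) between
#' sessions, a free-text lesion note, and whether visible motion artefact
#' was present in either acquisition.
#'
#' Only between-session averages and percent changes are available at the
#' per-patient level (per-session values and ADC histogram widths were not
#' published), so this table supports group-level statistics but not
#' refitting the error model.  ADC is in 10^-5 mm^2/s; one voxel is
#' 11.25 mm^3 (see [voxels_to_volume()]).
#'
#' @return A 20-row tibble with columns `patient_id`, `avg_voxels`,
#'   `delta_vol_pct`, `avg_mean_adc`, `delta_adc_pct`, `lesion_note`,
#'   `motion_flag`.
#' @export
#' @examples
#' cohort <- liver_cohort()
#' group_summary(cohort$delta_vol_pct)
liver_cohort <- function() {
  path <- system.file("extdata", "liver_cohort.csv", package = "adcrepeat",
                      mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         patient_id = readr::col_character(),
                         avg_voxels = readr::col_integer(),
                         delta_vol_pct = readr::col_double(),
                         avg_mean_adc = readr::col_double(),
                         delta_adc_pct = readr::col_double(),
                         lesion_note = readr::col_character(),
                         motion_flag = readr::col_logical()
                       ))
  x$lesion_note[is.na(x$lesion_note)] <- ""
  # transcription sanity checks
  stopifnot(nrow(x) == 20, sum(x$motion_flag) == 5,
            all(x$avg_mean_adc >= 76 & x$avg_mean_adc <= 198))
  x
}
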