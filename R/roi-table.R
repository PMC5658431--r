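#' Validate a table of per-session ROI summaries
#'
#' An ROI measurement row describes one imaging session of one region of
#' interest: the number of voxels `n_voxels`, the ROI mean ADC `mean_adc`
#' and ADC histogram standard deviation `adc_sd` (both in 10^-5 mm^2/s),
#' and a `motion_flag` marking visible motion artefact in that acquisition.
#'
#' @param x A data frame with columns `patient_id`, `roi_kind`, `session`,
#'   `n_voxels`, `mean_adc`, `adc_sd`, `motion_flag`.
#' @return `x` as a tibble, invisibly, if valid; otherwise an error naming
#'   the offending column or rows.
#' @export
validate_roi_table <- function(x) {
  required <- c("patient_id", "roi_kind", "session", "n_voxels",
                "mean_adc", "adc_sd", "motion_flag")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("ROI table is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  bad_kind <- which(!x$roi_kind %in% ROI_KINDS)
  if (length(bad_kind) > 0) {
    abort(sprintf(
      "`roi_kind` must be one of %s; invalid in row(s) %s.",
      paste(ROI_KINDS, collapse = ", "), paste(head(bad_kind, 5), collapse = ", ")))
  }
  bad_session <- which(!x$session %in% SESSIONS)
  if (length(bad_session) > 0) {
    abort(sprintf("`session` must be 'test' or 'retest'; invalid in row(s) %s.",
                  paste(head(bad_session, 5), collapse = ", ")))
  }
  check_rows <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      abort(sprintf("Invalid ROI measurement: %s in row(s) %s.",
                    what, paste(head(bad, 5), collapse = ", ")))
    }
  }
  check_rows(is.finite(x$n_voxels) & x$n_voxels >= 1 &
               x$n_voxels == round(x$n_voxels), "`n_voxels` must be a positive integer")
  check_rows(is.finite(x$mean_adc) & x$mean_adc > 0, "`mean_adc` must be > 0")
  check_rows(is.finite(x$adc_sd) & x$adc_sd >= 0, "`adc_sd` must be >= 0")
  check_rows(!is.na(x$motion_flag), "`motion_flag` must be TRUE/FALSE")
  invisible(x)
}

#' Read a delimiter-separated table of ROI session summaries
#'
#' Reads and validates a text table with one row per (patient, ROI kind,
#' session).  Expected columns: `patient_id`, `roi_kind` (one of
#' [roi_kinds()]), `session` (`"test"`/`"retest"`), `n_voxels`, `mean_adc`,
#' `adc_sd` (10^-5 mm^2/s), `motion_flag` (logical).  A parse report
#' (rows read / rejected) is attached as attribute `"parse_report"`; any
#' invariant violation is an error naming the row, so a successfully
#' returned table always has zero rejected rows.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, default `","`.
#' @return A validated tibble of ROI measurements, row order preserved.
#' @seealso [write_roi_table()], [pair_sessions()]
#' @export
read_roi_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  x <- validate_roi_table(x)
  x$n_voxels <- as.integer(x$n_voxels)
  x$motion_flag <- as.logical(x$motion_flag)
  attr(x, "parse_report") <- list(rows_read = nrow(x), rows_rejected = 0L)
  x
}

#' Write a table of ROI session summaries
#'
#' @param x A data frame passing [validate_roi_table()].
#' @param path Output path.
#' @param delim Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(x, path, delim = ",") {
  validate_roi_table(x)
  readr::write_delim(tibble::as_tibble(x), path, delim = delim)
  invisible(path)
}

#' Match test and retest sessions into ROI pairs
#'
#' Joins the two imaging sessions of each (patient, ROI kind) into one row,
#' deriving the standard error of each session's ROI mean as
#' `sem = adc_sd / sqrt(n_voxels)` (the size-dependent component of
#' measurement uncertainty).  A pair is flagged as motion-affected if either
#' session is.  Measurements lacking a partner session are not silently
#' dropped: they are returned in the `"unpaired"` attribute and reported.
#'
#' @param measurements A validated ROI measurement table
#'   (see [read_roi_table()]).
#' @param quiet If `TRUE`, suppress the unpaired-measurement message.
#' @return A tibble with one row per pair and columns `patient_id`,
#'   `roi_kind`, `n_1`, `mean_adc_1`, `adc_sd_1`, `motion_1`, `sem_1`
#'   (session 1 = test) and the `_2` equivalents (retest), plus `motion`
#'   (either session flagged).  Attribute `"unpaired"` holds the unmatched
#'   input rows.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 4, seed = 1))
#' pair_sessions(cohort)
pair_sessions <- function(measurements, quiet = FALSE) {
  x <- validate_roi_table(measurements)
  dup <- dplyr::count(x, .data$patient_id, .data$roi_kind, .data$session) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate (patient, roi_kind, session) measurements, e.g. %s / %s / %s.",
      dup$patient_id[1], dup$roi_kind[1], dup$session[1]))
  }
  wide <- tidyr::pivot_wider(
    x,
    id_cols = c("patient_id", "roi_kind"),
    names_from = "session",
    values_from = c("n_voxels", "mean_adc", "adc_sd", "motion_flag")
  )
  needed <- c("n_voxels_test", "n_voxels_retest")
  for (col in setdiff(c(needed, "mean_adc_test", "mean_adc_retest",
                        "adc_sd_test", "adc_sd_retest",
                        "motion_flag_test", "motion_flag_retest"),
                      names(wide))) {
    wide[[col]] <- NA
  }
  complete <- !is.na(wide$n_voxels_test) & !is.na(wide$n_voxels_retest)
  unpaired_keys <- wide[!complete, c("patient_id", "roi_kind")]
  unpaired <- dplyr::semi_join(x, unpaired_keys, by = c("patient_id", "roi_kind"))
  if (nrow(unpaired) > 0 && !quiet) {
    inform(sprintf("%d measurement(s) had no partner session and were set aside.",
                   nrow(unpaired)))
  }
  pairs <- wide[complete, ] |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      roi_kind = .data$roi_kind,
      n_1 = .data$n_voxels_test,
      mean_adc_1 = .data$mean_adc_test,
      adc_sd_1 = .data$adc_sd_test,
      motion_1 = .data$motion_flag_test,
      n_2 = .data$n_voxels_retest,
      mean_adc_2 = .data$mean_adc_retest,
      adc_sd_2 = .data$adc_sd_retest,
      motion_2 = .data$motion_flag_retest,
      sem_1 = .data$adc_sd_1 / sqrt(.data$n_1),
      sem_2 = .data$adc_sd_2 / sqrt(.data$n_2),
      motion = .data$motion_1 | .data$motion_2
    )
  attr(pairs, "unpaired") <- unpaired
  pairs
}
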