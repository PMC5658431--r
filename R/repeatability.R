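#' Symmetric percent change between paired measurements
#'
#' The repeatability metric used throughout: the difference between the two
#' sessions normalised by their mean,
#' \deqn{R_{12} = 200 (d_1 - d_2) / (d_1 + d_2),}
#' in percent.  Applied to mean ADC it gives the per-lesion ADC
#' repeatability (often written \eqn{\Delta ADC\%}); applied to voxel counts
#' it gives the volume repeatability (\eqn{\Delta VOL\%}).  It is
#' antisymmetric in its arguments and bounded in (-200, 200) for positive
#' inputs.
#'
#' @param d1,d2 Numeric vectors of paired positive measurements
#'   (test, retest).
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(110, 90)   # 20
#' percent_change(90, 110)   # -20
percent_change <- function(d1, d2) {
  if (any(!is.finite(d1)) || any(!is.finite(d2))) {
    abort("`d1` and `d2` must be finite.")
  }
  if (any(d1 + d2 <= 0)) {
    abort("percent_change() requires d1 + d2 > 0 for every pair.")
  }
  200 * (d1 - d2) / (d1 + d2)
}

#' Per-pair repeatability records
#'
#' Augments a paired-session table (see [pair_sessions()]) with the
#' repeatability statistics: `r12`, the symmetric percent change in mean
#' ADC between test and retest, and `delta_vol_pct`, the same statistic
#' applied to the ROI voxel counts.
#'
#' @param pairs A tibble of test-retest pairs from [pair_sessions()].
#' @return `pairs` with columns `r12` and `delta_vol_pct` appended.
#' @seealso [standardise()] which adds the model-predicted uncertainty and
#'   the standardised residual `z`.
#' @export
repeatability <- function(pairs) {
  check_pairs(pairs)
  dplyr::mutate(
    tibble::as_tibble(pairs),
    r12 = percent_change(.data$mean_adc_1, .data$mean_adc_2),
    delta_vol_pct = percent_change(.data$n_1, .data$n_2)
  )
}

check_pairs <- function(pairs, require = c("patient_id", "roi_kind", "n_1",
                                           "mean_adc_1", "adc_sd_1", "n_2",
                                           "mean_adc_2", "adc_sd_2", "motion")) {
  missing_cols <- setdiff(require, names(pairs))
  if (length(missing_cols) > 0) {
    abort(sprintf("Paired table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  invisible(pairs)
}

#' Group summary of a repeatability distribution
#'
#' Summarises a collection of percent-change values by their mean, standard
#' deviation and 95% confidence-interval width, the latter defined as
#' `1.96 * sd`.  That width is the threshold conventionally used to declare
#' a statistically significant change in an individual follow-up
#' measurement.  The default standard deviation uses the population (n)
#' denominator, which is the convention under which the bundled cohort's
#' printed summary values (SD 8.2, width 16.1 for volume change) are
#' reproduced exactly; `sd_method = "sample"` gives the n-1 denominator.
#'
#' @param values Numeric vector (percent), length >= 2.
#' @param sd_method `"population"` (default) or `"sample"`.
#' @param conf_mult Multiplier converting SD to interval width; default 1.96
#'   (two-sided 95% for a Gaussian).
#' @return A one-row tibble with `n`, `mean`, `sd`, `ci_width_95`.
#' @export
#' @examples
#' group_summary(liver_cohort()$delta_vol_pct)
group_summary <- function(values, sd_method = c("population", "sample"),
                          conf_mult = 1.96) {
  sd_method <- match.arg(sd_method)
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("group_summary() needs at least 2 values.")
  }
  s <- stat_sd(values, sd_method)
  tibble::tibble(n = length(values), mean = mean(values), sd = s,
                 ci_width_95 = conf_mult * s)
}

stat_sd <- function(x, method) {
  n <- length(x)
  if (method == "population") sd(x) * sqrt((n - 1) / n) else sd(x)
}

#' Within-subject coefficient of variation of paired ADC measurements
#'
#' The standard test-retest coefficient of variation on the absolute mean
#' ADC values:
#' \deqn{CoV = 100 \cdot SD(d_1 - d_2) / (\sqrt{2} \cdot \bar d),}
#' where \eqn{\bar d} is the grand mean of all session means.  The
#' \eqn{\sqrt 2} converts the SD of a difference of two equally-noisy
#' measurements to a per-measurement SD.  Scale-invariant.
#'
#' @param pairs A paired-session tibble (see [pair_sessions()]).
#' @param sd_method Passed to the SD of the within-pair differences;
#'   `"population"` (default) or `"sample"`.
#' @return CoV in percent (scalar).
#' @export
within_subject_cov <- function(pairs, sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  check_pairs(pairs, require = c("mean_adc_1", "mean_adc_2"))
  if (nrow(pairs) < 2) abort("within_subject_cov() needs at least 2 pairs.")
  diffs <- pairs$mean_adc_1 - pairs$mean_adc_2
  grand <- mean(c(pairs$mean_adc_1, pairs$mean_adc_2))
  if (grand <= 0) abort("Grand mean ADC must be positive.")
  100 * stat_sd(diffs, sd_method) / (sqrt(2) * grand)
}
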