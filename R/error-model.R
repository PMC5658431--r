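#' Measurement-error model parameters
#'
#' Container for the three-parameter model of the statistical uncertainty
#' on an ADC repeatability measurement:
#' \deqn{\varepsilon^2 = \beta^2 \varepsilon^2(\sigma_{D_1}, \sigma_{D_2})
#'       + \varepsilon^2(\sigma_{fix}/\sqrt{N_1}, \sigma_{fix}/\sqrt{N_2})
#'       + \varepsilon_{sys}^2,}
#' where \eqn{\varepsilon(\cdot,\cdot)} is the error-propagation formula of
#' [propagate_error()] and \eqn{\sigma_{D_j} = w_j / \sqrt{N_j}} is the
#' standard error of session j's ROI mean from its histogram width
#' \eqn{w_j} and voxel count \eqn{N_j}.
#'
#' * `beta`: dimensionless multiplier on the histogram-width (standard
#'   error of the mean) term; absorbs spatial noise correlation and other
#'   inflation of the nominal SEM.
#' * `sigma_fix`: fixed per-voxel fitting dispersion in 10^-5 mm^2/s,
#'   entering each session's mean-ADC error as `sigma_fix / sqrt(N)`.
#' * `epsilon_sys`: irreducible systematic (scanner) error in percent.
#'
#' Nested variants: `"sys_only"` (beta = sigma_fix = 0) and `"two_param"`
#' (sigma_fix = 0).
#'
#' @param beta,sigma_fix,epsilon_sys Non-negative scalars (see above).
#' @param variant One of `"three_param"`, `"two_param"`, `"sys_only"`.
#' @return An object of class `error_model_params`.
#' @export
#' @examples
#' error_model_params(beta = 4.87, sigma_fix = 69.35, epsilon_sys = 2.65)
error_model_params <- function(beta = 0, sigma_fix = 0, epsilon_sys = 0,
                               variant = c("three_param", "two_param", "sys_only")) {
  variant <- match.arg(variant)
  stopifnot_scalar_number(beta, "beta", min = 0)
  stopifnot_scalar_number(sigma_fix, "sigma_fix", min = 0)
  stopifnot_scalar_number(epsilon_sys, "epsilon_sys", min = 0)
  if (variant == "sys_only" && (beta != 0 || sigma_fix != 0)) {
    abort("Variant 'sys_only' requires beta = 0 and sigma_fix = 0.")
  }
  if (variant == "two_param" && sigma_fix != 0) {
    abort("Variant 'two_param' requires sigma_fix = 0.")
  }
  structure(list(beta = beta, sigma_fix = sigma_fix,
                 epsilon_sys = epsilon_sys, variant = variant),
            class = "error_model_params")
}

#' @export
print.error_model_params <- function(x, ...) {
  cat(sprintf("<error_model_params: %s>\n", x$variant))
  cat(sprintf("  beta        = %.4g\n", x$beta))
  cat(sprintf("  sigma_fix   = %.4g (1e-5 mm^2/s per voxel)\n", x$sigma_fix))
  cat(sprintf("  epsilon_sys = %.4g %%\n", x$epsilon_sys))
  invisible(x)
}

#' @export
tidy.error_model_params <- function(x, ...) {
  tibble::tibble(term = c("beta", "sigma_fix", "epsilon_sys"),
                 estimate = c(x$beta, x$sigma_fix, x$epsilon_sys))
}

as_error_model_params <- function(x) {
  if (inherits(x, "adc_error_fit")) return(x$params)
  if (inherits(x, "error_model_params")) return(x)
  abort("Expected an `error_model_params` object or an `adc_error_fit`.")
}

#' Propagate per-session mean-ADC errors to repeatability uncertainty
#'
#' First-order error propagation of the uncertainties on the two session
#' means through the symmetric percent change [percent_change()]:
#' \deqn{\varepsilon(\sigma_{D_1}, \sigma_{D_2}) =
#'   400 \sqrt{D_1^2 \sigma_{D_2}^2 + D_2^2 \sigma_{D_1}^2} / (D_1+D_2)^2,}
#' in percent.  Homogeneous of degree zero: rescaling all four arguments by
#' a common factor leaves the result unchanged.  In the symmetric case
#' \eqn{D_1 = D_2 = D}, \eqn{\sigma_1 = \sigma_2 = \sigma} it reduces to
#' \eqn{100\sqrt 2\,\sigma/D}.
#'
#' @param d1,d2 Session mean ADCs (positive, 10^-5 mm^2/s).
#' @param s1,s2 Uncertainties on `d1` and `d2` (same units, >= 0).
#' @return Uncertainty of the percent change, in percent (vectorised).
#' @export
#' @examples
#' propagate_error(100, 100, 1, 1)  # 100*sqrt(2)/100 = 1.4142...
propagate_error <- function(d1, d2, s1, s2) {
  if (any(d1 + d2 <= 0)) abort("propagate_error() requires d1 + d2 > 0.")
  if (any(s1 < 0) || any(s2 < 0)) abort("Uncertainties must be >= 0.")
  400 * sqrt(d1^2 * s2^2 + d2^2 * s1^2) / (d1 + d2)^2
}

#' Model-predicted uncertainty of each repeatability measurement
#'
#' Evaluates the three-term error model (see [error_model_params()]) for
#' every test-retest pair: the histogram-width term uses each session's
#' standard error of the mean `adc_sd / sqrt(n)` scaled by `beta`; the
#' fixed fitting term contributes `sigma_fix / sqrt(n)` per session; the
#' systematic term adds `epsilon_sys` in quadrature.
#'
#' @param pairs A paired-session tibble (see [pair_sessions()]); columns
#'   `mean_adc_1/2`, `adc_sd_1/2`, `n_1/2` are used.
#' @param params An [error_model_params()] object or a fitted
#'   [fit_error_model()] result.
#' @return Numeric vector of predicted uncertainties in percent, one per
#'   pair; an error if any prediction is exactly zero (such a model cannot
#'   be used to standardise data).
#' @export
total_uncertainty <- function(pairs, params) {
  params <- as_error_model_params(params)
  check_pairs(pairs)
  t_width <- params$beta * propagate_error(
    pairs$mean_adc_1, pairs$mean_adc_2,
    pairs$adc_sd_1 / sqrt(pairs$n_1), pairs$adc_sd_2 / sqrt(pairs$n_2))
  t_fix <- propagate_error(
    pairs$mean_adc_1, pairs$mean_adc_2,
    params$sigma_fix / sqrt(pairs$n_1), params$sigma_fix / sqrt(pairs$n_2))
  eps <- sqrt(t_width^2 + t_fix^2 + params$epsilon_sys^2)
  if (any(eps == 0)) {
    abort(paste("Model predicts zero uncertainty for at least one pair;",
                "standardisation would divide by zero."))
  }
  eps
}

#' Uncertainty of a single symmetric ROI measurement
#'
#' Convenience evaluation of [total_uncertainty()] for a hypothetical pair
#' with equal sessions (`D1 = D2 = d_nominal`, `N1 = N2 = n_voxels`,
#' common histogram SD `adc_sd`) -- the quantity tabulated by the look-up
#' chart.
#'
#' @param n_voxels ROI size(s) in voxels.
#' @param adc_sd ADC histogram SD(s) in 10^-5 mm^2/s.
#' @param params [error_model_params()] or fitted model.
#' @param d_nominal Nominal mean ADC level (default 109 x 10^-5 mm^2/s,
#'   the whole-tumour cohort average).
#' @return Predicted uncertainty in percent (vectorised over
#'   `n_voxels`/`adc_sd`).
#' @export
roi_uncertainty <- function(n_voxels, adc_sd, params, d_nominal = 109) {
  params <- as_error_model_params(params)
  if (any(n_voxels < 1)) abort("`n_voxels` must be >= 1.")
  if (any(adc_sd < 0)) abort("`adc_sd` must be >= 0.")
  stopifnot_scalar_number(d_nominal, "d_nominal", min = .Machine$double.eps)
  sem <- adc_sd / sqrt(n_voxels)
  t_width <- params$beta * propagate_error(d_nominal, d_nominal, sem, sem)
  sem_fix <- params$sigma_fix / sqrt(n_voxels)
  t_fix <- propagate_error(d_nominal, d_nominal, sem_fix, sem_fix)
  sqrt(t_width^2 + t_fix^2 + params$epsilon_sys^2)
}

#' Build a look-up grid of uncertainty vs ROI size and histogram width
#'
#' Tabulates the model-predicted repeatability uncertainty for a grid of
#' ROI sizes (voxels, log-spaced by default) and ADC histogram standard
#' deviations, at a nominal ADC level.  An investigator with a measured
#' ROI size and histogram SD can read off the statistical uncertainty of a
#' percent ADC change without refitting the model.  Cells decrease with
#' ROI size at fixed SD and increase with SD at fixed size, approaching
#' `epsilon_sys` for huge, narrow ROIs.
#'
#' @param params [error_model_params()] or fitted model.
#' @param n_grid Voxel counts; default 40 log-spaced values in
#'   `[50, 20000]`.
#' @param sd_grid Histogram SDs in 10^-5 mm^2/s; default `seq(5, 100, 5)`.
#' @param d_nominal Nominal ADC level, default 109.
#' @return A tibble of class `adc_lookup` with columns `n_voxels`,
#'   `volume_cm3`, `adc_sd`, `epsilon_pct`; attributes `params` and
#'   `d_nominal`.
#' @seealso [write_lookup()], [autoplot.adc_lookup()]
#' @export
#' @examples
#' p <- error_model_params(beta = 4.87, sigma_fix = 69.35, epsilon_sys = 2.65)
#' grid <- build_lookup(p)
#' dplyr::filter(grid, adc_sd == 50, n_voxels > 1900, n_voxels < 2300)
build_lookup <- function(params,
                         n_grid = round(exp(seq(log(50), log(20000), length.out = 40))),
                         sd_grid = seq(5, 100, by = 5),
                         d_nominal = 109) {
  params <- as_error_model_params(params)
  if (length(n_grid) < 1 || length(sd_grid) < 1) abort("Grids must be non-empty.")
  if (any(n_grid < 1)) abort("`n_grid` values must be >= 1.")
  if (any(sd_grid < 0)) abort("`sd_grid` values must be >= 0.")
  grid <- tidyr::expand_grid(n_voxels = sort(unique(n_grid)),
                             adc_sd = sort(unique(sd_grid)))
  grid$volume_cm3 <- voxels_to_volume(grid$n_voxels, units = "cm3")
  grid$epsilon_pct <- roi_uncertainty(grid$n_voxels, grid$adc_sd, params,
                                      d_nominal = d_nominal)
  grid <- grid[, c("n_voxels", "volume_cm3", "adc_sd", "epsilon_pct")]
  structure(grid, params = params, d_nominal = d_nominal,
            class = c("adc_lookup", class(grid)))
}

#' Export a look-up grid as CSV (plus JSON metadata)
#'
#' Writes the grid in wide form: one row per voxel count, one column per
#' histogram SD, cells in percent.  The numeric export is the normative
#' artifact; plots are cosmetic.
#'
#' @param grid An `adc_lookup` tibble from [build_lookup()].
#' @param path Output CSV path.
#' @param meta_path Optional JSON path for the model parameters and nominal
#'   ADC level; default `NULL` (not written).
#' @return `path`, invisibly.
#' @export
write_lookup <- function(grid, path, meta_path = NULL) {
  if (!inherits(grid, "adc_lookup")) abort("`grid` must come from build_lookup().")
  wide <- tidyr::pivot_wider(tibble::as_tibble(grid)[, c("n_voxels", "adc_sd", "epsilon_pct")],
                             names_from = "adc_sd", values_from = "epsilon_pct",
                             names_prefix = "sd_")
  readr::write_csv(wide, path)
  if (!is.null(meta_path)) {
    p <- attr(grid, "params")
    jsonlite::write_json(
      list(beta = p$beta, sigma_fix = p$sigma_fix, epsilon_sys = p$epsilon_sys,
           variant = p$variant, d_nominal = attr(grid, "d_nominal")),
      meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Plot a look-up grid
#'
#' Heat map of predicted uncertainty over ROI size (log axis) and histogram
#' SD, or iso-SD curves of uncertainty vs size.
#'
#' @param object An `adc_lookup` tibble.
#' @param style `"heatmap"` (default) or `"curves"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adc_lookup <- function(object, style = c("heatmap", "curves"), ...) {
  style <- match.arg(style)
  df <- tibble::as_tibble(object)
  if (style == "heatmap") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$n_voxels, y = .data$adc_sd,
                                     fill = .data$epsilon_pct)) +
      ggplot2::geom_tile() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_fill_viridis_c(name = "uncertainty (%)") +
      ggplot2::labs(x = "ROI size (voxels, log scale)",
                    y = "ADC histogram SD (1e-5 mm²/s)",
                    title = "Predicted repeatability uncertainty") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$n_voxels, y = .data$epsilon_pct,
                                     group = .data$adc_sd,
                                     colour = .data$adc_sd)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_colour_viridis_c(name = "histogram SD") +
      ggplot2::labs(x = "ROI size (voxels, log scale)",
                    y = "predicted uncertainty (%)") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.adc_lookup
#' @param grid An `adc_lookup` tibble.
#' @export
plot_lookup <- function(grid, style = c("heatmap", "curves")) {
  autoplot.adc_lookup(grid, style = style)
}
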