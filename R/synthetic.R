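#' Configuration for a synthetic test-retest cohort
#'
#' Defines the ground truth for [generate_cohort()].  Defaults mirror the
#' reference liver-metastasis study: 20 patients, four ROI kinds, tumour
#' sizes log-uniform over 100-10000 voxels, true mean ADC uniform over
#' 76-198 x 10^-5 mm^2/s, 25% of patients motion-corrupted, and error-model
#' truth (beta = 4.87, sigma_fix = 69.35, epsilon_sys = 2.65).
#'
#' Biological heterogeneity is drawn per ROI from `w_bio_range` (default
#' 10-60 x 10^-5 mm^2/s, spanning the histogram widths used as worked
#' examples in the look-up chart); a lesion-varying width is also what
#' makes `beta` and `sigma_fix` jointly identifiable, since both scale as
#' 1/sqrt(N) but only the width term scales with w.  Session voxel counts
#' jitter around the lesion size with relative SD `vol_jitter`
#' (default 0.058, chosen so the simulated volume-change SD matches the
#' observed ~8.2%).  Parenchyma ROIs use a fixed size (`parenchyma_voxels`)
#' with no volume jitter, emulating fixed-dimension normal-liver ROIs.
#'
#' @param n_patients Number of patients (default 20).
#' @param roi_kinds ROI kinds to simulate; subset of [roi_kinds()].
#' @param n_voxel_range Log-uniform bounds for tumour size in voxels.
#' @param parenchyma_voxels Fixed parenchyma ROI size (voxels).
#' @param adc_range Uniform bounds for true mean ADC (10^-5 mm^2/s).
#' @param w_bio_range Uniform bounds for per-ROI biological histogram width
#'   (10^-5 mm^2/s).
#' @param beta,sigma_fix,epsilon_sys True error-model parameters
#'   (see [error_model_params()]).
#' @param motion_fraction Probability that a patient's dataset is
#'   motion-corrupted (one random session across all their ROIs).
#' @param motion_bias_range Magnitude bounds (percent) of the one-sided
#'   multiplicative ADC bias applied to a motion-corrupted session.
#' @param vol_jitter Relative SD of per-session voxel-count jitter.
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20,
                             roi_kinds = c("whole_3d", "slice_largest",
                                           "slice_solid", "parenchyma"),
                             n_voxel_range = c(100, 10000),
                             parenchyma_voxels = 125,
                             adc_range = c(76, 198),
                             w_bio_range = c(10, 60),
                             beta = 4.87, sigma_fix = 69.35, epsilon_sys = 2.65,
                             motion_fraction = 0.25,
                             motion_bias_range = c(5, 30),
                             vol_jitter = 0.058,
                             seed) {
  if (missing(seed)) abort("`seed` is mandatory in synthetic_config().")
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(n_patients, "n_patients", min = 1)
  roi_kinds <- match.arg(roi_kinds, ROI_KINDS, several.ok = TRUE)
  check_range <- function(r, name, min = 0) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
        r[1] > r[2] || r[1] < min) {
      abort(sprintf("`%s` must be a non-decreasing range with lower bound >= %s.",
                    name, format(min)))
    }
  }
  check_range(n_voxel_range, "n_voxel_range", min = 2)
  check_range(adc_range, "adc_range", min = .Machine$double.eps)
  check_range(w_bio_range, "w_bio_range", min = 0)
  check_range(motion_bias_range, "motion_bias_range", min = 0)
  stopifnot_scalar_number(parenchyma_voxels, "parenchyma_voxels", min = 2)
  stopifnot_scalar_number(beta, "beta", min = 0)
  stopifnot_scalar_number(sigma_fix, "sigma_fix", min = 0)
  stopifnot_scalar_number(epsilon_sys, "epsilon_sys", min = 0)
  stopifnot_scalar_number(vol_jitter, "vol_jitter", min = 0)
  if (motion_fraction < 0 || motion_fraction > 1) {
    abort("`motion_fraction` must be in [0, 1].")
  }
  structure(list(
    n_patients = as.integer(n_patients), roi_kinds = roi_kinds,
    n_voxel_range = n_voxel_range, parenchyma_voxels = as.integer(parenchyma_voxels),
    adc_range = adc_range, w_bio_range = w_bio_range,
    beta = beta, sigma_fix = sigma_fix, epsilon_sys = epsilon_sys,
    motion_fraction = motion_fraction, motion_bias_range = motion_bias_range,
    vol_jitter = vol_jitter, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config: %d patients x %d ROI kinds, seed %d>\n",
              x$n_patients, length(x$roi_kinds), x$seed))
  cat(sprintf("  truth: beta = %.3g, sigma_fix = %.3g, epsilon_sys = %.3g\n",
              x$beta, x$sigma_fix, x$epsilon_sys))
  cat(sprintf("  motion: fraction %.2f, bias %g-%g%%\n",
              x$motion_fraction, x$motion_bias_range[1], x$motion_bias_range[2]))
  invisible(x)
}

#' Generate a synthetic test-retest ROI cohort
#'
#' Simulates paired-session ROI summaries with exactly the statistical
#' structure the error model assumes.  Per patient x ROI kind: a lesion
#' size N (log-uniform) and true mean ADC (uniform) are drawn, along with a
#' biological histogram width.  Each session then observes:
#' * a jittered voxel count `N_j`;
#' * a histogram SD `w_j` equal to the biological width times chi-square
#'   sampling jitter (the spread an `N_j`-voxel sample SD would show);
#' * a mean ADC `D_true * (1 + g_j) + u_j + v_j`, where
#'   `g_j ~ N(0, epsilon_sys / (100 sqrt(2)))` is the session-level
#'   systematic error (so its paired contribution to the percent-change SD
#'   is `epsilon_sys`), `u_j ~ N(0, (beta w_j / sqrt(N_j))^2)` is the
#'   width-term error and `v_j ~ N(0, (sigma_fix / sqrt(N_j))^2)` the fixed
#'   fitting error.
#'
#' A `motion_fraction` share of patients (binomial draw) has one random
#' session corrupted: all that session's ROI means are multiplied by
#' `1 + s * U(bias range)/100` with a random sign `s`, and flagged.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A long ROI-measurement tibble (one row per patient x kind x
#'   session) passing [validate_roi_table()]; the configuration is attached
#'   as attribute `"truth"`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 5, seed = 42))
#' repeatability(pair_sessions(cohort))
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config object.")
  }
  c_ <- config
  with_seed(c_$seed, {
    grid <- tidyr::expand_grid(
      patient_id = sprintf("P%02d", seq_len(c_$n_patients)),
      roi_kind = c_$roi_kinds)
    n_roi <- nrow(grid)
    n_base <- ifelse(
      grid$roi_kind == "parenchyma", c_$parenchyma_voxels,
      round(exp(runif(n_roi, log(c_$n_voxel_range[1]), log(c_$n_voxel_range[2])))))
    d_true <- runif(n_roi, c_$adc_range[1], c_$adc_range[2])
    w_bio <- runif(n_roi, c_$w_bio_range[1], c_$w_bio_range[2])

    # patient-level motion: one random session biased across all ROIs
    hit <- runif(c_$n_patients) < c_$motion_fraction
    hit_session <- sample(SESSIONS, c_$n_patients, replace = TRUE)
    bias <- sample(c(-1, 1), c_$n_patients, replace = TRUE) *
      runif(c_$n_patients, c_$motion_bias_range[1], c_$motion_bias_range[2]) / 100
    patient_idx <- match(grid$patient_id,
                         sprintf("P%02d", seq_len(c_$n_patients)))

    one_session <- function(session) {
      jitter <- ifelse(grid$roi_kind == "parenchyma", 0,
                       rnorm(n_roi, 0, c_$vol_jitter))
      n_j <- pmax(2L, as.integer(round(n_base * (1 + jitter))))
      w_j <- w_bio * sqrt(rchisq(n_roi, n_j - 1) / (n_j - 1))
      g <- rnorm(n_roi, 0, c_$epsilon_sys / (100 * sqrt(2)))
      u <- rnorm(n_roi, 0, c_$beta * w_j / sqrt(n_j))
      v <- rnorm(n_roi, 0, c_$sigma_fix / sqrt(n_j))
      d_obs <- d_true * (1 + g) + u + v
      corrupt <- hit[patient_idx] & hit_session[patient_idx] == session
      d_obs[corrupt] <- d_obs[corrupt] * (1 + bias[patient_idx][corrupt])
      tibble::tibble(
        patient_id = grid$patient_id, roi_kind = grid$roi_kind,
        session = session, n_voxels = n_j,
        mean_adc = pmax(d_obs, 1e-3), adc_sd = w_j,
        motion_flag = corrupt)
    }
    out <- dplyr::bind_rows(one_session("test"), one_session("retest"))
    out <- dplyr::arrange(out, .data$patient_id, .data$roi_kind,
                          match(.data$session, SESSIONS))
    validate_roi_table(out)
    attr(out, "truth") <- c_
    out
  })
}

#' Generate a synthetic multi-b-value DWI phantom
#'
#' Builds a 4-D magnitude image stack following mono-exponential decay,
#' `S(b) = s0 * exp(-b * ADC)`, with per-voxel ADC drawn from a Gaussian
#' lesion distribution inside an ellipsoidal lesion and a background
#' distribution outside, plus optional Rician magnitude noise of scale
#' `noise_sigma` (two independent Gaussian channels in quadrature).  Used
#' to exercise the ADC-mapping stage end to end.
#'
#' @param dims Image dimensions in voxels, length 3.
#' @param b_values Diffusion weightings in s/mm^2; default
#'   `c(100, 500, 900)`.
#' @param lesion_centre Lesion centre (voxel coordinates); default the
#'   image centre.
#' @param lesion_radius Lesion semi-axes in voxels (scalar or length 3).
#' @param lesion_mean,lesion_sd Lesion ADC distribution (10^-5 mm^2/s).
#' @param background_mean,background_sd Background ADC distribution.
#' @param s0 Unweighted signal amplitude (> 0).
#' @param noise_sigma Rician noise scale (>= 0, signal units).
#' @param seed Integer seed.
#' @return A list of class `dwi_phantom`: `b_values`, `signals` (4-D array,
#'   last axis = b), `mask` (logical 3-D lesion mask), `adc_true` (3-D),
#'   `noise_sigma`, `s0`.
#' @seealso [adc_map()], [summarise_roi()], [write_phantom_nifti()]
#' @export
generate_dwi_phantom <- function(dims = c(32, 32, 12),
                                 b_values = c(100, 500, 900),
                                 lesion_centre = (dims + 1) / 2,
                                 lesion_radius = c(8, 8, 4),
                                 lesion_mean = 109, lesion_sd = 20,
                                 background_mean = 150, background_sd = 10,
                                 s0 = 1000, noise_sigma = 0, seed = 1L) {
  if (length(dims) != 3L || any(dims < 1)) abort("`dims` must be 3 positive sizes.")
  if (length(b_values) < 2 || length(unique(b_values)) < 2) {
    abort("Need at least 2 distinct b-values.")
  }
  if (s0 <= 0) abort("`s0` must be positive.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (length(lesion_radius) == 1) lesion_radius <- rep(lesion_radius, 3)
  if (any(lesion_centre - lesion_radius < 1) ||
      any(lesion_centre + lesion_radius > dims)) {
    abort("Lesion does not fit inside the image.")
  }
  with_seed(seed, {
    ix <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                      z = seq_len(dims[3]))
    r2 <- ((ix$x - lesion_centre[1]) / lesion_radius[1])^2 +
      ((ix$y - lesion_centre[2]) / lesion_radius[2])^2 +
      ((ix$z - lesion_centre[3]) / lesion_radius[3])^2
    mask <- array(r2 <= 1, dim = dims)
    n_vox <- prod(dims)
    adc <- rnorm(n_vox, background_mean, background_sd)
    adc[mask] <- rnorm(sum(mask), lesion_mean, lesion_sd)
    adc <- pmax(adc, 1)
    adc_true <- array(adc, dim = dims)
    signals <- array(0, dim = c(dims, length(b_values)))
    for (k in seq_along(b_values)) {
      s <- s0 * exp(-b_values[k] * adc_to_mm2s(adc_true))
      if (noise_sigma > 0) {
        s <- sqrt((s + rnorm(n_vox, 0, noise_sigma))^2 +
                    rnorm(n_vox, 0, noise_sigma)^2)
      }
      signals[, , , k] <- s
    }
    structure(list(b_values = b_values, signals = signals, mask = mask,
                   adc_true = adc_true, noise_sigma = noise_sigma, s0 = s0),
              class = "dwi_phantom")
  })
}

#' Write a DWI phantom to NIfTI files
#'
#' Writes the per-b-value magnitude volumes and the lesion mask as NIfTI
#' images (requires the suggested RNifti package).
#'
#' @param phantom A [generate_dwi_phantom()] result.
#' @param dir Output directory (created if needed).
#' @param voxel_dims Voxel edge lengths in mm for the header.
#' @return Character vector of file paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir, voxel_dims = c(1.5, 1.5, 5)) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("write_phantom_nifti() requires the RNifti package.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(phantom$b_values)) {
    p <- file.path(dir, sprintf("b%04d.nii.gz", phantom$b_values[k]))
    img <- RNifti::asNifti(phantom$signals[, , , k], pixdim = voxel_dims)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$mask * 1, pixdim = voxel_dims), mp)
  invisible(c(paths, mp))
}

#' Parameter-recovery study for the error-model fit
#'
#' Repeatedly simulates cohorts from a known truth, fits the requested
#' model variant to each (motion excluded), and summarises the per-replicate
#' estimates as median / IQR and median relative bias versus truth.  Fit
#' failures are recorded per replicate, not fatal.
#'
#' @param config A [synthetic_config()] holding the truth; replicate r uses
#'   seed `config$seed + r`.
#' @param n_replicates Number of simulated cohorts (>= 1).
#' @param variant Model variant to fit (see [fit_error_model()]).
#' @param n_starts Optimiser starts per fit.
#' @return A tibble of class `recovery_study` with one row per replicate
#'   (`replicate`, `beta`, `sigma_fix`, `epsilon_sys`, `nll`, `converged`,
#'   `failed`); attributes `truth` (the config) and `summary` (per-parameter
#'   median, IQR and median relative bias).
#' @export
recovery_study <- function(config, n_replicates = 200,
                           variant = "three_param", n_starts = 8) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config object.")
  }
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  one <- function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    res <- tryCatch({
      cohort <- generate_cohort(cfg)
      records <- repeatability(pair_sessions(cohort, quiet = TRUE))
      fit <- fit_error_model(records, variant = variant,
                             exclude_motion = TRUE, n_starts = n_starts,
                             seed = cfg$seed)
      tibble::tibble(replicate = r, beta = fit$params$beta,
                     sigma_fix = fit$params$sigma_fix,
                     epsilon_sys = fit$params$epsilon_sys,
                     nll = fit$neg_log_likelihood,
                     converged = fit$converged, failed = FALSE)
    }, error = function(e) {
      tibble::tibble(replicate = r, beta = NA_real_, sigma_fix = NA_real_,
                     epsilon_sys = NA_real_, nll = NA_real_,
                     converged = FALSE, failed = TRUE)
    })
    res
  }
  out <- purrr::map_dfr(seq_len(n_replicates), one)
  truth_vec <- c(beta = config$beta, sigma_fix = config$sigma_fix,
                 epsilon_sys = config$epsilon_sys)
  summarise_param <- function(name) {
    est <- out[[name]][!out$failed]
    med <- median(est, na.rm = TRUE)
    tv <- truth_vec[[name]]
    tibble::tibble(
      term = name, truth = tv, median = med,
      iqr_lo = quantile(est, 0.25, na.rm = TRUE, names = FALSE),
      iqr_hi = quantile(est, 0.75, na.rm = TRUE, names = FALSE),
      median_rel_bias = if (tv > 0) (med - tv) / tv else NA_real_)
  }
  smry <- purrr::map_dfr(c("beta", "sigma_fix", "epsilon_sys"), summarise_param)
  structure(out, truth = config, summary = smry,
            class = c("recovery_study", class(out)))
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Recovery study: %d replicates (%d failed)\n",
              nrow(x), sum(x$failed)))
  print(attr(x, "summary"))
  invisible(x)
}
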