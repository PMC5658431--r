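#' Rician noise-floor correction of magnitude signal
#'
#' Magnitude MRI noise has a positive floor that biases low-SNR signal
#' upward, which inflates the apparent decay at high b-values and hence
#' biases ADC.  For single-coil Rician magnitude, `E[M^2] = A^2 + 2 sigma^2`
#' with `A` the true amplitude, so a moment-consistent estimate of `A` is
#' the quadrature subtraction
#' `sqrt(max(signal^2 - 2 * noise_sigma^2, floor))`.
#'
#' The clamp `floor` handles the degenerate branch
#' `signal^2 <= 2 sigma^2`: by default it is `noise_sigma^2` (always capped
#' at `signal^2`, so the correction never increases the signal).  Clamping
#' at the noise scale, rather than near zero, stops over-subtracted voxels
#' from collapsing towards zero and blowing up downstream log-domain
#' fitting; a magnitude at or below the noise floor carries no usable
#' amplitude information anyway.
#'
#' @param signal Magnitude signal(s), >= 0.
#' @param noise_sigma Noise scale in signal units, >= 0.
#' @param floor Clamp on the corrected squared signal; default
#'   `noise_sigma^2` (with a 1e-12 lower bound so the zero-noise case stays
#'   the identity).
#' @return Corrected signal(s), in `[0, signal]`.
#' @export
#' @examples
#' correct_noise_floor(100, 10)   # sqrt(100^2 - 200)
#' correct_noise_floor(12, 10)    # clamped to the noise scale, 10
correct_noise_floor <- function(signal, noise_sigma,
                                floor = pmax(noise_sigma^2, 1e-12)) {
  if (any(signal < 0) || any(noise_sigma < 0)) {
    abort("`signal` and `noise_sigma` must be >= 0.")
  }
  if (any(floor <= 0)) abort("`floor` must be a small positive clamp.")
  sq <- pmax(signal^2 - 2 * noise_sigma^2, pmin(floor, signal^2))
  sqrt(sq)
}

#' Voxel-wise mono-exponential ADC estimation
#'
#' Estimates ADC from multi-b-value magnitude signals by ordinary least
#' squares on the log-signal: the negated slope of `ln S` versus `b`.
#' Signals are first noise-floor corrected ([correct_noise_floor()]);
#' non-positive corrected values are treated as unusable.  A voxel
#' needs at least two usable points at distinct b-values; otherwise it is
#' marked invalid (`NA`), never an exception.  Results are reported in
#' 10^-5 mm^2/s.
#'
#' `fit_adc()` handles a single voxel (vector of signals); [adc_map()]
#' handles a full stack.
#'
#' @param signals Numeric vector, one magnitude value per b-value.
#' @param b_values Diffusion weightings in s/mm^2 (>= 2 distinct).
#' @param noise_sigma Magnitude-noise scale (default 0 = no correction).
#' @return ADC in 10^-5 mm^2/s, or `NA` for an invalid voxel.
#' @export
#' @examples
#' b <- c(100, 500, 900)
#' fit_adc(1000 * exp(-b * 109e-5), b)   # 109 exactly
fit_adc <- function(signals, b_values, noise_sigma = 0) {
  res <- adc_map(matrix(signals, nrow = 1), b_values, noise_sigma = noise_sigma)
  res$adc[1]
}

#' @rdname fit_adc
#' @param signals_matrix Either an `n_voxels x n_b` matrix or a 4-D array
#'   whose last axis indexes b-values.
#' @return For `adc_map()`: a list with `adc` (same spatial shape as the
#'   input, 10^-5 mm^2/s, `NA` where invalid) and `valid` (logical mask of
#'   successful fits).  Invalid voxels are excluded from all downstream
#'   statistics.
#' @export
adc_map <- function(signals_matrix, b_values, noise_sigma = 0) {
  if (length(b_values) < 2 || length(unique(b_values)) < 2) {
    abort("Need at least 2 distinct b-values.")
  }
  dims4 <- NULL
  if (is.array(signals_matrix) && length(dim(signals_matrix)) == 4) {
    dims4 <- dim(signals_matrix)
    if (dims4[4] != length(b_values)) {
      abort("Last array axis must match the number of b-values.")
    }
    signals_matrix <- matrix(signals_matrix, ncol = dims4[4])
  }
  if (!is.matrix(signals_matrix) || ncol(signals_matrix) != length(b_values)) {
    abort("`signals_matrix` must have one column per b-value.")
  }
  corr <- correct_noise_floor(signals_matrix, noise_sigma)
  usable <- is.finite(corr) & corr > 0
  y <- log(pmax(corr, .Machine$double.xmin))
  y[!usable] <- 0
  bmat <- matrix(b_values, nrow(corr), ncol(corr), byrow = TRUE)
  k <- rowSums(usable)
  sx <- rowSums(usable * bmat)
  sy <- rowSums(usable * y)
  sxx <- rowSums(usable * bmat^2)
  sxy <- rowSums(usable * bmat * y)
  denom <- k * sxx - sx^2
  slope <- ifelse(denom > 0, (k * sxy - sx * sy) / denom, NA_real_)
  adc <- -slope * 1e5
  valid <- k >= 2 & is.finite(adc)
  adc[!valid] <- NA_real_
  if (!is.null(dims4)) {
    adc <- array(adc, dim = dims4[1:3])
    valid <- array(valid, dim = dims4[1:3])
  }
  list(adc = adc, valid = valid)
}

#' Summarise an ADC map over an ROI mask
#'
#' Pools the valid voxel ADC values inside the mask into the per-session
#' ROI summary used by the repeatability pipeline: voxel count `N`,
#' arithmetic mean `D`, and histogram width `w` as the sample standard
#' deviation (N-1 denominator).  The raw voxel values are attached as
#' attribute `"adc_values"` for histogram export.  Statistics are invariant
#' to voxel ordering.
#'
#' @param map An [adc_map()] result (or a list with `adc` and `valid`).
#' @param mask Logical mask (same shape as `map$adc`) or integer voxel
#'   indices.
#' @param patient_id,session,roi_kind,motion_flag Metadata for the output
#'   row.
#' @return A one-row ROI-measurement tibble (see [validate_roi_table()]).
#' @export
summarise_roi <- function(map, mask, patient_id = "P01", session = "test",
                          roi_kind = "whole_3d", motion_flag = FALSE) {
  if (!is.list(map) || is.null(map$adc) || is.null(map$valid)) {
    abort("`map` must be an adc_map() result with `adc` and `valid`.")
  }
  if (is.logical(mask)) {
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
  }
  idx <- idx[map$valid[idx]]
  vals <- map$adc[idx]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    abort("Empty ROI: no valid voxels inside the mask.")
  }
  w <- if (length(vals) > 1) sd(vals) else 0
  out <- tibble::tibble(
    patient_id = patient_id, roi_kind = roi_kind, session = session,
    n_voxels = length(vals), mean_adc = mean(vals), adc_sd = w,
    motion_flag = motion_flag)
  validate_roi_table(out)
  attr(out, "adc_values") <- vals
  out
}

#' Read a multi-b-value NIfTI stack and mask
#'
#' Thin wrappers over RNifti (suggested dependency) returning plain arrays
#' suitable for [adc_map()] and [summarise_roi()].
#'
#' @param paths NIfTI file paths, one per b-value (in `b_values` order), or
#'   a single 4-D file.
#' @param b_values Diffusion weightings matching `paths`.
#' @return A list with `b_values` and `signals` (4-D array).
#' @export
read_bvalue_stack <- function(paths, b_values) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("read_bvalue_stack() requires the RNifti package.")
  }
  vols <- lapply(paths, function(p) as.array(RNifti::readNifti(p)))
  if (length(vols) == 1 && length(dim(vols[[1]])) == 4) {
    signals <- vols[[1]]
  } else {
    if (length(vols) != length(b_values)) {
      abort("Need one volume per b-value.")
    }
    signals <- array(0, dim = c(dim(vols[[1]]), length(vols)))
    for (k in seq_along(vols)) signals[, , , k] <- vols[[k]]
  }
  list(b_values = b_values, signals = signals)
}

#' @rdname read_bvalue_stack
#' @param path Path to a NIfTI label volume; voxels with value > 0 are in
#'   the mask.
#' @export
read_mask <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("read_mask() requires the RNifti package.")
  }
  as.array(RNifti::readNifti(path)) > 0
}
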