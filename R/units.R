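#' Convert ROI voxel counts to physical volume
#'
#' ADC maps in the reference acquisition protocol use 1.5 x 1.5 mm pixels
#' and 5 mm slices, so one voxel corresponds to 11.25 mm^3.  The voxel
#' geometry is configurable for other protocols.
#'
#' @param n_voxels Numeric vector of voxel counts (each >= 0).
#' @param voxel_dims Length-3 numeric vector of voxel edge lengths in mm
#'   (in-plane x, in-plane y, slice thickness).  Default `c(1.5, 1.5, 5)`.
#' @param units Output units, `"mm3"` (default) or `"cm3"`.
#' @return Numeric vector of volumes.
#' @export
#' @examples
#' voxels_to_volume(1)                  # 11.25 mm^3
#' voxels_to_volume(2000, units = "cm3") # 22.5 cm^3
voxels_to_volume <- function(n_voxels, voxel_dims = c(1.5, 1.5, 5),
                             units = c("mm3", "cm3")) {
  units <- match.arg(units)
  if (!is.numeric(n_voxels) || any(!is.finite(n_voxels)) || any(n_voxels < 0)) {
    abort("`n_voxels` must be finite and non-negative.")
  }
  if (!is.numeric(voxel_dims) || length(voxel_dims) != 3L || any(voxel_dims <= 0)) {
    abort("`voxel_dims` must be three positive edge lengths in mm.")
  }
  mm3 <- n_voxels * prod(voxel_dims)
  if (units == "cm3") mm3 / 1000 else mm3
}

#' Convert between the package ADC scale and mm^2/s
#'
#' ADC values are stored and reported throughout in units of 10^-5 mm^2/s
#' (the convention of the cohort tables this package reproduces); typical
#' liver-lesion values are then of order 100.  These helpers convert to and
#' from plain mm^2/s.
#'
#' @param x Numeric vector.
#' @return Numeric vector on the other scale.
#' @export
#' @examples
#' adc_to_mm2s(109)    # 1.09e-3 mm^2/s
#' adc_from_mm2s(1.09e-3)
adc_to_mm2s <- function(x) x * 1e-5

#' @rdname adc_to_mm2s
#' @export
adc_from_mm2s <- function(x) x * 1e5
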