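#' Illumination geometry
#'
#' Polar/azimuthal incidence angles of the (plane-wave) illumination and the
#' refractive index of the medium between sample and sensor.  The carrier
#' spatial frequencies follow `f_x = n sin(theta) cos(phi) / lambda`,
#' `f_y = n sin(theta) sin(phi) / lambda`.
#'
#' @param theta_rad polar incidence angle in radians, in `[0, pi/2)`.
#' @param phi_rad azimuthal angle in radians.
#' @param medium_index refractive index, >= 1.
#' @return an object of class `illumination_geometry`.
#' @export
illumination_geometry <- function(theta_rad = 0, phi_rad = 0, medium_index = 1) {
  if (!is.finite(theta_rad) || theta_rad < 0 || theta_rad >= pi / 2)
    stop("illumination_geometry: theta_rad must lie in [0, pi/2)", call. = FALSE)
  if (!is.finite(medium_index) || medium_index < 1)
    stop("illumination_geometry: medium_index must be >= 1", call. = FALSE)
  structure(list(theta_rad = theta_rad, phi_rad = phi_rad,
                 medium_index = medium_index),
            class = "illumination_geometry")
}

#' Angular-spectrum transfer kernel
#'
#' Frequency-domain kernel for exact scalar free-space propagation over a
#' distance `z`: `exp(+i 2 pi z sqrt((n/lambda)^2 - fx^2 - fy^2))` on
#' propagating frequencies (`fx^2 + fy^2 <= (n/lambda)^2`), exactly 0 on
#' evanescent ones.  The sign of `distance_um` selects forward (+z, object to
#' sensor) versus backward (-z) propagation; the time convention is
#' `exp(+i 2 pi ...)` throughout the package.
#'
#' @param grid a [grid_spec()]; spatial frequencies are derived from its
#'   pitch in cycles/um on the standard FFT lattice (zero frequency first).
#' @param wavelength_nm illumination wavelength in nanometres (> 0).
#' @param distance_um signed propagation distance in micrometres.
#' @param medium_index refractive index of the propagation medium (> 0).
#' @return complex matrix of shape `(height_px, width_px)` in FFT frequency
#'   ordering, unit magnitude on propagating frequencies, 0 elsewhere.
#' @export
angular_spectrum_kernel <- function(grid, wavelength_nm, distance_um,
                                    medium_index = 1) {
  if (!is_grid_spec(grid)) stop("angular_spectrum_kernel: grid must be a grid_spec", call. = FALSE)
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("angular_spectrum_kernel: wavelength_nm must be positive", call. = FALSE)
  if (!is.finite(medium_index) || medium_index <= 0)
    stop("angular_spectrum_kernel: medium_index must be positive", call. = FALSE)
  lambda_um <- wavelength_nm * 1e-3
  fy <- fft_freq(grid$height_px, grid$pitch_um)
  fx <- fft_freq(grid$width_px, grid$pitch_um)
  f2 <- outer(fy^2, fx^2, `+`)
  fmax2 <- (medium_index / lambda_um)^2
  kernel <- matrix(0 + 0i, grid$height_px, grid$width_px)
  prop <- f2 <= fmax2
  kz <- sqrt(fmax2 - f2[prop])           # cycles/um along z
  kernel[prop] <- exp(2i * pi * distance_um * kz)
  kernel
}

#' Propagate a field through free space
#'
#' Angular-spectrum propagation: inverse transform of the kernel times the
#' forward transform of the field, on the same grid.  Energy carried by
#' propagating frequencies is conserved; evanescent content is removed
#' (hard cutoff).
#'
#' @param field a [complex_field()].
#' @inheritParams angular_spectrum_kernel
#' @return a [complex_field()] on the same grid.
#' @export
propagate <- function(field, wavelength_nm, distance_um, medium_index = 1) {
  if (!is_complex_field(field)) stop("propagate: field must be a complex_field", call. = FALSE)
  kernel <- angular_spectrum_kernel(field$grid, wavelength_nm, distance_um,
                                    medium_index)
  propagate_with_kernel(field, kernel)
}

# Propagation with a precomputed kernel (hot path of the GS iteration).
propagate_with_kernel <- function(field, kernel) {
  if (!identical(dim(kernel), dim(field$values)))
    stop("propagate: kernel/lattice shape mismatch", call. = FALSE)
  spec <- stats::fft(field$values)
  out <- stats::fft(spec * kernel, inverse = TRUE) / length(spec)
  complex_field(out, field$grid)
}

#' Plane-wave tilt carrier
#'
#' Unit-magnitude phase ramp `exp(i 2 pi (f_x x + f_y y))` of a tilted
#' plane-wave illumination, sampled on the grid, with the carrier
#' frequencies given by the illumination geometry.
#'
#' @param geometry an [illumination_geometry()].
#' @param wavelength_nm wavelength in nm (> 0).
#' @param grid a [grid_spec()].
#' @return a [complex_field()] of unit magnitude.
#' @export
tilt_carrier <- function(geometry, wavelength_nm, grid) {
  if (!inherits(geometry, "illumination_geometry"))
    stop("tilt_carrier: geometry must be an illumination_geometry", call. = FALSE)
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("tilt_carrier: wavelength_nm must be positive", call. = FALSE)
  lambda_um <- wavelength_nm * 1e-3
  fx <- geometry$medium_index * sin(geometry$theta_rad) *
    cos(geometry$phi_rad) / lambda_um
  fy <- geometry$medium_index * sin(geometry$theta_rad) *
    sin(geometry$phi_rad) / lambda_um
  co <- grid_coords(grid)
  ramp <- exp(2i * pi * (outer(fy * co$y, fx * co$x, `+`)))
  complex_field(ramp, grid)
}

#' Inter-wavelength phase rescaling
#'
#' When the reconstruction wavelength changes from `lambda_from` to
#' `lambda_to`, the retrieved phase of a thin object is rescaled by the
#' wavelength ratio (optical path length, not phase, is wavelength
#' invariant): each pixel's wrapped phase `phi` in `(-pi, pi]` becomes
#' `phi * lambda_from / lambda_to`; the amplitude is unchanged.
#'
#' @param field a [complex_field()].
#' @param lambda_from_nm,lambda_to_nm positive wavelengths in nm.
#' @return a [complex_field()] with identical magnitudes and rescaled phase.
#' @export
phase_rescale <- function(field, lambda_from_nm, lambda_to_nm) {
  if (!is.finite(lambda_from_nm) || lambda_from_nm <= 0 ||
      !is.finite(lambda_to_nm) || lambda_to_nm <= 0)
    stop("phase_rescale: wavelengths must be positive", call. = FALSE)
  if (lambda_from_nm == lambda_to_nm) return(field)
  ratio <- lambda_from_nm / lambda_to_nm
  v <- field$values
  complex_field(Mod(v) * exp(1i * Arg(v) * ratio), field$grid)
}
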