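#' Sampling grid specification
#'
#' A `grid_spec` describes the 2-D sampling lattice shared by fields,
#' holograms and image planes: pixel counts and the physical pixel pitch.
#'
#' @param height_px,width_px positive integers, at least 2.
#' @param pitch_um physical sampling interval in micrometres (> 0).
#' @return an object of class `grid_spec`.
#' @examples
#' grid_spec(64, 64, 1.85)
#' @export
grid_spec <- function(height_px, width_px, pitch_um) {
  height_px <- as.integer(height_px)
  width_px <- as.integer(width_px)
  if (is.na(height_px) || is.na(width_px) || height_px < 2L || width_px < 2L)
    stop("grid_spec: height_px and width_px must be integers >= 2", call. = FALSE)
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || !is.finite(pitch_um) ||
      pitch_um <= 0)
    stop("grid_spec: pitch_um must be a positive finite number", call. = FALSE)
  structure(list(height_px = height_px, width_px = width_px,
                 pitch_um = as.numeric(pitch_um)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, pitch %.4g um (%.4g x %.4g um)\n",
              x$height_px, x$width_px, x$pitch_um,
              x$height_px * x$pitch_um, x$width_px * x$pitch_um))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

grids_equal <- function(a, b) {
  a$height_px == b$height_px && a$width_px == b$width_px &&
    isTRUE(all.equal(a$pitch_um, b$pitch_um))
}

#' Complex optical field on a grid
#'
#' Carries a 2-D lattice of complex field amplitude (dimensionless) together
#' with its sampling grid.  Used for objects, object estimates and
#' sensor-plane wavefronts.
#'
#' @param values complex (or real, promoted) matrix of shape
#'   `(height_px, width_px)`; all entries must be finite.
#' @param grid a [grid_spec()].
#' @return an object of class `complex_field`.
#' @export
complex_field <- function(values, grid) {
  if (!is_grid_spec(grid)) stop("complex_field: grid must be a grid_spec", call. = FALSE)
  if (!is.matrix(values)) stop("complex_field: values must be a matrix", call. = FALSE)
  if (nrow(values) != grid$height_px || ncol(values) != grid$width_px)
    stop(sprintf("complex_field: values are %d x %d but grid says %d x %d",
                 nrow(values), ncol(values), grid$height_px, grid$width_px),
         call. = FALSE)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("complex_field: all entries must be finite", call. = FALSE)
  structure(list(values = values, grid = grid), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px, pitch %.4g um, |.| in [%.4g, %.4g]\n",
              x$grid$height_px, x$grid$width_px, x$grid$pitch_um,
              min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}

is_complex_field <- function(x) inherits(x, "complex_field")

#' Field amplitude (modulus)
#' @param field a [complex_field()].
#' @return real matrix of per-pixel magnitudes.
#' @export
field_amplitude <- function(field) Mod(field$values)

#' Field intensity (squared modulus)
#' @param field a [complex_field()].
#' @return real matrix of per-pixel intensities.
#' @export
field_intensity <- function(field) Mod(field$values)^2

# Discrete-transform frequency lattice in cycles/um, zero frequency first
# (standard FFT ordering); works for even and odd n.
fft_freq <- function(n, pitch_um) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k / (n * pitch_um)
}

# Pixel-centre spatial coordinates in um, origin at the first sample.
grid_coords <- function(grid) {
  list(x = (seq_len(grid$width_px) - 1) * grid$pitch_um,
       y = (seq_len(grid$height_px) - 1) * grid$pitch_um)
}
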