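# Per-band wavelength-scanning pixel super-resolution and phase retrieval.
#
# The object estimate O_C lives at super-resolved pitch (sensor pitch / L).
# Each Gerchberg-Saxton style iteration cycles the band's wavelengths in
# ascending order: forward-propagate O_C to the sensor plane, enforce the
# measured hologram amplitude there, back-propagate, and rescale the phase
# before switching to the next wavelength. After the last wavelength the
# phase is rescaled back to the band's first wavelength so O_C is always
# referenced to lambda_1.

#' Reconstruction settings
#'
#' @param z2_um sample-sensor distance in um (> 0).
#' @param upsample_factor_L positive integer up-sampling rate (default 4).
#' @param n_iterations number of full passes over the band's wavelengths
#'   (default 15, the middle of the usual 5-20 range).
#' @param initial_filter_px odd mean-filter kernel for the initial guess
#'   (default 3).
#' @param constraint_mode `"block_scale"` (default): each L x L block of the
#'   sensor-plane field is scaled so its mean intensity matches the measured
#'   pixel while intra-block (super-resolved) structure survives;
#'   `"replace"`: per-pixel magnitude replaced by the upsampled measurement
#'   (kept for ablation -- it collapses sub-pixel detail to the interpolant).
#' @param upsample_method interpolation for hologram up-sampling
#'   (`"bicubic"` default).
#' @param phase_rescale_on whether the inter-wavelength phase correction is
#'   applied (default TRUE).
#' @return an object of class `recon_settings`.
#' @export
recon_settings <- function(z2_um, upsample_factor_L = 4L, n_iterations = 15L,
                           initial_filter_px = 3L,
                           constraint_mode = c("block_scale", "replace"),
                           upsample_method = c("bicubic", "bilinear", "nearest"),
                           phase_rescale_on = TRUE) {
  constraint_mode <- match.arg(constraint_mode)
  upsample_method <- match.arg(upsample_method)
  n_iterations <- as.integer(n_iterations)
  initial_filter_px <- as.integer(initial_filter_px)
  if (!is.finite(z2_um) || z2_um <= 0)
    stop("recon_settings: z2_um must be positive", call. = FALSE)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("recon_settings: n_iterations must be >= 1", call. = FALSE)
  if (is.na(initial_filter_px) || initial_filter_px < 1L ||
      initial_filter_px %% 2L == 0L)
    stop("recon_settings: initial_filter_px must be odd", call. = FALSE)
  structure(list(z2_um = z2_um,
                 upsample_factor_L = as.integer(upsample_factor_L),
                 n_iterations = n_iterations,
                 initial_filter_px = initial_filter_px,
                 constraint_mode = constraint_mode,
                 upsample_method = upsample_method,
                 phase_rescale_on = isTRUE(phase_rescale_on)),
            class = "recon_settings")
}

#' Initial object guess from a band's hologram stack
#'
#' For every wavelength the square root of the up-sampled hologram is taken
#' as a zero-phase sensor-plane amplitude and back-propagated to the object
#' plane; the per-wavelength magnitudes are averaged across the band
#' (magnitudes, not complex fields: phases scale with wavelength and complex
#' sums interfere destructively) and mean-filtered.  The result is returned
#' as a zero-phase amplitude estimate.
#'
#' @param stack_band named list of sensor-pitch intensity matrices (one per
#'   wavelength) as stored in a `hologram_stack` band.
#' @param plan_band ascending numeric vector of the band's wavelengths (nm).
#' @param settings a [recon_settings()].
#' @param sensor_grid [grid_spec()] of the holograms.
#' @return an `object_estimate` (see [reconstruct_channel()]) with an empty
#'   residual history.
#' @export
initial_guess <- function(stack_band, plan_band, settings, sensor_grid) {
  if (length(stack_band) == 0L || length(plan_band) == 0L)
    stop("initial_guess: empty band", call. = FALSE)
  if (length(stack_band) != length(plan_band))
    stop("initial_guess: stack and wavelength plan sizes differ", call. = FALSE)
  L <- settings$upsample_factor_L
  sg <- grid_spec(sensor_grid$height_px * L, sensor_grid$width_px * L,
                  sensor_grid$pitch_um / L)
  acc <- matrix(0, sg$height_px, sg$width_px)
  for (k in seq_along(plan_band)) {
    amp <- sqrt(pmax(upsample_hologram(stack_band[[k]], L,
                                       settings$upsample_method), 0))
    u <- complex_field(amp, sg)
    o <- propagate(u, plan_band[k], -settings$z2_um)
    acc <- acc + Mod(o$values)
  }
  amp0 <- box_filter(acc / length(plan_band), settings$initial_filter_px)
  object_estimate(complex_field(amp0, sg), band = NA_character_,
                  residual_history = numeric(0))
}

object_estimate <- function(field, band, residual_history) {
  structure(list(field = field, band = band,
                 residual_history = residual_history),
            class = "object_estimate")
}

#' @export
print.object_estimate <- function(x, ...) {
  cat(sprintf("<object_estimate> band %s, %d x %d px @ %.4g um, %d iterations\n",
              x$band, x$field$grid$height_px, x$field$grid$width_px,
              x$field$grid$pitch_um, length(x$residual_history)))
  if (length(x$residual_history))
    cat(sprintf("  residual: first %.3e, last %.3e\n",
                x$residual_history[1],
                x$residual_history[length(x$residual_history)]))
  invisible(x)
}

#' Enforce a measured hologram on a sensor-plane field
#'
#' The Gerchberg-Saxton amplitude constraint, adapted to a super-resolved
#' field meeting a sensor-pitch measurement.  Phase is preserved exactly in
#' both modes.  `block_scale` multiplies each `L x L` block's magnitudes by
#' `sqrt(I_measured / block-mean(|U|^2))`, so every block-mean intensity
#' equals the measurement while intra-block structure survives; `replace`
#' substitutes per-pixel magnitudes by the square root of the up-sampled
#' measurement.
#'
#' @param U a [complex_field()] at super-resolved pitch.
#' @param I_measured sensor-pitch intensity matrix with
#'   `dim(U) = dim(I_measured) * L`.
#' @param L positive integer block size.
#' @param mode `"block_scale"` or `"replace"`.
#' @param upsample_method interpolation used by `replace` mode.
#' @return the constrained [complex_field()].
#' @export
apply_amplitude_constraint <- function(U, I_measured, L,
                                       mode = c("block_scale", "replace"),
                                       upsample_method = "bicubic") {
  mode <- match.arg(mode)
  L <- as.integer(L)
  if (nrow(U$values) != nrow(I_measured) * L ||
      ncol(U$values) != ncol(I_measured) * L)
    stop("apply_amplitude_constraint: U dimensions must be I_measured x L",
         call. = FALSE)
  I_measured <- pmax(I_measured, 0)
  if (mode == "replace") {
    amp <- sqrt(pmax(upsample_hologram(I_measured, L, upsample_method), 0))
    phase <- Arg(U$values)
    return(complex_field(amp * exp(1i * phase), U$grid))
  }
  eps <- 1e-12
  block_mean <- bin_to_sensor(Mod(U$values)^2, L)
  scale <- sqrt(I_measured / pmax(block_mean, eps))
  scale_full <- scale[rep(seq_len(nrow(scale)), each = L),
                      rep(seq_len(ncol(scale)), each = L)]
  complex_field(U$values * scale_full, U$grid)
}

#' Reconstruct one colour band by wavelength scanning
#'
#' Runs the full per-band pipeline: initial guess, then `n_iterations`
#' Gerchberg-Saxton passes over the band's wavelengths in ascending order
#' (forward propagation, amplitude constraint, back propagation,
#' inter-wavelength phase rescale, with a wrap-around rescale to the band's
#' first wavelength at the end of each pass).  The per-iteration residual is
#' the RMS misfit between the block-binned sensor intensity of the estimate
#' and the measured holograms, averaged over the band's wavelengths.
#'
#' @inheritParams initial_guess
#' @param band optional band label stored in the result.
#' @return an `object_estimate`: `$field` at super-resolved pitch, `$band`,
#'   and `$residual_history` of length `n_iterations`.
#' @export
reconstruct_channel <- function(stack_band, plan_band, settings, sensor_grid,
                                band = NA_character_) {
  if (length(stack_band) != length(plan_band))
    stop("reconstruct_channel: stack and wavelength plan are inconsistent",
         call. = FALSE)
  if (is.unsorted(plan_band, strictly = TRUE))
    stop("reconstruct_channel: wavelengths must be strictly ascending",
         call. = FALSE)
  est <- initial_guess(stack_band, plan_band, settings, sensor_grid)
  O <- est$field
  L <- settings$upsample_factor_L
  nk <- length(plan_band)
  # kernels are wavelength- and direction-dependent but iteration-invariant
  fwd <- lapply(plan_band, function(wl)
    angular_spectrum_kernel(O$grid, wl, +settings$z2_um))
  bwd <- lapply(plan_band, function(wl)
    angular_spectrum_kernel(O$grid, wl, -settings$z2_um))
  residuals <- numeric(settings$n_iterations)
  for (it in seq_len(settings$n_iterations)) {
    res_sum <- 0
    for (k in seq_len(nk)) {
      U <- propagate_with_kernel(O, fwd[[k]])
      if (anyNA(U$values))
        stop(sprintf("reconstruct_channel: NaN at wavelength %g nm, iteration %d",
                     plan_band[k], it), call. = FALSE)
      res_sum <- res_sum +
        sqrt(mean((bin_to_sensor(Mod(U$values)^2, L) - stack_band[[k]])^2))
      U <- apply_amplitude_constraint(U, stack_band[[k]], L,
                                      settings$constraint_mode,
                                      settings$upsample_method)
      O <- propagate_with_kernel(U, bwd[[k]])
      if (settings$phase_rescale_on) {
        wl_next <- if (k < nk) plan_band[k + 1L] else plan_band[1L]
        O <- phase_rescale(O, plan_band[k], wl_next)
      }
    }
    residuals[it] <- res_sum / nk
  }
  object_estimate(O, band, residuals)
}

#' Single-hologram back-propagation baseline
#'
#' The "low-resolution reconstructed image" reference: one hologram is
#' up-sampled, its square root taken as a zero-phase amplitude, and
#' back-propagated once to the object plane.  No iteration, no phase
#' retrieval; the twin image remains.
#'
#' @param hologram sensor-pitch intensity matrix.
#' @param wavelength_nm reconstruction wavelength (nm).
#' @param settings a [recon_settings()].
#' @param sensor_grid [grid_spec()] of the hologram.
#' @return an `object_estimate` with empty residual history.
#' @export
backpropagate_single <- function(hologram, wavelength_nm, settings, sensor_grid) {
  L <- settings$upsample_factor_L
  sg <- grid_spec(sensor_grid$height_px * L, sensor_grid$width_px * L,
                  sensor_grid$pitch_um / L)
  amp <- sqrt(pmax(upsample_hologram(hologram, L, settings$upsample_method), 0))
  o <- propagate(complex_field(amp, sg), wavelength_nm, -settings$z2_um)
  object_estimate(o, NA_character_, numeric(0))
}

#' Reconstruct all bands of a hologram stack
#'
#' @param stack a `hologram_stack` from [simulate_stack()] or
#'   [read_hologram_stack()].
#' @param settings a [recon_settings()]; defaults to the stack's acquisition
#'   geometry when omitted.
#' @return named list of `object_estimate`s, one per band.
#' @export
reconstruct_stack <- function(stack, settings = NULL) {
  if (is.null(settings))
    settings <- recon_settings(z2_um = stack$acq$z2_um,
                               upsample_factor_L = stack$acq$upsample_factor_L)
  out <- lapply(names(stack$bands), function(band)
    reconstruct_channel(stack$bands[[band]], stack$plan$bands[[band]],
                        settings, stack$sensor_grid, band = band))
  names(out) <- names(stack$bands)
  out
}
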