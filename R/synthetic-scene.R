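# Fixture generation: resolution targets, stained-tissue-like phantoms and
# the forward acquisition model (propagation, pixel-aperture integration,
# optional shot noise).

#' Three-bar resolution target specification
#'
#' Geometry of a USAF1951-style three-bar element: equally spaced parallel
#' bars of a given line width.  With the default duty cycle of 0.5 the bar
#' period is twice the line width and the pattern spans
#' `(2 n_bars - 1) * line_width` along the modulation axis.  Bar length
#' defaults to the USAF convention of five line widths.
#'
#' @param line_width_um positive bar width in um (may be below the grid pitch;
#'   sub-pitch targets are the point of super-resolution testing).
#' @param orientation `"horizontal"` (bars run along rows, modulation down
#'   the columns of the image) or `"vertical"`.
#' @param n_bars number of bars (default 3).
#' @param duty_cycle fraction of one period occupied by the bar, in (0, 1).
#' @param bar_length_um length of each bar; default `5 * line_width_um`.
#' @return an object of class `bar_target_spec`.
#' @export
bar_target_spec <- function(line_width_um, orientation = c("vertical", "horizontal"),
                            n_bars = 3L, duty_cycle = 0.5,
                            bar_length_um = 5 * line_width_um) {
  orientation <- match.arg(orientation)
  if (!is.finite(line_width_um) || line_width_um <= 0)
    stop("bar_target_spec: line_width_um must be positive", call. = FALSE)
  if (!is.finite(duty_cycle) || duty_cycle <= 0 || duty_cycle >= 1)
    stop("bar_target_spec: duty_cycle must lie in (0, 1)", call. = FALSE)
  n_bars <- as.integer(n_bars)
  if (is.na(n_bars) || n_bars < 1L)
    stop("bar_target_spec: n_bars must be a positive integer", call. = FALSE)
  structure(list(line_width_um = line_width_um, orientation = orientation,
                 n_bars = n_bars, duty_cycle = duty_cycle,
                 bar_length_um = bar_length_um),
            class = "bar_target_spec")
}

# Extent of the bar pattern along (modulation, bar-length) axes, in um.
bar_target_extent <- function(spec) {
  period <- spec$line_width_um / spec$duty_cycle
  mod_extent <- (spec$n_bars - 1) * period + spec$line_width_um
  c(modulation = mod_extent, along = spec$bar_length_um)
}

#' Render a three-bar amplitude target
#'
#' Amplitude-only transmission object: opaque bars (amplitude 0) on a clear
#' background (amplitude 1), phase identically zero.  The pattern centre is
#' aligned to the centre of the grid's sample lattice; bars are rasterised by
#' pixel-centre inclusion so sub-pitch widths produce partial sampling, which
#' is exactly what resolution testing probes.
#'
#' @param spec a [bar_target_spec()].
#' @param grid a [grid_spec()]; the pattern must fit inside the grid.
#' @param center_row,center_col pattern centre in (possibly fractional)
#'   1-based pixel indices; by default the lattice point nearest the grid
#'   centre, so the central bar centre is grid-aligned.
#' @return a [complex_field()] (real-valued amplitudes 0/1, zero phase).
#' @export
make_bar_target <- function(spec, grid,
                            center_row = round((grid$height_px - 1) / 2) + 1,
                            center_col = round((grid$width_px - 1) / 2) + 1) {
  ext <- bar_target_extent(spec)
  if (ext["modulation"] > grid$height_px * grid$pitch_um ||
      ext["modulation"] > grid$width_px * grid$pitch_um ||
      ext["along"] > grid$height_px * grid$pitch_um ||
      ext["along"] > grid$width_px * grid$pitch_um)
    stop("make_bar_target: target larger than grid", call. = FALSE)
  mask <- bar_target_mask(spec, grid, center_row, center_col)
  complex_field(matrix(as.numeric(!mask), grid$height_px, grid$width_px), grid)
}

# Logical mask of bar pixels (TRUE = opaque bar) with the pattern centred at
# the given (possibly fractional) pixel indices.
bar_target_mask <- function(spec, grid,
                            center_row = round((grid$height_px - 1) / 2) + 1,
                            center_col = round((grid$width_px - 1) / 2) + 1) {
  co <- grid_coords(grid)
  cy <- (center_row - 1) * grid$pitch_um
  cx <- (center_col - 1) * grid$pitch_um
  period <- spec$line_width_um / spec$duty_cycle
  centres <- (seq_len(spec$n_bars) - (spec$n_bars + 1) / 2) * period
  in_bars <- function(u) {
    hit <- rep(FALSE, length(u))
    for (c0 in centres) hit <- hit | abs(u - c0) < spec$line_width_um / 2
    hit
  }
  if (spec$orientation == "vertical") {
    # bars run along rows (y), modulation across columns (x)
    mod_hit <- in_bars(co$x - cx)
    len_hit <- abs(co$y - cy) < spec$bar_length_um / 2
    outer(len_hit, mod_hit, `&`)
  } else {
    mod_hit <- in_bars(co$y - cy)
    len_hit <- abs(co$x - cx) < spec$bar_length_um / 2
    outer(mod_hit, len_hit, `&`)
  }
}

#' Stained-tissue phantom specification
#'
#' A thin absorbing object with band-dependent transmission, emulating the
#' wavelength-selective absorption of histological stains (e.g. a reddish
#' smear that is nearly transparent in red light and strongly absorbing in
#' green).  `amplitude_map` is the full-contrast transmission amplitude of
#' the object; for a band with transmittance `t` the rendered amplitude is
#' the blend `t * 1 + (1 - t) * amplitude_map`, so `t = 1` gives a blank
#' field (invisible object) and `t = 0` the full-contrast map.
#'
#' @param amplitude_map numeric matrix in `[0, 1]`.
#' @param phase_map optional numeric matrix (radians), default all-zero.
#' @param per_band_transmittance named numeric vector/list with entries
#'   `R`, `G`, `B` in `[0, 1]`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(amplitude_map, phase_map = NULL,
                         per_band_transmittance = c(R = 0.5, G = 0.5, B = 0.5)) {
  if (!is.matrix(amplitude_map) || any(amplitude_map < 0) || any(amplitude_map > 1))
    stop("phantom_spec: amplitude_map must be a matrix with entries in [0, 1]",
         call. = FALSE)
  if (is.null(phase_map))
    phase_map <- matrix(0, nrow(amplitude_map), ncol(amplitude_map))
  if (!identical(dim(phase_map), dim(amplitude_map)))
    stop("phantom_spec: phase_map shape must match amplitude_map", call. = FALSE)
  tr <- unlist(per_band_transmittance)
  if (!all(c("R", "G", "B") %in% names(tr)) || any(tr < 0) || any(tr > 1))
    stop("phantom_spec: per_band_transmittance needs R, G, B entries in [0, 1]",
         call. = FALSE)
  structure(list(amplitude_map = amplitude_map, phase_map = phase_map,
                 per_band_transmittance = tr[c("R", "G", "B")]),
            class = "phantom_spec")
}

#' Render a phantom for one colour band
#'
#' @param spec a [phantom_spec()].
#' @param band one of `"R"`, `"G"`, `"B"`.
#' @param grid a [grid_spec()] matching the map dimensions.
#' @return a [complex_field()] whose amplitude is the transmittance-blended
#'   map and whose phase comes from `phase_map`.
#' @export
make_stain_phantom <- function(spec, band = c("R", "G", "B"), grid) {
  band <- match.arg(band)
  if (!inherits(spec, "phantom_spec"))
    stop("make_stain_phantom: spec must be a phantom_spec", call. = FALSE)
  t_band <- spec$per_band_transmittance[[band]]
  amp <- t_band + (1 - t_band) * spec$amplitude_map
  complex_field(amp * exp(1i * spec$phase_map), grid)
}

#' Disk phantom amplitude map
#'
#' Convenience map for a circular absorbing object (used as the
#' band-selective stain fixture in tests and examples).
#'
#' @param grid a [grid_spec()].
#' @param radius_um disk radius in um.
#' @param inner_amplitude amplitude inside the disk (default 0.2).
#' @return numeric matrix in `[0, 1]`.
#' @export
disk_amplitude_map <- function(grid, radius_um, inner_amplitude = 0.2) {
  co <- grid_coords(grid)
  cy <- (grid$height_px - 1) * grid$pitch_um / 2
  cx <- (grid$width_px - 1) * grid$pitch_um / 2
  r2 <- outer((co$y - cy)^2, (co$x - cx)^2, `+`)
  m <- matrix(1, grid$height_px, grid$width_px)
  m[r2 <= radius_um^2] <- inner_amplitude
  m
}

#' Acquisition specification
#'
#' Physical parameters of the simulated lensfree acquisition: sensor grid
#' (1.85 um pitch by default), up-sampling factor `L` (the simulation runs at
#' super-resolved pitch `pitch / L`), sample-to-sensor distance `z2` (below
#' 2 mm), and the noise model.
#'
#' @param sensor_grid a [grid_spec()] at sensor pitch.
#' @param upsample_factor_L positive integer (default 4).
#' @param z2_um sample-sensor distance in um, in (0, 2000); default 1000.
#' @param noise_model `"none"` (default) or `"shot"`.
#' @param photon_budget mean photons per pixel at unit intensity for shot
#'   noise (default 10000).
#' @param rng_seed integer seed used (with a deterministic per-wavelength
#'   offset) when noise is enabled.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sensor_grid = grid_spec(64, 64, 1.85),
                             upsample_factor_L = 4L,
                             z2_um = 1000,
                             noise_model = c("none", "shot"),
                             photon_budget = 1e4,
                             rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  upsample_factor_L <- as.integer(upsample_factor_L)
  if (is.na(upsample_factor_L) || upsample_factor_L < 1L)
    stop("acquisition_spec: upsample_factor_L must be >= 1", call. = FALSE)
  if (!is.finite(z2_um) || z2_um <= 0 || z2_um >= 2000)
    stop("acquisition_spec: z2_um must lie in (0, 2000) um", call. = FALSE)
  if (noise_model == "shot" && (!is.finite(photon_budget) || photon_budget <= 0))
    stop("acquisition_spec: photon_budget must be positive", call. = FALSE)
  structure(list(sensor_grid = sensor_grid,
                 upsample_factor_L = upsample_factor_L,
                 z2_um = z2_um, noise_model = noise_model,
                 photon_budget = photon_budget,
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_spec")
}

#' Super-resolved simulation grid of an acquisition
#'
#' The grid on which objects are sampled: sensor dimensions times `L`, pitch
#' divided by `L`, so pixel-aperture binning is exact.
#'
#' @param acq an [acquisition_spec()].
#' @return a [grid_spec()].
#' @export
super_grid <- function(acq) {
  g <- acq$sensor_grid
  L <- acq$upsample_factor_L
  grid_spec(g$height_px * L, g$width_px * L, g$pitch_um / L)
}

#' Simulate a multi-wavelength hologram stack
#'
#' Forward model of the acquisition: for every wavelength of every band the
#' object field is propagated to the sensor plane by the angular-spectrum
#' method, the intensity is integrated over the pixel aperture
#' ([bin_to_sensor()]), and (optionally) Poisson shot noise at the configured
#' photon budget is applied with a deterministic per-wavelength seed offset.
#' A blank object under this convention yields unit intensity everywhere
#' (background-normalised holograms).
#'
#' @param object_per_band named list (`R`, `G`, `B`) of [complex_field()]s at
#'   super-resolved pitch; a single field is recycled across bands.
#' @param plan a [build_wavelength_plan()] result.
#' @param acq an [acquisition_spec()].
#' @return an object of class `hologram_stack`: `$bands[[band]]` is a named
#'   list of sensor-pitch intensity matrices keyed by wavelength (ascending),
#'   with `$sensor_grid`, `$plan` and `$acq` attached.
#' @export
simulate_stack <- function(object_per_band, plan, acq) {
  if (!is_wavelength_plan(plan)) stop("simulate_stack: plan must be a wavelength_plan", call. = FALSE)
  if (!inherits(acq, "acquisition_spec")) stop("simulate_stack: acq must be an acquisition_spec", call. = FALSE)
  sg <- super_grid(acq)
  if (is_complex_field(object_per_band))
    object_per_band <- stats::setNames(
      rep(list(object_per_band), length(plan$bands)), names(plan$bands))
  if (!all(names(plan$bands) %in% names(object_per_band)))
    stop("simulate_stack: object_per_band must cover every band in the plan",
         call. = FALSE)
  L <- acq$upsample_factor_L
  wl_index <- 0L
  bands <- lapply(names(plan$bands), function(band) {
    obj <- object_per_band[[band]]
    if (!is_complex_field(obj) || !grids_equal(obj$grid, sg))
      stop(sprintf("simulate_stack: band %s object must be sampled on the super grid (%d x %d, pitch %.4g um)",
                   band, sg$height_px, sg$width_px, sg$pitch_um), call. = FALSE)
    holos <- lapply(plan$bands[[band]], function(wl) {
      wl_index <<- wl_index + 1L
      u_sensor <- propagate(obj, wl, +acq$z2_um)
      intensity <- bin_to_sensor(field_intensity(u_sensor), L)
      if (acq$noise_model == "shot") {
        old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
        set.seed(acq$rng_seed + 1009L * wl_index)
        counts <- stats::rpois(length(intensity), acq$photon_budget * intensity)
        intensity <- matrix(counts / acq$photon_budget,
                            nrow(intensity), ncol(intensity))
        if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      }
      intensity
    })
    names(holos) <- format_nm(plan$bands[[band]])
    holos
  })
  names(bands) <- names(plan$bands)
  structure(list(bands = bands, sensor_grid = acq$sensor_grid,
                 plan = plan, acq = acq),
            class = "hologram_stack")
}

format_nm <- function(wl) sprintf("%gnm", wl)

#' @export
print.hologram_stack <- function(x, ...) {
  cat(sprintf("<hologram_stack> %d holograms, sensor %d x %d px @ %.4g um\n",
              sum(lengths(x$bands)), x$sensor_grid$height_px,
              x$sensor_grid$width_px, x$sensor_grid$pitch_um))
  invisible(x)
}
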