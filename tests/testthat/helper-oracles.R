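# Independent oracles and shared fixtures. The propagation oracle below is
# a literal frequency-by-frequency summation of the angular-spectrum
# integral: DFT coefficients computed from outer products of complex
# exponentials, each multiplied by the closed-form transfer factor and
# accumulated back into the spatial domain. No fft() anywhere, so it is an
# independent check of the production path.

oracle_fft_freqs <- function(n, pitch_um) {
  k <- integer(n)
  for (i in seq_len(n)) {
    idx <- i - 1L
    k[i] <- if (idx < ceiling(n / 2)) idx else idx - n
  }
  k / (n * pitch_um)
}

oracle_propagate <- function(values, pitch_um, wavelength_nm, z_um,
                             medium_index = 1) {
  h <- nrow(values); w <- ncol(values)
  fy <- oracle_fft_freqs(h, pitch_um)
  fx <- oracle_fft_freqs(w, pitch_um)
  y <- (seq_len(h) - 1) * pitch_um
  x <- (seq_len(w) - 1) * pitch_um
  lambda_um <- wavelength_nm * 1e-3
  fmax2 <- (medium_index / lambda_um)^2
  out <- matrix(0 + 0i, h, w)
  for (a in seq_len(h)) {
    for (b in seq_len(w)) {
      f2 <- fy[a]^2 + fx[b]^2
      if (f2 > fmax2) next
      ey <- exp(-2i * pi * fy[a] * y)
      ex <- exp(-2i * pi * fx[b] * x)
      coef <- sum(outer(ey, ex) * values) / (h * w)
      transfer <- exp(2i * pi * z_um * sqrt(fmax2 - f2))
      out <- out + coef * transfer * outer(Conj(ey), Conj(ex))
    }
  }
  out
}

# count of evanescent lattice frequencies by explicit enumeration
oracle_evanescent_count <- function(h, w, pitch_um, wavelength_nm,
                                    medium_index = 1) {
  fy <- oracle_fft_freqs(h, pitch_um)
  fx <- oracle_fft_freqs(w, pitch_um)
  lambda_um <- wavelength_nm * 1e-3
  cnt <- 0L
  for (a in seq_len(h))
    for (b in seq_len(w))
      if (fy[a]^2 + fx[b]^2 > (medium_index / lambda_um)^2) cnt <- cnt + 1L
  cnt
}

# small random complex field on a given grid
random_field <- function(grid, seed = 1) {
  set.seed(seed)
  n <- grid$height_px * grid$width_px
  complex_field(matrix(complex(real = stats::rnorm(n),
                               imaginary = stats::rnorm(n)),
                       grid$height_px, grid$width_px), grid)
}

# single-band plan wrapper used throughout the tests
one_band_plan <- function(band, wavelengths) {
  structure(list(bands = stats::setNames(list(wavelengths), band)),
            class = "wavelength_plan")
}

# small G-band bar-target acquisition used by several reconstruction tests
sim_bar_stack <- function(width_um = 1.85, orientation = "vertical",
                          sensor_px = 48L, n_wl = 7L,
                          z2_um = 1000, L = 4L) {
  acq <- acquisition_spec(grid_spec(sensor_px, sensor_px, 1.85), L, z2_um)
  sg <- super_grid(acq)
  spec <- bar_target_spec(width_um, orientation)
  obj <- make_bar_target(spec, sg)
  wls <- build_wavelength_plan()$bands$G[seq_len(n_wl)]
  stack <- simulate_stack(stats::setNames(list(obj), "G"),
                          one_band_plan("G", wls), acq)
  list(acq = acq, sg = sg, spec = spec, obj = obj, wls = wls, stack = stack)
}
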