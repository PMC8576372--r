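test_that("bar target geometry: extent, transposition symmetry, pixel counts", {
  g <- grid_spec(128, 128, 0.4625)
  w <- 2.0   # bar edges fall strictly between lattice points: no FP boundary
  spec_v <- bar_target_spec(w, "vertical")
  spec_h <- bar_target_spec(w, "horizontal")
  # total extent along the modulation axis is (2*3 - 1) * w = 5w
  expect_equal(unname(bar_target_extent(spec_v)["modulation"]), 5 * w)
  tv <- make_bar_target(spec_v, g)
  th <- make_bar_target(spec_h, g)
  # orientations are exact transposes (square grid, centred pattern)
  expect_identical(Re(th$values), t(Re(tv$values)))
  # amplitude is binary 0/1 with zero phase
  expect_true(all(Re(tv$values) %in% c(0, 1)))
  expect_true(all(Im(tv$values) == 0))
  # bar pixel count: each bar is w wide and 5w long at pitch 0.4625 -> the
  # opaque fraction of the 5w x 5w bounding box, counted on the lattice,
  # must match the rendered mask exactly
  mask <- Re(tv$values) == 0
  n_bar_px <- sum(mask)
  # independent count: enumerate lattice columns/rows hit by bars
  xs <- (seq_len(g$width_px) - 1) * g$pitch_um
  ys <- (seq_len(g$height_px) - 1) * g$pitch_um
  cx <- round((g$width_px - 1) / 2) * g$pitch_um
  cy <- round((g$height_px - 1) / 2) * g$pitch_um
  cols_hit <- 0L
  for (c0 in c(-2 * w, 0, 2 * w))
    cols_hit <- cols_hit + sum(abs(xs - (cx + c0)) < w / 2)
  rows_hit <- sum(abs(ys - cy) < 5 * w / 2)
  expect_identical(n_bar_px, as.integer(cols_hit * rows_hit))
})

test_that("bar target that does not fit the grid errors", {
  g <- grid_spec(16, 16, 0.5)   # 8 um field
  expect_error(make_bar_target(bar_target_spec(2), g), "larger than grid")
})

test_that("stain phantom blends amplitude with per-band transmittance", {
  g <- grid_spec(32, 32, 0.4625)
  amp <- disk_amplitude_map(g, radius_um = 5, inner_amplitude = 0.2)
  ph <- phantom_spec(amp, per_band_transmittance = c(R = 0.9, G = 0.2, B = 0.7))
  # transmittance 1 -> blank field; 0 -> the map itself
  ph_extremes <- phantom_spec(amp, per_band_transmittance = c(R = 1, G = 0, B = 0.5))
  expect_lt(max(Mod(make_stain_phantom(ph_extremes, "R", g)$values - 1)), 1e-12)
  expect_equal(Mod(make_stain_phantom(ph_extremes, "G", g)$values), amp,
               tolerance = 1e-12)
  # band means strictly ordered by transmittance: G < B < R
  means <- vapply(c("R", "G", "B"),
                  function(b) mean(Mod(make_stain_phantom(ph, b, g)$values)),
                  numeric(1))
  expect_lt(means[["G"]], means[["B"]])
  expect_lt(means[["B"]], means[["R"]])
  # phase map carried through
  ph2 <- phantom_spec(amp, phase_map = matrix(0.3, 32, 32),
                      per_band_transmittance = c(R = 0.5, G = 0.5, B = 0.5))
  expect_equal(Arg(make_stain_phantom(ph2, "R", g)$values),
               matrix(0.3, 32, 32), tolerance = 1e-12)
})

test_that("bin_to_sensor is an exact block mean", {
  expect_identical(bin_to_sensor(matrix(1, 8, 8), 4), matrix(1, 2, 2))
  x <- matrix(stats::runif(36), 6, 6)
  expect_identical(bin_to_sensor(x, 1), x)
  m4 <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_equal(bin_to_sensor(m4, 4), matrix(8.5, 1, 1))
  # mean conservation and block arithmetic on a random case
  y <- matrix(stats::rnorm(12 * 18)^2, 12, 18)
  b <- bin_to_sensor(y, 3)
  expect_equal(mean(b), mean(y), tolerance = 1e-14)
  expect_equal(b[2, 3], mean(y[4:6, 7:9]), tolerance = 1e-14)
  expect_error(bin_to_sensor(matrix(1, 5, 6), 2), "divisible")
})

test_that("simulate_stack produces 21 holograms under the default plan", {
  acq <- acquisition_spec(grid_spec(16, 16, 1.85), 2L, 800)
  sg <- super_grid(acq)
  obj <- complex_field(matrix(1 + 0i, sg$height_px, sg$width_px), sg)
  stack <- simulate_stack(obj, build_wavelength_plan(), acq)
  expect_identical(sum(lengths(stack$bands)), 21L)
  expect_identical(lengths(stack$bands), c(R = 7L, G = 7L, B = 7L))
  # blank object, noise off -> every hologram is exactly uniform 1
  for (band in names(stack$bands))
    for (h in stack$bands[[band]])
      expect_lt(max(abs(h - 1)), 1e-9)
})

test_that("shot noise is seed-deterministic and leaves the global RNG state alone", {
  acq1 <- acquisition_spec(grid_spec(8, 8, 1.85), 2L, 500,
                           noise_model = "shot", photon_budget = 1000,
                           rng_seed = 11L)
  acq2 <- acquisition_spec(grid_spec(8, 8, 1.85), 2L, 500,
                           noise_model = "shot", photon_budget = 1000,
                           rng_seed = 12L)
  sg <- super_grid(acq1)
  obj <- make_bar_target(bar_target_spec(1.85), sg)
  plan <- one_band_plan("G", c(512, 530, 548))
  set.seed(99)
  s1 <- simulate_stack(stats::setNames(list(obj), "G"), plan, acq1)
  draw_after <- stats::runif(1)
  set.seed(99)
  s1b <- simulate_stack(stats::setNames(list(obj), "G"), plan, acq1)
  expect_identical(s1$bands, s1b$bands)          # bit-identical across runs
  expect_identical(draw_after, {set.seed(99); stats::runif(1)})  # RNG restored
  s2 <- simulate_stack(stats::setNames(list(obj), "G"), plan, acq2)
  expect_false(identical(s1$bands, s2$bands))    # different seed differs
  # wavelengths get distinct noise draws
  expect_false(identical(s1$bands$G[[1]], s1$bands$G[[2]]))
})

test_that("hologram contrast falls as line width shrinks below the sensor limit", {
  # forward-model only: modulation depth of the binned hologram of a bar
  # target decreases monotonically through the near/sub-Nyquist ladder
  depth <- vapply(c(7.4, 3.7, 1.85, 0.925), function(w) {
    s <- sim_bar_stack(width_um = w, sensor_px = 48L, n_wl = 1L)
    h <- s$stack$bands$G[[1]]
    stats::sd(h)
  }, numeric(1))
  expect_true(all(diff(depth) < 0))
})

test_that("identical per-band transmittance gives identical stacks up to diffraction", {
  acq <- acquisition_spec(grid_spec(16, 16, 1.85), 2L, 600)
  sg <- super_grid(acq)
  amp <- disk_amplitude_map(sg, radius_um = 6, inner_amplitude = 0.3)
  ph <- phantom_spec(amp, per_band_transmittance = c(R = 1, G = 1, B = 1))
  objs <- lapply(c(R = "R", G = "G", B = "B"),
                 function(b) make_stain_phantom(ph, b, sg))
  plan <- build_wavelength_plan()
  stack <- simulate_stack(objs, plan, acq)
  # transmittance 1 in every band: object invisible, all holograms blank,
  # hence identical across bands for every wavelength
  for (band in names(stack$bands))
    for (h in stack$bands[[band]])
      expect_lt(max(abs(h - 1)), 1e-9)
})
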