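test_that("wavelength plans follow the printed band ranges", {
  plan <- build_wavelength_plan()
  expect_identical(plan$bands$R, seq(606, 642, by = 6))
  expect_length(plan$bands$R, 7L)
  expect_length(plan$bands$G, 7L)
  expect_length(plan$bands$B, 7L)
  expect_identical(n_wavelengths(plan), 21L)
  # degenerate range: a single wavelength
  single <- build_wavelength_plan(list(G = c(530, 530)), 6)
  expect_identical(single$bands$G, 530)
  # step larger than range warns but yields one wavelength
  expect_warning(p <- build_wavelength_plan(list(G = c(512, 514)), 6), "single")
  expect_identical(p$bands$G, 512)
  expect_error(build_wavelength_plan(list(G = c(548, 512)), 6), "max >= min")
})

test_that("upsample_hologram preserves constants, means and the nearest round trip", {
  u <- matrix(3.5, 6, 6)
  for (m in c("nearest", "bilinear", "bicubic")) {
    up <- upsample_hologram(u, 4, m)
    expect_identical(dim(up), c(24L, 24L))
    expect_lt(max(abs(up - 3.5)), 1e-12)
    expect_identical(upsample_hologram(u, 1, m), u)
  }
  set.seed(5)
  x <- matrix(stats::runif(64, 0.5, 1.5), 8, 8)
  # nearest upsample then block binning is the exact identity
  expect_equal(bin_to_sensor(upsample_hologram(x, 3, "nearest"), 3), x,
               tolerance = 1e-14)
  # smooth input: interpolation is locally mass-preserving to ~1%
  sm <- outer(sin(seq(0, pi, length.out = 16)),
              cos(seq(0, pi / 2, length.out = 16))) + 1
  for (m in c("bilinear", "bicubic"))
    expect_lt(abs(mean(upsample_hologram(sm, 4, m)) - mean(sm)) / mean(sm), 0.01)
  # clamped at zero
  spik <- matrix(0, 8, 8); spik[4, 4] <- 1
  expect_gte(min(upsample_hologram(spik, 4, "bicubic")), 0)
})

test_that("initial guess: blank stack and degenerate single-wavelength pipeline", {
  g <- grid_spec(16, 16, 1.85)
  settings <- recon_settings(z2_um = 700, upsample_factor_L = 2L,
                             initial_filter_px = 3L)
  blank <- list(matrix(1, 16, 16), matrix(1, 16, 16))
  est <- initial_guess(blank, c(512, 518), settings, g)
  expect_lt(max(abs(Mod(est$field$values) - 1)), 1e-9)
  expect_lt(max(abs(Arg(est$field$values))), 1e-9)
  # z2 -> 0, one wavelength, 1x1 filter: the guess is sqrt of the upsampled hologram
  set.seed(8)
  holo <- matrix(stats::runif(256, 0.5, 2), 16, 16)
  s0 <- recon_settings(z2_um = 1e-9, upsample_factor_L = 2L,
                       initial_filter_px = 1L, upsample_method = "nearest")
  est0 <- initial_guess(list(holo), 530, s0, g)
  expect_equal(Mod(est0$field$values),
               sqrt(upsample_hologram(holo, 2, "nearest")), tolerance = 1e-9)
  expect_error(initial_guess(list(), numeric(0), settings, g), "empty")
})

test_that("initial guess of a simulated bar stack correlates with the truth", {
  s <- sim_bar_stack(width_um = 2.775, sensor_px = 48L)  # 6 super px wide bars
  settings <- recon_settings(z2_um = 1000, upsample_factor_L = 4L)
  est <- initial_guess(s$stack$bands$G, s$wls, settings, s$acq$sensor_grid)
  r <- recovery_error(est, s$obj)$pearson_r
  expect_gt(r, 0.5)
})

test_that("amplitude constraint preserves phase and enforces the measurement", {
  g <- grid_spec(12, 12, 0.925)
  U <- random_field(g, seed = 4)
  I_meas <- matrix(stats::runif(36, 0.5, 2), 6, 6)
  # block_scale: block-mean intensity equals the measurement afterwards
  Uc <- apply_amplitude_constraint(U, I_meas, 2L, "block_scale")
  expect_equal(bin_to_sensor(Mod(Uc$values)^2, 2L), I_meas, tolerance = 1e-9)
  expect_equal(Arg(Uc$values), Arg(U$values), tolerance = 1e-12)
  # already-consistent field is returned unchanged
  I_self <- bin_to_sensor(Mod(U$values)^2, 2L)
  U_same <- apply_amplitude_constraint(U, I_self, 2L, "block_scale")
  expect_lt(max(Mod(U_same$values - U$values)), 1e-12)
  # replace mode with uniform measurement 4.0: all magnitudes 2, phase kept
  Ur <- apply_amplitude_constraint(U, matrix(4, 6, 6), 2L, "replace",
                                   upsample_method = "nearest")
  expect_lt(max(abs(Mod(Ur$values) - 2)), 1e-12)
  expect_equal(Arg(Ur$values), Arg(U$values), tolerance = 1e-12)
  expect_error(apply_amplitude_constraint(U, matrix(1, 5, 5), 2L), "dimensions")
})

test_that("reconstruct_channel recovers a bar target and reduces the residual", {
  s <- sim_bar_stack(width_um = 1.85, sensor_px = 48L)  # 4x super pitch
  settings <- recon_settings(z2_um = 1000, upsample_factor_L = 4L,
                             n_iterations = 15L)
  est <- reconstruct_channel(s$stack$bands$G, s$wls, settings,
                             s$acq$sensor_grid, band = "G")
  expect_length(est$residual_history, 15L)
  expect_lt(est$residual_history[15], est$residual_history[1])
  fit <- recovery_error(est, s$obj)
  expect_gte(fit$pearson_r, 0.9)
  # twin-image suppression: RMS error strictly below the single-hologram baseline
  base <- backpropagate_single(s$stack$bands$G[[4]], s$wls[4], settings,
                               s$acq$sensor_grid)
  fit_base <- recovery_error(base, s$obj)
  expect_lt(fit$nrmse, fit_base$nrmse)
})

test_that("a blank stack is a fixed point of the iteration", {
  g <- grid_spec(16, 16, 1.85)
  blank <- lapply(1:3, function(i) matrix(1, 16, 16))
  settings <- recon_settings(z2_um = 900, upsample_factor_L = 2L,
                             n_iterations = 4L)
  est <- reconstruct_channel(blank, c(512, 518, 524), settings, g)
  expect_lt(max(abs(Mod(est$field$values) - 1)), 1e-7)
  expect_lt(max(abs(Arg(est$field$values))), 1e-7)
  expect_lt(max(est$residual_history), 1e-8)
})

test_that("reconstruction is deterministic and residuals are stable on consistent stacks", {
  s <- sim_bar_stack(width_um = 3.7, sensor_px = 32L, n_wl = 3L)
  settings <- recon_settings(z2_um = 1000, upsample_factor_L = 4L,
                             n_iterations = 6L)
  e1 <- reconstruct_channel(s$stack$bands$G, s$wls, settings, s$acq$sensor_grid)
  e2 <- reconstruct_channel(s$stack$bands$G, s$wls, settings, s$acq$sensor_grid)
  expect_identical(e1$field$values, e2$field$values)
  expect_identical(e1$residual_history, e2$residual_history)
  # residuals non-increasing (to small relative tolerance) on a noise-free stack
  rh <- e1$residual_history
  expect_true(all(diff(rh) <= 1e-6 * rh[1]))
})

test_that("inconsistent stack and plan are rejected", {
  g <- grid_spec(8, 8, 1.85)
  settings <- recon_settings(z2_um = 500, upsample_factor_L = 2L)
  expect_error(reconstruct_channel(list(matrix(1, 8, 8)), c(512, 518),
                                   settings, g), "inconsistent")
  expect_error(reconstruct_channel(list(matrix(1, 8, 8), matrix(1, 8, 8)),
                                   c(518, 512), settings, g), "ascending")
})
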