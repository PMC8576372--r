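# holoscan

Wavelength-scanning pixel super-resolution for lensfree in-line colour
holographic microscopy, in R.

## The problem

A lensfree (Gabor) in-line holographic microscope puts a stained pathology
slide directly between a quasi-point source and a bare CMOS sensor, with a
sub-2 mm sample-to-sensor gap `z2`. The geometry decouples resolution from
field of view — the whole photosensitive area images at unit magnification —
but two physical limits remain:

* the sensor records only intensity, so back-propagating a single hologram
  overlays the reconstruction with its defocused conjugate (the *twin
  image*);
* the sensor pixel pitch (1.85 µm here) under-samples the hologram, capping
  resolution near the pitch.

Both are attacked at once by **wavelength scanning**: each colour band
(R 606–642 nm, G 512–548 nm, B 452–488 nm) is scanned in seven 6 nm steps,
giving 21 holograms `{I_C,k}`. Changing the wavelength shifts object
information in frequency space, so the stack carries both the phase
diversity needed to suppress the twin image and the sampling diversity
needed for pixel super-resolution. Composing the three reconstructed bands
into RGB and smoothing only the chrominance planes in YUV space removes the
rainbow-like artifacts of coherent colour imaging while the luminance plane
keeps full resolution.

## The algorithm

For band `C` with wavelengths `λ_C,1 < … < λ_C,7`, the object estimate `O_C`
lives at the super-resolved pitch `Δ/L` (`Δ` = 1.85 µm, `L` = 4):

1. **Initial guess** — every hologram is up-sampled, its square root
   back-propagated to the object plane by the angular spectrum method, the
   magnitudes averaged over the band and mean-filtered.
2. **Gerchberg–Saxton sweep** (15 iterations by default): for each `λ_C,k`
   in turn, propagate `O_C` forward by `+z2`, enforce the measured hologram
   — each `L×L` block of `|U|²` is rescaled so its block mean equals the
   measured pixel, preserving phase and intra-block detail — and propagate
   back by `−z2`.
3. **Phase relationship** — before moving to `λ_C,k+1` the wrapped phase is
   rescaled by `λ_C,k / λ_C,k+1` (optical path length, not phase, is
   wavelength-invariant for a thin object); amplitude is untouched.
4. **Colour** — channel intensities `|O_C|²` are background-normalised into
   R, G, B; converted to YUV (BT.601: `Y = 0.299R + 0.587G + 0.114B`,
   `U = 0.492(B−Y)`, `V = 0.877(R−Y)`); `U`, `V` are box-filtered; `Y` is
   kept bit-identical; the result is converted back to RGB.

Free-space propagation is the exact scalar transfer function
`H(f) = exp(+j2πz√((n/λ)² − f²))` with a hard evanescent cutoff. A forward
simulator (plane-wave illumination, pixel-aperture integration as an exact
`L×L` block mean, optional Poisson shot noise) generates hologram stacks of
three-bar USAF-style targets and band-selective stain phantoms, so the
whole pipeline is testable without experimental data.

## Worked example

Simulate the G-band acquisition of a 1.38 µm three-bar target (USAF group 8,
element 4) and compare multi-wavelength super-resolution with a single
back-propagated hologram:

```r
library(holoscan)

plan <- build_wavelength_plan()            # R/G/B x 7 wavelengths, 6 nm step
acq  <- acquisition_spec(sensor_grid = grid_spec(48, 48, 1.85),
                         upsample_factor_L = 4L, z2_um = 1000)
sg   <- super_grid(acq)                    # 192 x 192 px at 0.4625 um

target <- bar_target_spec(1.38, "vertical")
object <- make_bar_target(target, sg)
stack  <- simulate_stack(object, plan, acq)   # 21 holograms

settings <- recon_settings(z2_um = 1000, upsample_factor_L = 4L,
                           n_iterations = 15L)
est  <- reconstruct_channel(stack$bands$G, plan$bands$G, settings,
                            acq$sensor_grid, band = "G")
base <- backpropagate_single(stack$bands$G[["530nm"]], 530, settings,
                             acq$sensor_grid)

pl <- bar_placement(target, sg)
michelson_contrast(Mod(est$field$values),  pl)   # 0.902
michelson_contrast(Mod(base$field$values), pl)   # 0.064
recovery_error(est, object)$pearson_r            # 0.913
```

The residual history printed by `est` drops from `2.57e-02` to `1.75e-03`
over the 15 sweeps. The 1.38 µm element is far above the 0.15 contrast
criterion after super-resolution (0.90) and unresolved by the baseline
(0.06): the twin image and pixel aperture bury it at sensor pitch.

`evaluate_resolution_ladder()` runs the same comparison over the full
group-8 width ladder {1.95, 1.74, 1.55, 1.38, 1.23, 1.10} µm in both
orientations, and `cmd_simulate()` / `cmd_reconstruct()` /
`cmd_colourize()` / `cmd_evaluate()` (or `inst/cli/holoscan.R`) drive the
same stages through a YAML config and a fixed on-disk run layout.

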