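---
title: "Methods: wavelength-scanning pixel super-resolution and colour reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelength-scanning pixel super-resolution and colour reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Imaging model

The package models a lensfree in-line holographic microscope: a thin object
with complex transmission `o(x, y)` sits a distance `z2` (default 1000 µm,
always below 2 mm) above a monochrome sensor of pitch Δ = 1.85 µm. The
source-to-sample distance is large compared to `z2`, so illumination is
treated as an ideal unit-amplitude plane wave and magnification is unity. A
tilted plane wave carries spatial frequencies
`f_x = n sinθ cosφ / λ`, `f_y = n sinθ sinφ / λ`; the hardware being
modelled is normal-incidence, so `tilt_carrier()` exists for completeness
but is unused in the default pipeline.

Propagation is the exact scalar angular-spectrum transfer function
`H(f) = exp(+j 2π z √((n/λ)² − |f|²))` on the standard FFT frequency
lattice (zero frequency first, cycles/µm, even and odd sizes supported).
Above the band limit `|f| > n/λ` the kernel is **exactly zero**: at
`z2 ~ 1` mm evanescent waves are attenuated by hundreds of orders of
magnitude, and the hard cutoff is numerically safer than an exponential
decay branch. Consequences tested for: unit kernel magnitude on the band
limit, energy conservation over propagating frequencies to 1e−9 relative,
and a forward/backward round trip that is the band-limit projection
(idempotent to 1e−8). The production FFT path is checked against a
brute-force frequency-summation oracle on small grids to 1e−10. The sign
convention is `exp(+j2π·)` with `+z` the object→sensor direction.

## Acquisition and the forward simulator

The simulated acquisition reproduces the wavelength-scanning protocol:
three bands (R 606–642 nm, G 512–548 nm, B 452–488 nm) of seven wavelengths
at 6 nm spacing — 21 holograms. Objects are sampled at the super-resolved
pitch Δ/L (L = 4 by default); each hologram is `|propagate(o, λ, +z2)|²`
integrated over the pixel aperture as an exact L×L block **mean**. Block
mean rather than sum keeps a blank field at intensity 1.0, i.e. the
holograms are background-normalised — the real instrument's exposure and
gain are not modelled, and no normalization step is documented for it, so
unit background is the package's stated convention.

Pixel aperture is full-fill-factor box integration. Real sensors have
microlenses and a fill factor below one, which attenuates near-Nyquist
contrast *less* than the box model; this conservative choice matters for
the baseline resolution claim (see Limitations). Shot noise is Poisson at a
configurable photon budget (default 10⁴ photons/pixel at unit intensity),
**off by default** so acceptance runs are deterministic; each wavelength
uses a deterministic offset from the acquisition seed and the global RNG
state is restored afterwards. Sensor read noise, dark current, the 2–7 nm
AOTF line width and source speckle are not modelled: a green test
establishes algorithmic correctness under ideal coherent imaging, not
instrument-level performance.

## Reconstruction

Per band, the estimate `O_C` is initialised from the data themselves: each
hologram is up-sampled (bicubic by default), its square root taken as a
zero-phase sensor-plane amplitude, back-propagated at its own wavelength,
and the **magnitudes** averaged, then mean-filtered (3×3 default; the
kernel size is a free parameter of the method, configurable). Averaging
magnitudes rather than complex fields is a deliberate reading of "summing
the object functions": retrieved phases scale with wavelength, so a complex
sum across a 36 nm band interferes destructively; the magnitude average is
the robust variant and converges to the same fixed points.

Each of the `n_iterations` (default 15, the middle of the sensible 5–20
range) Gerchberg–Saxton sweeps visits the band's wavelengths in ascending
order. The sensor-plane constraint has two modes:

* `block_scale` (default): each L×L block of magnitudes is multiplied by
  `√(I_measured / max(block-mean |U|², 1e−12))`. Every block-mean intensity
  then equals the measurement exactly while intra-block structure — the
  super-resolved detail accumulated across wavelengths — survives. This is
  what makes the scheme a *pixel super-resolution*, not just a phase
  retrieval.
* `replace`: per-pixel magnitude replaced by the square-root of the
  up-sampled measurement. Kept for ablation; it collapses sub-pixel detail
  to the interpolant.

Between wavelengths the wrapped phase (taken in (−π, π]) is multiplied by
`λ_k/λ_k+1` with amplitude unchanged — the thin-object assumption that
optical path length, not phase, is wavelength-invariant. Scaling *wrapped*
phase is the simplest faithful variant (an unwrapped or OPL-parameterised
variant would need a phase-unwrapping step with its own failure modes); it
is exact wherever `|φ|·λ_k/λ_k+1 < π` and the behaviour is switchable via
`phase_rescale_on`. After the last wavelength of a sweep the phase is
rescaled back to the band's first wavelength, so `O_C` is always referenced
to `λ_C,1`; whether the original procedure rescales across the iteration
boundary is unstated, and this wrap-around is the package's convention.
The per-iteration residual is the RMS misfit between block-binned estimate
intensity and the measured holograms, averaged over the band; on noise-free
self-consistent stacks it is non-increasing, and a blank stack is an exact
fixed point. Reconstruction is fully deterministic.

Measured intensities are clamped at zero before square roots; a NaN
appearing mid-iteration aborts with the offending wavelength and iteration
named.

## Colour

Channel images are **intensities** `|O_C|²` ("intensity images" read
literally; amplitude composition is available behind a flag). Each plane is
normalised so blank background maps to 1: by default division by the modal
intensity (peak bin of a 256-bin histogram, then the median within that
bin — robust when background dominates), or by the 99th percentile. YUV
uses BT.601 full-range coefficients — the conventional matrix in the
digital-holography colour literature, which cites YUV without printing
coefficients — and the inverse is the exact matrix inverse, so round trips
are exact to 1e−10 in gamut. `enhance_colour()` box-filters U and V
(reflect padding; default 9×9 at super-resolved pitch, a scale safely above
the rainbow-fringe period yet below stain-structure scale; configurable and
the artifact-score tests are kernel-parametric) and never touches Y —
bit-exact preservation is asserted. `ablation_replace_y()` implements the
single-band luminance-replacement baseline: chroma from a low-resolution
composite, Y from one high-resolution band. On a band-selective phantom
(transmittance R 0.9, G 0.2, B 0.7 — a reddish stain mostly opaque to
green) the full three-band pipeline reproduces the ground-truth colour
image with strictly lower RMS error than this ablation, because absorption
seen only in the R/B bands is absent from a G-only luminance.

## Resolution metric

The paper-style resolvability judgement is visual; the package quantifies
it. For a three-bar element the mean profile across the bars (averaged
along the central 60 % of the bar length) is sampled at the geometric bar
centres (3 troughs) and at the gap and flank centres (2 + 2 peaks; flanks
half a period outside the outer bars, symmetric with the gaps — the only
placement consistent with a pure-sinusoid profile giving
(0.7−0.3)/(0.7+0.3) = 0.4). Contrast is `(I_max − I_min)/(I_max + I_min)`
after normalising by the flank level, which makes the statistic exactly
invariant to positive global rescaling; invariance to an additive offset is
not achievable without a dark reference and is not claimed. A ladder is
scanned coarse-to-fine and stops at the first element failing the 0.15
threshold in either orientation (USAF convention). The 0.15 default sits
below the Rayleigh-equivalent ~26 % and tolerates pixel-integration
attenuation near Nyquist; it is surfaced in every report.

Bar targets are rasterised by pixel-centre inclusion with the pattern
centre snapped to the nearest sample-lattice point ("grid-aligned"); the
ladder evaluator additionally offers sensor-pixel-centre alignment
(`align = "sensor"`), the best-case geometry for the near-Nyquist baseline
where bar-to-aperture phase dominates the measured contrast.

## Desk scale

The resolution ladder is simulated **per target** on 64×64-pixel sensor
grids (256×256 super-resolved). The targets span < 10 µm and the first
Fresnel zone at `z2 = 1` mm is ~23 µm, so a 118 µm field holds the fringe
energy; pitches, wavelengths, `z2`, iteration count and constraint are
exactly those of the full-scale acquisition. This keeps the complete
acceptance run near one minute in base-R FFTs instead of ~15 minutes at a
512×512 sensor, without changing any physics the claims depend on.

## Limitations

* **Single-hologram baseline at 1.74 µm.** The 1.74 µm element has period
  3.48 µm = 0.53 cycles per 1.85 µm sample — above the sensor Nyquist
  limit. Under full-fill box integration, bicubic up-sampling and an
  uncorrected twin image at `z2 = 1000` µm, its amplitude contrast measures
  ≈ 0.13 for both lattice- and sensor-aligned placements, just under the
  0.15 criterion, so the simulated baseline resolves 1.95 µm. The
  corresponding acceptance test is left failing rather than tuned: the
  instrument-level claim rests on a visual judgement, an unknown effective
  fill factor and an unstated `z2` for a chart laid directly on the sensor,
  none of which the stated simulation world includes.
* The simulator shares the angular-spectrum propagator with the
  reconstructor (an inverse-crime setup); the propagator itself is verified
  against an independent brute-force oracle, but real-data mismatches
  (partial coherence, sensor MTF, z2 error) are out of scope, as are
  multi-height retrieval, TIE initialisation and autofocus.
* Phase objects are supported by the forward model and constraint, but the
  acceptance evidence is amplitude-target based.
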