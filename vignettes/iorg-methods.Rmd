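---
title: "Methods: intensity-based optoretinography analysis in iorgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intensity-based optoretinography analysis in iorgtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iorgtools)
```

## The measurement and its model

Intensity-based optoretinography (iORG) measures cone photoreceptor
function from the light they backscatter: after a visible stimulus, the
reflectance of individual cones recorded by an adaptive-optics scanning
light ophthalmoscope (AOSLO) begins to fluctuate, and the magnitude of
that fluctuation tracks the cell's functional response. `iorgtools`
implements the analysis chain from registered acquisition videos plus
cone-center coordinates to per-cone and per-population response
amplitudes, together with the structural metrics (mosaic spacing, outer
segment length), stimulus dosimetry, and cohort statistics with which
those amplitudes are interpreted.

An *acquisition* is one video (six seconds at 29.4 Hz by default, with
the stimulus delivered two seconds in); a *trial* is a series of ten
acquisitions. Frame $k$ is stamped $(k-1)/f$ seconds at frame rate $f$,
and the stimulus frame is the first frame at or after the delivery
time.

### Signal extraction

For each acquisition the package:

1. optionally removes residual intra-frame distortion by measuring, per
   horizontal strip, the displacement aligning every frame's strip to
   the reference frame and undoing the median across frames
   (`correct_intraframe_distortion()`), and residual full-frame drift by
   an affine registration that maximizes Pearson correlation with the
   reference (`affine_register_frames()`);
2. standardizes the image-containing pixels of each frame to mean 70
   and SD 35 (`standardize_frames()`), removing global intensity swings
   while keeping values in image units;
3. refines each cone coordinate to a local maximum of the acquisition
   average image by greedy 8-connected hill climbing
   (`refine_coordinates()`);
4. averages pixel intensities inside a cylindrical column through each
   cone (`extract_cone_signals()`); the column radius is half the median
   nearest-neighbor spacing times the cone-profile FWHM fraction
   (default 0.6), so it covers the central full width at half maximum of
   one cone's reflectance profile without touching its neighbors';
5. excludes cones missing more than 50% of the frames within 0.2 s of
   stimulus delivery, missing 50% or more of the acquisition's frames,
   or present in fewer than half of the trial's acquisitions
   (`apply_exclusion()`); and
6. subtracts each cone's pre-stimulus mean (`subtract_prestim_mean()`),
   using all frames strictly before the stimulus frame.

"Image-containing" pixels default to those with positive intensity
(registration zero-fills empty canvas); an explicit mask can be
supplied. The boundary semantics of the exclusion rules are
deliberately asymmetric — strictly more than 50% for the stimulus
window, at least 50% for the whole acquisition, strictly fewer than 50%
of acquisitions — following the operating definitions the rules were
stated with.

### RMS summaries and amplitudes

With $R_c[t]$ the mean-subtracted reflectance of cone $c$ at frame $t$,
the population summary of one acquisition with $n$ cones is

$$\mathrm{RMS}_\mathrm{pop}[t] = \sqrt{\tfrac1n \sum_{c=1}^n R_c[t]^2},$$

and the individual summary of one cone over its $m$ acquisitions is

$$\mathrm{RMS}_\mathrm{indiv}[t] = \sqrt{\tfrac1m \sum_{a=1}^m R_a[t]^2}.$$

Missing cone-frames are dropped from the mean rather than imputed, and
the per-frame count of contributing terms is recorded. The response
**amplitude** of either trace is the 99th percentile of the RMS within
one second after the stimulus minus the mean RMS within one second
before it; percentiles interpolate linearly between order statistics
(type-7 quantiles), the most common convention and continuous in the
data. Because the spread of individual amplitudes grows with their
mean, individual amplitudes are log-transformed (base 10 — the
conventional reading of decade-scaled amplitude axes; configurable) and
summarized as an empirical CDF.

Population amplitudes are computed per acquisition, averaged within a
trial, then averaged across the (by default three) stimulus trials;
both this mode and pooling are available, and the choice only matters
at small trial counts.

### Healthy-cone fraction

The 554 nm stimulus barely excites S cones (~5% of the mosaic), so in a
fully healthy mosaic about 5% of cones should populate the bottom of
the amplitude distribution. The package therefore takes the 5th
percentile of a control (normative) sample of log amplitudes as a
threshold and reports the fraction of cones at or above it
(`healthy_fraction()`); a healthy mosaic scores ~0.95 by construction.
Cones with non-positive amplitudes count as below threshold.

### Structural metrics and dosimetry

`bound_nnd()` reports the mean nearest-neighbor distance over *bound*
cones — those whose Voronoi cell lies entirely inside the region of
interest — so edge cones whose true nearest neighbor may be outside the
field do not bias the estimate. Cells are built by half-plane
intersection (clipping a large box with perpendicular bisectors,
nearest-first with a distance cutoff), which is exact for this purpose
and needs no external geometry library. `z_score()` standardizes a
metric against per-eccentricity control means and SDs.

`detect_os_length()` measures cone outer-segment length from an OCT
longitudinal reflectance profile as the distance between the two most
prominent peaks (the ellipsoid-zone and interdigitation-zone bands) in
a depth window, with Gaussian pre-smoothing (SD 2 samples by default)
and parabolic sub-sample refinement. Detection is invariant to
reflectance gain/offset and depth-axis orientation; results outside
12.8–38.4 µm (the plausible control range across eccentricities) carry
a QC flag. The 2-sample smoothing default was chosen by simulation:
against bands of typical width it roughly halves the noise-driven error
(RMSE ~0.5 µm at 10:1 peak SNR) at a negligible (<0.05 µm) separation
bias.

`photon_density()` converts the corneal power density of the stimulus
(default 17.6 µW/deg² at 554 nm) to photons/s via the photon energy
$hc/\lambda$, attenuates by lens and macular pigment transmissions,
multiplies by the flash duration (66 ms), and divides by the retinal
area per square degree — the squared retinal magnification factor
(291 µm/deg) scaled by $(\mathrm{AL}/24\,\mathrm{mm})^2$, since a longer
eye spreads one degree over more retina (and accordingly the longest
eyes in a cohort receive the lowest photon density). Two conventions
deserve note. First, because the input power is already a per-degree²
density, dividing it by the stimulus area (1.13 deg²) would normalize
twice; the default skips that division, and `area_normalize = TRUE`
restores it for inputs expressed as total power. Second, the flash
duration used in dosimetry (66 ms) and the stimulus duration used by
the acquisition timeline (68 ms) are kept as separate configurable
fields. At unit transmissions and the reference axial length the closed
form gives 3.823×10⁷ photons/µm²; at typical adult transmissions
(0.78 lens, 0.80 macular) it falls in the middle of the 1.86–2.77×10⁷
range spanned by a real adult cohort.

## The synthetic acquisition generator

Raw AOSLO recordings are large, subject-specific, and not
redistributable, so the package carries a generator that reproduces the
statistical structure the analysis relies on, with ground-truth
manifests for validation.

**Mosaic.** `generate_mosaic()` lays a hexagonal lattice (spacing
default 5 µm, the scale of the parafoveal cone mosaic) with isotropic
Gaussian positional jitter, on a pixel grid defined by the imaging
scale (600 px/deg) and retinal magnification (291 µm/deg). With zero
jitter the nearest-neighbor distance equals the spacing exactly, which
anchors the mosaic-metric tests. Under jitter the *mean* NND shrinks
below the spacing — the minimum of several jittered neighbor distances
concentrates low — by roughly $1.2\sqrt2\,\sigma_j$; this is a property
of any jittered lattice, and the tests assert the Monte-Carlo-derived
value rather than wishing it away.

**Response.** Each cone draws a ground-truth amplitude from
$10^{\mathcal N(\mu, \sigma)}$ (defaults $\mu = 1.5$, $\sigma = 0.35$
log₁₀ AU, i.e. ~32 AU typical — matching control-range population
amplitudes — with the decade-wide per-cone spread seen in empirical
amplitude CDFs); a `nonresponder_fraction` (default 5%, the S-cone
share) responds not at all. During the response window (1 s from
stimulus onset) the cone's reflectance deviates from baseline by
*amplitude × a random sign per frame*. This controlled-RMS process has
per-frame RMS exactly equal to the programmed amplitude, which is what
makes the manifest a usable ground truth: the extraction pipeline must
return the manifest amplitude to within numerical error. A zero-mean
Gaussian process with SD equal to the amplitude has the same second
moment, but the 99th-percentile-of-RMS summary of such a trace is
biased upward at any finite number of acquisitions, so it cannot serve
as an exact reference; only the second moment of the process is
analytically relevant, and any controlled-RMS process is equivalent for
the statistics computed here. Frame-rate noise of SD `noise_sd`
(default 5 AU) rides on every frame; the default places the extracted
noise floor near 5 AU for a 10-acquisition trial, the floor level
observed for cone populations whose mean amplitudes sit near 30 AU.
A `dropout_fraction` of frames is marked invalid, and small per-frame
affine motion can be injected and is recorded in the manifest.

**Rendering.** `render_acquisition()` draws cones as isotropic Gaussian
profiles with FWHM 0.6× the mosaic spacing, truncated at half the
spacing. Truncation keeps each cone's sampling column free of neighbor
light — without it, tail overlap from six neighbors leaks percent-level
cross-talk into the column average and no exact ground truth exists.
Each cone's fluctuation is divided by the mean of its profile over its
own sampling column (the same disc-pixel helper the extractor uses), so
manifest amplitudes are in extracted-signal units. For cohort-scale
statistical simulations, `simulate_trial_signals()` produces the
cone-by-frame tables directly — identical response model, no pixel
round trip — because rendering is validated separately and only adds
cost at that scale.

The generator deliberately omits optics: no PSF, no rod mosaic, no
intra-frame scan distortion model, no split-detection channel. Passing
tests on synthetic cohorts therefore demonstrate that the *analysis*
chain is correct and well calibrated — amplitude recovery, monotonicity,
threshold calibration — not that it is robust to every artifact of real
AOSLO video; the registration and distortion-correction operators are
exercised against injected motion of known magnitude instead.

## Numerical and design choices

- **Percentile and threshold conventions:** type-7 (linear
  interpolation) quantiles throughout; the empirical CDF is
  right-continuous with $F(\min) = 1/n$.
- **Hill climbing:** 8-connected, strictly uphill (plateaus stay put),
  at most 10 steps, displacement capped by `max_radius`, ties broken by
  first-found in row-major order — deterministic by construction.
- **Stimulus window for exclusion:** the 0.2-s window is one-sided,
  `[stimulus_frame, stimulus_frame + ceil(0.2 f)]`; missing data after
  delivery is what makes stimulus receipt unverifiable. (A centered
  window is a defensible alternative; it changes only which frames the
  50% rule counts.)
- **Pre-stimulus mean:** all frames strictly before the stimulus frame,
  with no window cap — the amplitude definition applies its own 1-s
  windows separately.
- **Registration:** integer-translation initialization by exhaustive
  correlation search, then BFGS refinement of the six affine
  parameters (translations scaled 100:1 against the linear part);
  frames that fail to converge or correlate below `min_cor` are flagged
  invalid rather than propagated.
- **Spearman p-values:** exact null distribution for n ≤ 20 without
  ties, t-approximation otherwise (exhaustive permutation is infeasible
  beyond tiny n).
- **Degenerate inputs:** zero-variance frames are flagged invalid;
  constant reflectance profiles raise a "no peaks" error; cones with no
  valid pre-stimulus frame are dropped with a message; non-positive
  amplitudes are excluded from log summaries and counted as unhealthy.
- **Z-scores:** computed signed, reported as magnitudes in summary
  tables (the convention in normative comparisons), with both exposed.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
every check statistically meaningful while remaining quick on one CPU:
mosaics of ~50–200 cones, rendered acquisitions of ~117 frames
(4 s at 29.4 Hz — one second of margin on each side of the amplitude
windows), 1000-cone signal-level arms for threshold calibration, 20-seed
grids for monotonicity and cohort ordering, 100-seed Monte Carlo for
OS-length recovery, and 1000 replicates at n = 50 for
prediction-interval coverage. All are package choices and scale up
linearly via the corresponding arguments.

## Limitations

- The synthetic response is phenomenological: it controls the RMS of
  the post-stimulus fluctuation and nothing else. Real iORG dynamics
  (oscillatory components, slow recovery, subject adaptation) are out
  of scope, as are rods, optics and scanner artifacts.
- OS length from clinical OCT is an aggregate over many cones; the
  per-profile measurement here inherits that interpretation.
- The dosimetry model is monochromatic at 554 nm and treats lens and
  macular transmission as supplied constants; measured spectra and
  age-dependent transmission tables can be plugged in but are not
  bundled.
- Sensitivity pairing is by eccentricity alone; no fundus
  co-registration is attempted.
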