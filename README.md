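# iorgtools

Analysis of **intensity-based optoretinography (iORG)** — a functional
assay of cone photoreceptors that measures stimulus-evoked changes in
the light individual cones backscatter in adaptive-optics scanning
light ophthalmoscope (AOSLO) video. The package is aimed at retinal
imaging groups who have registered acquisition stacks and cone-center
coordinates and want reproducible per-cone and per-population response
amplitudes, plus the structural and dosimetric context those amplitudes
are read against.

## What it computes

Given mean-subtracted cone reflectances $R_c[t]$, the package summarizes
responses as the frame-wise root mean square over the cones of one
acquisition (population RMS),

$$\mathrm{RMS}_\mathrm{pop}[t] = \sqrt{\tfrac1n \sum_{c=1}^{n} R_c[t]^2},$$

or over one cone's $m$ acquisitions (individual RMS),

$$\mathrm{RMS}_\mathrm{indiv}[t] = \sqrt{\tfrac1m \sum_{a=1}^{m} R_a[t]^2}.$$

The **amplitude** of a trace is the 99th percentile of the RMS within
1 s after stimulus delivery minus the mean RMS within 1 s before it.
Individual amplitudes are log₁₀-transformed, summarized as empirical
CDFs, and scored against a normative 5th-percentile threshold to give
the fraction of putatively healthy cones (~95% in a healthy mosaic,
since ~5% of cones are S cones that a 554 nm stimulus barely excites).

Around that core the package provides:

- the extraction chain: frame standardization (mean 70 / SD 35),
  strip-median distortion correction, correlation-maximizing full-frame
  affine registration, hill-climbing coordinate refinement, cylindrical
  column projection, missing-data exclusion rules, pre-stimulus mean
  subtraction;
- mosaic metrics: bound nearest-neighbor distance (Voronoi-cell
  containment) and z-scores against per-eccentricity normative tables;
- outer-segment length from OCT longitudinal reflectance profiles
  (ellipsoid-zone to interdigitation-zone peak distance);
- retinal photon-density dosimetry from corneal power and ocular
  biometry;
- cohort statistics: OLS fits with 95% prediction intervals, Spearman
  correlations, eccentricity-based pairing with microperimetry
  sensitivities;
- a synthetic acquisition generator (mosaics, videos, reflectance
  profiles, whole cohorts) with ground-truth manifests, used by the
  test suite to validate the entire chain end to end.

## Worked example

Simulate one imaging location and run the full summarization chain:

```r
library(iorgtools)

# simulate one imaging location: jittered cone mosaic + one stimulus trial
mosaic <- generate_mosaic(mosaic_spec(spacing = 5, jitter_sd = 0.3,
                                      field_size = 0.15, seed = 1))
resp   <- response_spec(seed = 1)
amps   <- draw_amplitudes(nrow(mosaic), resp)
trial  <- lapply(1:10, function(a) {
  acq <- render_acquisition(mosaic, resp, duration = 4, amplitudes = amps,
                            seed = 100 + a)
  subtract_prestim_mean(
    extract_cone_signals(acq$stack, mosaic, compute_column_radius(mosaic)))
})

# population response of the first acquisition
pop <- population_rms(trial[[1]])
extract_amplitude(pop)
#> <amplitude_record> amplitude 43.014 AU (pre 4.805, post p99 47.818)

# individual response distribution across the trial
log_amps <- log_transform(sapply(seq_len(nrow(mosaic)), function(i)
  extract_amplitude(individual_rms(trial, i))$amplitude))
normative <- normative_distribution(log_amps)
round(normative$p5_threshold, 2)
#> [1] 0.71
round(healthy_fraction(log_amps, normative), 3)
#> [1] 0.942

# mosaic structure and stimulus dose
bound_nnd(mosaic, scale = attr(mosaic, "um_per_px"))
#> <mosaic_metrics> mean bound NND 4.504 um over 27 bound cones (52 total)
signif(photon_density(photometry_params(lens_transmission = 0.78,
                                        macular_transmission = 0.80,
                                        axial_length = 24.1)), 4)
#> [1] 23660000
```

Reading the numbers: the population of this simulated location responds
with an amplitude of ~43 AU above a ~4.8 AU pre-stimulus noise floor;
94.2% of its cones clear the 5th-percentile normative threshold (the
location *is* its own normative sample here, so ~95% is expected by
construction); the mosaic's bound nearest-neighbor distance is 4.5 µm
(slightly under the 5 µm lattice spacing because positional jitter
shortens minima); and the stimulus delivered ~2.4×10⁷ photons/µm² to
this eye.

`run_pipeline()` (or `inst/scripts/iorg-pipeline.R` from a shell)
chains simulation, extraction, summarization, metrics and reporting for
whole multi-arm cohorts and writes traces, amplitudes, CDFs, metrics,
a statistics report and a provenance manifest.

## Package layout

- `R/` — implementation (synthetic data, extraction, registration, RMS
  summaries, mosaic metrics, LRP, photometry, cohort statistics,
  pipeline).
- `inst/extdata/` — example cohort demographics and normative
  statistics tables.
- `vignettes/iorg-methods.Rmd` — the model, parameter choices,
  numerical conventions and limitations, in detail.
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
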