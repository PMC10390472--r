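# spherosect

Quantitative image analysis for cryosectioned spheroid and hydrogel samples.

Thin sections of multicellular spheroids embedded in fibrillar (collagen)
hydrogels can be imaged by essentially every modality at once — widefield,
confocal, Airyscan, SIM, STORM, and DESI mass-spectrometry imaging of the
same physical slices. `spherosect` implements the quantification that such
experiments need, together with synthetic phantoms carrying full ground
truth so that every estimator is testable by parameter recovery:

* **Fiber-width morphometry** — intensity transects across fibers fit with
  `y = y0 + A·exp(−(x−x0)²/(2σ²))`; fits with adjusted R² < 0.95 are
  discarded; apparent width is the mean FWHM `2√(2 ln 2)·σ` over accepted
  fits. Bead images calibrate each modality's PSF FWHM (its resolution and
  minimum apparent fiber width).
* **Characteristic pore size** — band-pass + rolling-ball preprocessing,
  auto local threshold, row-by-row and column-by-column counting of gaps
  between "on" pixels, and a maximum-likelihood fit of the exponential
  density `f(x) = λ·e^(−λx)`; the reported pore size is `1/λ`.
* **SMLM reconstruction** — camera-model photon conversion
  (`photons = (ADU − baseline)·gain`), per-frame detection and weighted 2D
  Gaussian fitting, photon/σ quality filters, DBSCAN outlier removal
  (ε = 50 nm, minPts = 5), cross-correlation drift correction over 5
  temporal bins, normalized-Gaussian rendering (10 nm), Thompson-style
  localization precision, Nyquist resolution `2/√ρ` from localization
  density, and the combined metric
  `Resolution = √(Precision² + Nyquist²)`.
* **Spheroid-section metrics** — max-normalized bisecting intensity
  profiles and per-slice summaries (staining uniformity), max-ratio
  signal-to-background, and the invasion metric
  `2π·(r_front − r_core)` with `r_front` the radius enclosing ≥ 90% of
  invading-cell centroids.
* **MSI statistics** — TIC normalization, windowed mean intensities over
  section masks, pairwise condition comparisons with star annotations
  (α = 0.05), ppm-tolerance ion images, and annotation against a
  user-supplied monoisotopic mass table (5 ppm default).
* **Correlative registration** — fiducial-free rigid/similarity alignment
  by normalized cross-correlation, robust to a 40 µm-vs-sub-µm resolution
  gap, with RGB overlays.

## Worked example

Simulate a collagen-like network whose inter-fiber gaps follow an
exponential law with rate 1/3 µm⁻¹ (characteristic pore size 3 µm), then
recover the pore size and the apparent fiber width from the image alone:

```r
library(spherosect)

phantom <- fiber_network_phantom(field_um = c(102.4, 102.4), pixel_size = 0.1,
                                 gap_rate = 1 / 3, seed = 7)
image <- generate_fiber_image(phantom, modality = "storm_render",
                              background = 0.05, seed = 8)
phantom
#> <fiber_phantom> 788 fibers in 102.4 x 102.4 um, sigma 150 nm, gap rate 0.3333 /um (1/rate = 3 um)

fit <- pore_size_pipeline(image)
summary(fit)
#> Characteristic pore size: 2.851 um
#> Exponential rate lambda:  0.3507 per um (mle)
#> Gap sample:               n = 60626, mean 2.851 um, median 2 um
#> KS statistic vs fit:      0.1003

rois <- auto_transects(image, 30, length_um = 3, seed = 9)
fiber_width_report(image, rois)
#> <fiber_width_report> mean FWHM 0.3669 um (SD 0.0297), 18 accepted / 12 rejected fits

combined_resolution(precision_nm = 10, nyquist_nm = 40)
#> <resolution_estimate> precision 10 nm, Nyquist 40 nm, combined 41.2 nm
```

The recovered pore size (2.85 µm) sits a few percent from the generative
3 µm on this deliberately small demonstration field; larger fields tighten
the sampling scatter (see the methods vignette for the bias/variance
budget). The fiber width, 0.367 µm, is the rendered width of the phantom's
150 nm-σ fibers (FWHM 353 nm) plus interpolation broadening.

Other entry points: `generate_smlm_movie()` → `detect_and_fit()` →
`filter_localizations()` → `dbscan_filter()` → `drift_correct()` →
`render_localizations()` for the STORM chain; `generate_spheroid_slices()`,
`bisecting_profile()`, `invasive_distance()`, `compare_groups()` for
section metrics; `generate_msi_cube()`, `tic_normalize()`, `window_mean()`,
`ion_image()`, `annotate_peaks()` for MSI; `register_images()`,
`overlay_images()` for correlative work; `run_pipeline()` for seeded,
manifest-producing batch runs.

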