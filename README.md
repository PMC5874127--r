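# ringnps — ring-sampled noise power spectrum analysis for CT

CT reconstruction algorithms differ not only in how much noise they leave
in an image but in its *texture*: filtered back projection (FBP)
concentrates noise power in a mid-frequency ridge, while model-based
iterative reconstruction pushes it toward low spatial frequencies and
changes with dose. The noise power spectrum (NPS) is the standard bench
measurement of this texture. For patient-sized (elliptical) phantoms the
noise is also nonstationary — stronger toward the isocenter and
direction-dependent — so a single central ROI is not representative.

`ringnps` implements the ring-sampled NPS protocol for medical physicists
doing phantom-based image-quality assessment: 16 × 16 px ROIs are placed
along concentric rings (default radii 50, 90, 120, 180 px, arc spacing
8 px, giving ⌊2πr/8⌋ = 39/70/94/141 ROIs), noise is isolated by
ratio-detrended subtraction of consecutive scans

```
I_noise(i,j,Ck) = ( ROI_i − ROI_{i+1} · mean(ROI_i)/mean(ROI_{i+1}) ) / √2,
```

with circular wrap of the scan index, and each ring's 2D NPS is the
ensemble-averaged periodogram

```
NPS(fx,fy) = Δx·Δy / (Nx·Ny) · mean | DFT2D[I_noise] |²   [HU²·mm²],
```

reported as one-sided horizontal/vertical marginal curves plus scalar
summaries: peak frequency (DC excluded), integrated power (the Parseval
variance, HU²), and a normalized-L1 anisotropy index in [0, 2] comparing
the two marginals. A synthetic phantom generator with exactly known
spectra (spectral synthesis), a radial noise-magnitude profile and the
quantum dose law σ(D) = σ_ref·√(D_ref/D) makes every stage verifiable
without scanner data. Readers for uncompressed DICOM series, multi-page
TIFF and a plain-text array-stack format are included, along with the
0.625 mm → 2.5 mm thin-to-thick slice reformat (unweighted 4-slice mean).

## Worked example

Simulate 10 repeated scans of the elliptical phantom with FBP-like
band-pass noise (marginal-NPS peak at 0.30 /mm, σ = 10 HU at 18.88 mGy,
center-elevated magnitude) at 5.81 mGy, and run the full analysis:

```r
library(ringnps)

stack <- generate_scan_series(series_recipe(
  phantom = phantom_spec(),
  noise = noise_model("bandpass", sigma_ref = 10, f0 = 0.30, width = 0.15,
                      radial = radial_profile(g_center = 2, r_edge_px = 256)),
  n_scans = 10, dose_mGy = 5.81, seed = 42, condition = "fbp_like"))
stack
#> image_stack: 10 scan(s) of 512 x 512 px, spacing 0.703125 x 0.703125 mm
#> labels: condition=fbp_like, dose_mGy=5.81, seed=42

res <- run_analysis(analysis_config(list(fbp_like = stack)))
print(res$fbp_like$scalars, digits = 3)
#>   condition ring_radius_px peak_horizontal_per_mm peak_vertical_per_mm
#> 1  fbp_like             50                  0.267                0.267
#> 2  fbp_like             90                  0.267                0.267
#> 3  fbp_like            120                  0.267                0.356
#> 4  fbp_like            180                  0.267                0.267
#>   integrated_power_hu2 anisotropy_index
#> 1                 1044           0.0333
#> 2                  883           0.0211
#> 3                  762           0.0244
#> 4                  544           0.0109
```

Reading the output: the horizontal-peak frequency lands on the DFT bin
nearest the 0.30 /mm texture target (bin width 1/(16·0.703125 mm) ≈
0.089 /mm); integrated power — the noise variance in HU² — falls
monotonically from the innermost ring (1044) to the outermost (544),
reflecting the radial profile; at 5.81 mGy the variance is inflated by
18.88/5.81 ≈ 3.25 over the reference-dose σ² = 100 before the radial
multiplier. The anisotropy index near 0 says horizontal and vertical
texture match, as they should for this isotropic-in-axes model. Per-ring
curves are available as tidy tables:

```r
head(condition_curve_table(res$fbp_like), 4)
#>   condition ring_radius_px       axis frequency_per_mm nps_hu2mm2
#> 1  fbp_like             50 horizontal       0.00000000   221.2268
#> 2  fbp_like             50 horizontal       0.08888889   394.8780
#> 3  fbp_like             50 horizontal       0.17777778   690.5132
#> 4  fbp_like             50 horizontal       0.26666667   926.1266
```

`run_compare()` tabulates per-ring, per-axis curve differences and scalar
deltas between conditions.

## The analysis workflow

`analysis/` holds the three-step synthetic study, each script a thin
driver over the package:

1. `01_simulate.R` — defines 12 conditions (FBP-like and MBIR-like
   textures across the six-level CTDIvol ladder 0.97–18.88 mGy) and
   writes their recipes to `results/recipes/`; recipes plus seeds *are*
   the dataset.
2. `02_estimate_nps.R` — regenerates every stack and writes per-condition
   curve tables, scalar summaries and a full-parameter run log to
   `results/nps/`.
3. `03_compare.R` — texture comparison by dose, the 1/D dose-law fit
   (exponent ≈ −1), the MBIR-like peak shift toward low frequency at low
   dose, and a curve figure, under `results/comparisons/` and
   `results/figures/`.

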