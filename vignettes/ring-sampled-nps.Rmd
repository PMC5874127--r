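---
title: "Ring-sampled NPS estimation: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-sampled NPS estimation: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The noise in a CT image is not white: the reconstruction kernel, and even
more so iterative reconstruction, correlates neighbouring pixels and gives
the noise a characteristic *texture*. The noise power spectrum (NPS)
decomposes the pixel noise variance over spatial frequency and is the
standard bench quantity for comparing reconstruction algorithms: filtered
back projection concentrates power in a mid-frequency ridge, model-based
iterative reconstruction pushes it toward low frequencies (a "blotchy"
look), and the peak position and magnitude change with dose.

For a patient-sized (elliptical) phantom the noise is also *nonstationary*:
its magnitude grows toward the image center, and its directionality depends
on position. A single central ROI therefore does not characterise the
image. This package measures the NPS on four concentric sampling rings
(radii 50, 90, 120 and 180 pixels by default) so that each ring reports a
locally-stationary spectrum at its own distance from the isocenter.

## The estimator

**Sampling.** Square ROIs of $N \times N = 16 \times 16$ pixels are centred
on each ring at equal arc spacing of 8 pixels, giving
$\lfloor 2\pi r / 8 \rfloor$ ROIs per ring (39, 70, 94, 141 on the default
rings). Neighbouring ROIs overlap tangentially by about half; this is
deliberate — it doubles the angular sampling density at the cost of
inter-patch correlation, which inflates estimator variance but not bias.
Centers are rounded to whole pixels; no subpixel resampling is done, since
interpolation would colour the very spectrum being measured.

**Noise isolation.** With $n$ repeated scans of a static phantom, the
noise of ROI $j$ on ring $C_k$ in scan $i$ is taken as

$$I_{noise}(i,j,C_k) = \Big(A_{i,j} - A_{i+1,j}\,
  \frac{\overline{A_{i,j}}}{\overline{A_{i+1,j}}}\Big)\frac{1}{\sqrt2},
  \qquad A_{n+1} \equiv A_1,$$

the difference of co-located ROIs of consecutive scans, with the second
patch rescaled by the ratio of patch means. The subtraction removes the
deterministic phantom structure and the DC component; the ratio removes
multiplicative drift between scans (tube output fluctuation); the
$1/\sqrt2$ restores single-image variance. The pairing wraps circularly so
each of the $n$ scans contributes exactly once as minuend, yielding
$n \times (\text{ROI count})$ noise patches per ring.

*The mean offset.* The ratio $\overline{A_i}/\overline{A_{i+1}}$ is
numerically fragile when ROI means sit near 0 HU (water-like material, as
in a phantom test module). `noise_roi_pair()` therefore adds a
`mean_offset` (default +1000 HU, i.e. the CT-number offset to the linear
attenuation scale) to both patches before forming the ratio. At offset 0
the literal ratio formula is recovered; as the offset grows the estimator
tends to the plain scan difference. A consequence worth stating: with a
*finite* offset the estimator is only approximately invariant to adding a
global HU constant — exactly invariant for constant patches and in the
pure-subtraction limit, and in realistic conditions (±100 HU shifts,
$\sigma \approx 10$ HU) the induced relative NPS change is below $10^{-3}$.
The test suite pins both the approximate and the limiting exact behaviour.

**Spectrum.** Per ring, the 2D NPS is the ensemble-averaged periodogram

$$NPS(f_x, f_y) = \frac{\Delta x\, \Delta y}{N_x N_y}\;
  \overline{\big|\mathrm{DFT}_{2D}[I_{noise}]\big|^2},$$

in HU²·mm², on the unshifted DFT grid with bin widths
$\Delta f = 1/(N\Delta)$. No window, no zero padding, and no detrending
beyond the pair subtraction are applied. The DC bin is kept as computed
(the pair subtraction is the DC-removal step) but excluded from peak
finding, since the residual DC term is not noise texture. With this
normalization the Parseval identity

$$\sum_{\text{bins}} NPS \cdot \Delta f_x \Delta f_y
  = \overline{\;\overline{I_{noise}^2}\;}$$

holds to machine precision for any input, and is enforced as an invariant
test at $10^{-10}$ relative tolerance.

**Marginal curves.** The horizontal curve is the mean of the 2D NPS over
all $f_y$ bins as a function of $f_x$ (and conversely for vertical),
averaged over scans. Because the periodogram of real input is exactly
symmetric under $(f_x,f_y) \to (-f_x,-f_y)$, the two-sided marginals are
folded to one-sided axes $0 \dots f_{Nyq}$ by averaging the $\pm f$ bins —
no doubling, DC and Nyquist reported once. Folding (rather than slicing
the positive half) was chosen because the marginals are exactly symmetric,
so the fold loses nothing and halves the reported table size.

**Scalar summaries.** `peak_frequency()` (argmax excluding DC, ties to the
lower frequency), `integrated_power()` (the Parseval variance, HU²), and
an anisotropy index

$$AI = \frac{\sum_k |h_k - v_k|}{\sum_k (h_k + v_k)/2} \in [0, 2]$$

over non-DC bins. The index is this package's own construction — the
horizontal/vertical match is usually judged visually — chosen as a
normalized $L_1$ distance for scale invariance (conditions of different
noise magnitude compare fairly) and boundedness. 0 means identical curves;
2 means disjoint support.

## The synthetic twin

Scanner data for algorithm comparisons are not redistributable, so the
package carries a generator whose noise statistics are known exactly,
making every pipeline stage verifiable.

**Phantom.** A piecewise-constant HU map: central test module (radius
100 mm, +40 HU) inside an oval fat-equivalent annulus (semi-axes
170 × 135 mm, −100 HU) in air (−1000 HU), rendered at 512 × 512 px and
0.703125 mm pixels (a 36 cm field of view). With this geometry all four
default rings lie on phantom material; `phantom_mask()` supports masking
for geometries where an outer ring leaves the phantom.

**Noise.** Correlated fields are produced by spectral synthesis: a unit
white Gaussian field is reweighted in the frequency domain by
$\sqrt{P_{target}/(\Delta x \Delta y)}$, so the *expected periodogram of
the full field equals the target exactly, bin by bin* (circulant
synthesis). Spectrum families:

* `white` — flat at $\sigma^2 \Delta x \Delta y$;
* `lowpass_gaussian` — isotropic Gaussian low-pass (default width
  0.5 /mm), the smooth texture of iterative reconstruction;
* `bandpass` — a *separable* ridge
  $e^{-(|f_x|-f_0)^2/2w^2} e^{-(|f_y|-f_0)^2/2w^2}$ (defaults $f_0 =
  0.30$ /mm, $w = 0.15$ /mm). Separability is a deliberate choice: it
  makes the horizontal/vertical *marginal* curves peak exactly at $f_0$,
  so $f_0$ is directly the texture-peak frequency the estimator reports.
  A radially symmetric ridge would put the marginal peak well below $f_0$
  because averaging over the orthogonal frequency smears the ring;
* `anisotropic_gaussian` — Gaussian low-pass with the $x$ width multiplied
  and the $y$ width divided by `axis_ratio` (default 2), for
  direction-dependent texture.

All families are normalized so the spectrum integrates to $\sigma^2$.

**Nonstationarity and dose.** A radial multiplier
$g(r) = 1 + (g_{center}-1)\max(0, 1 - r/r_{edge})$ (defaults
$g_{center} = 2$, $r_{edge} = 256$ px) emulates the center-elevated noise
of attenuating phantoms; it is a minimal model — real nonstationarity also
changes the spectral *shape* with position, which this multiplier does
not. Dose enters through the quantum-noise law
$\sigma(D) = \sigma_{ref}\sqrt{D_{ref}/D}$ with $\sigma_{ref} = 10$ HU at
$D_{ref} = 18.88$ mGy, over the ladder 0.97, 1.69, 2.9, 5.81, 11.62,
18.88 mGy; the study this emulates states dose levels but no law, and
$\sigma^2 \propto 1/D$ is the standard photon-statistics assumption.

**Seeding.** One master seed per series; per-scan seeds are derived by a
fixed affine step (`scan_seed()`), so any single scan is reproducible in
isolation and the caller's RNG state is never touched.

## What the synthetic tests do and do not show

Passing recovery tests demonstrate that the estimator is unbiased and
correctly normalized for stationary (per ring) Gaussian noise with known
spectra, that the dose, reformat, radial and isotropy behaviours follow
their constructions, and that the geometry and bookkeeping are exact. They
do not validate behaviour on real scanner noise, which is non-Gaussian at
very low dose, nonstationary in spectral shape, and reconstruction-
dependent in ways (edge artifacts, bowtie/ellipse interactions on the
outermost ring) the generator deliberately does not model.

One estimator property matters when comparing against targets: a 16 × 16
patch cut from a *large* correlated field has an expected periodogram
equal to the target convolved with the patch's Fejér kernel (spectral
leakage). This bias belongs to finite-patch periodograms, not to this
implementation. Bin-exact recovery is therefore asserted on ensembles of
independently synthesized patch-sized fields (where circulant synthesis
makes the expectation exact), while full-pipeline ring tests use the white
target (leakage-free) for bin-exact checks and assert peak location — a
leakage-robust property — for coloured targets.

## Numerical and design choices

* Coordinates are 1-based row/column in R; even-sized patches follow the
  half-open convention (a 16-patch around centre $c$ spans
  $[c-8, c+8)$ in 0-based terms). Ring angles start at 3 o'clock and
  advance toward increasing rows; centers round half-up, which keeps the
  center multiset translation-equivariant for integer shifts.
* The hard-coded scan count 10 of the reference protocol generalises to
  the actual $n \geq 2$ everywhere.
* Consecutive pairs share scans, and overlapping ROIs share pixels; the
  ensemble average treats them as exchangeable. This is a variance
  (not bias) effect and is visible as a mild inflation of the
  mean-absolute-relative deviation of flat-spectrum recoveries
  (about 3% at ~2000 patches, versus ~2.3% for independent patches).
* Degenerate inputs fail loudly and early: near-zero denominator means in
  the ratio (within $10^{-6}$ of $-$`mean_offset`), empty patch
  ensembles, masks that remove every ROI, rings whose ROI count is zero,
  non-divisible reformat group sizes, negative or asymmetric synthesis
  targets.
* Slice reformat is an unweighted mean of `group_size` consecutive thin
  slices (thickness-weighted schemes are out of scope); for z-uncorrelated
  noise it divides the variance by the group size, which the tests verify.
* The analysis path contains no randomness: re-running a configuration is
  bit-identical in its CSV outputs.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the estimator at the full
512 × 512 geometry with 4–6 scans (2064+ patches pooled over the four
rings) for flat-spectrum recovery and isotropy, 2000 synthesized patches
for coloured-spectrum recovery, 256 × 256 stacks for the dose ladder and
reformat checks, and 10-scan, 12-condition series in the `analysis/`
scripts. These sizes put Monte-Carlo error comfortably inside the asserted
tolerances (e.g. per-bin relative standard error $\approx 2\%$ at 2000
independent patches) while keeping a full run in tens of seconds.

## Known limitations

* Per-ring stationarity is an approximation; within-ROI nonstationarity
  (strong radial gradients across 16 pixels) biases the local spectrum.
* The outermost ring of a real patient-sized phantom shows behaviour
  (bowtie/ellipse mismatch, different material) that the generator does
  not emulate; on the synthetic twin the radial trend is clean by
  construction.
* No radially-averaged 1D NPS, NEQ, MTF or detectability indices; the
  horizontal/vertical marginals are the reported curves.
* DICOM support is read-only and restricted to uncompressed little-endian
  single-frame files; undefined-length sequences are rejected.
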