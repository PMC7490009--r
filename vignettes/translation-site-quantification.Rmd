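---
title: "Counting nascent chains from smFISH-IF images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nascent chains from smFISH-IF images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentq)
```

## The scientific question

When a SunTag translation reporter is imaged by combined single-molecule
FISH (mRNA channel) and immunofluorescence against the nascent SunTag
epitopes (protein channel), each cytoplasmic mRNA is either *associated*
with a bright green focus — a translation site carrying one or more
ribosome-attached nascent chains — or not. The per-cell fraction of
associated mRNAs is the readout used to ask whether drugs such as
puromycin release nascent chains, and whether elongation inhibitors
(emetine, anisomycin) modulate that release. `nascentq` implements the
full quantification chain for this readout, plus a simulator that
generates images with known per-mRNA translation states so the whole
chain can be validated end to end.

## The measurement model

Every diffraction-limited object is modeled as an anisotropic 3D Gaussian
over a constant local background:

$$ f(z, y, x) = B + A \exp\!\left(-\frac{(x - x_0)^2 + (y - y_0)^2}
   {2\sigma_{xy}^2} - \frac{(z - z_0)^2}{2\sigma_z^2}\right), $$

whose background-subtracted integrated intensity is
$I = A\,(2\pi)^{3/2}\,\sigma_{xy}^2\,\sigma_z$ (voxel units). The chain of
estimators is:

1. **Detection** (both channels independently): Laplacian-of-Gaussian
   bandpass at the PSF scale, sign-flipped so spots are maxima; candidates
   are strict 3×3×3 local maxima above `median + k_mad · MAD` of the
   filtered stack (`k_mad = 6` by default).
2. **Fitting**: Levenberg–Marquardt least squares of the Gaussian model
   over a 5 × 11 × 11 voxel window (z, y, x) clamped to the stack — an
   11 × 11 lateral box with the z extent matched to the ~2.8× coarser
   axial sampling. Fits that do not converge, have non-positive
   amplitude, leave the window, or pin a width at its bound are flagged
   failed.
3. **Single-peptide calibration**: protein spots inside the cytoplasm and
   farther than 500 nm (laterally) from every mRNA are free, released
   single SunTag peptides. Spots outside median ± 3 MAD in integrated
   intensity or width are discarded — an automated stand-in for manual
   inspection of single-peptide fits — and `I_single` is the *mean*
   integrated intensity of the survivors (an idealized-PSF average).
4. **Site quantification**: for each mRNA, the brightest protein voxel in
   an 11 × 11 lateral box (mRNA plane ± 2 z-planes) seeds a Gaussian fit.
   The site passes only with positive amplitude, widths within 0.5–3× the
   calibration medians, and a fitted center within 3 px (~320 nm) of the
   mRNA; any failure assigns a site intensity of exactly 0. The
   nascent-chain count is `N = I_ts / I_single`, and an mRNA is
   *associated* iff `N >= 1` (strictly-below-one-peptide sites are
   unassociated).
5. **Aggregation**: per-cell fraction = associated / total cytoplasmic
   mRNAs; cells with more than five and fewer than 36 mRNAs (6–35
   inclusive) enter the condition summary (mean with SEM); conditions are
   compared with a two-sided two-sample t-test, Welch's unequal-variance
   form by default.

### Choices made where the procedure was open

Several elements of the published workflow depend on an external
detection tool or on manual curation, so this package fixes explicit,
automated equivalents:

- *Detection thresholds* are nowhere stated; LoG + median/MAD with
  `k_mad = 6` gives zero false positives on flat noise at the default
  camera model while keeping full recall at the simulated SNR.
- *The z extent of the 11 × 11 box* is unstated (the box is described
  laterally); ±2 z-planes covers ±~2σ_z of the PSF at the 300 nm step.
- *The distance filter* value is unstated; 3 px ≈ 320 nm keeps a fitted
  site within the mRNA's diffraction volume.
- *Shape bounds* of 0.5–3× the calibration widths automate the "shape"
  filter.
- *The t-test variant* is unstated; Welch is the safer default and the
  pooled-variance form is available via `var_equal = TRUE`. Two-sided
  p values throughout; no multiple-testing correction is applied, so the
  pairwise p values are presented individually.
- *Cell inclusion*: the workflow is described in two places with bounds
  differing by one ("fewer than 35" vs "fewer than 36" mRNAs); the bound
  that accompanies the reported per-cell statistics (n ≤ 35 included) is
  implemented.
- *3D site integration*: whether site intensity was integrated over a 2D
  plane or the 3D volume is not stated; 3D is used so the site unit and
  the free-peptide unit are identical by construction.
- Association uses a closed threshold at exactly one peptide
  (`N >= 1` associated), matching the wording "less than one idealized
  single peptide" for unassociated sites.

## What the simulator emulates — and what it does not

`sample_ground_truth()` + `render_stack()` generate matched two-channel
stacks with the statistical structure the estimator assumes:

- Each mRNA is independently translating with probability
  `p_translating`; the four condition presets use 0.63, 0.03, 0.05 and
  0.50 (untreated, puromycin, emetine + puromycin, anisomycin +
  puromycin) — the reported mean per-cell colocalized fractions, so
  recovery of these values is a parameter-recovery test.
- Translating mRNAs carry `k = 1 + Poisson(4)` nascent chains. The
  ribosome load per translating mRNA is not reported anywhere we could
  anchor it; λ = 4 puts P(k = 1) at ~1.8%, so essentially every
  translating site sits above the one-peptide threshold and the
  estimator's target equals `p_translating`. This is a stand-in, not an
  inferred value.
- Free peptide count per cell is Poisson(20) — again a stand-in chosen so
  calibration always has candidates; intensities are log-normal around
  one single-peptide unit (CV 0.1).
- mRNA spot intensities are log-normal (CV 0.2) around 800 counts; no
  mRNA-channel intensity model is published.
- The PSF is Gaussian with σ_xy = 100 nm, σ_z = 350 nm (a 1.4 NA system
  at ~515 nm emission) on a 107.5 nm / 300 nm voxel grid; spots are
  *point-sampled* Gaussians, which at these widths differ from the
  continuous Gaussian integral by < 10⁻⁶ relative (Poisson summation), so
  renderer and fit model agree to well below every stated tolerance.
- Noise is Poisson shot noise on (signal + 50-count background) plus
  2-count Gaussian read noise; `gain = 0` disables shot noise for
  deterministic scenes.
- mRNA positions keep a 5 px minimum lateral spacing — overlapping
  translation sites are not disambiguated by the fitting procedure either
  way, so the simulator does not generate them.

Not emulated: optical aberrations, photobleaching, nuclear mRNAs, axially
varying cell shape, and touching cells. Passing tests therefore show that
the estimator chain is correct and unbiased *under its own assumptions*;
they do not certify performance on real images with dense spot fields,
aberrated PSFs, or autofluorescent structures.

## Numerical choices

- Coordinates are 1-based voxel indices in `(z, y, x)` order with spot
  centers in continuous voxel units at voxel centers — the R array
  convention.
- The detection threshold adds a relative guard of 10⁻⁹ of the filtered
  dynamic range, and the bandpass snaps responses below 10⁻¹⁰ of the
  input scale to zero; both exist purely so that exactly-flat noiseless
  regions (MAD = 0) never yield float-dust candidates.
- The calibration's median ± 3 MAD trim floors its band at a relative
  10⁻⁶ so near-identical noiseless fits are never trimmed on numeric
  dust.
- Equal-response plateau maxima are broken toward the lowest `(z, y, x)`
  index; duplicate fits converging onto one emitter (< 2 px lateral,
  < 1.5 plane axial) keep the brighter fit.
- Fit windows are clamped at stack edges; a fitted center that leaves the
  clamped window fails the spot.
- Per-cell seeds are a deterministic 31-bit hash of (master seed,
  condition name, cell index, stream), so the experiment is a pure
  function of configuration and master seed, and adding cells never
  perturbs existing ones.

## Problem sizes

The default experiment used by the analysis scripts and the acceptance
checks simulates 24 cells per condition on 11 × 256 × 256 voxel stacks
with 8–30 mRNAs per cell — the same order as the reported per-condition
cell and mRNA counts (20–27 cells, 313–513 mRNAs) — which keeps a full
four-condition run in the minutes range on one core. Unit scenes use
smaller stacks (≈ 9 × 64 × 64) since the estimators are windowed and
local.

## The diffusion calculator

The companion question — can a pulse of puromycin-family labeling
localize translation? — is answered by free-diffusion scaling,
$\langle x^2 \rangle = 2 n D t$. With the cytosolic GFP value
D = 126 µm²/s:

```{r diffusion}
rms_displacement(D = 126, n = 1, t = 60)   # ~123 um in one minute, 1D
time_to_reach(D = 126, n = 1, x = 100)     # under 40 s to cover 100 um
```

so a released protein crosses a cell-scale distance orders of magnitude
faster than any practical fixation protocol — the quantitative core of
the argument that released nascent chains cannot be assigned to their
site of synthesis.

## ROI quantification

For the germline metabolic-labeling comparison, `average_projection()`,
`roi_mean()` (pixel-center membership, even-odd rule; sub-pixel polygon
handling is a convention choice the original ImageJ workflow leaves
unspecified) and `normalize_to_control()` reproduce the
projection → ROI mean → control-normalization chain; no background
subtraction is applied before ROI measurement, as none is described.
ROIs are inputs — the mitotic-zone outlines were drawn by hand in the
original workflow and no automatic segmentation is attempted.

## Known limitations

- The estimator inherits a small positive bias in low-translation
  conditions: a free peptide that lands within the association distance
  of an mRNA is indistinguishable from a genuine one-chain site. At the
  default free-peptide density this contributes ~1–2 percentage points,
  visible in the puromycin conditions.
- Sites with exactly one nascent chain sit on the classification
  boundary; under shot noise about half of them fall below `N = 1`. With
  the default load law this affects < 2% of translating mRNAs.
- Calibration quality degrades in cells with few detectable free
  peptides; cells whose calibration fails (fewer than 5 usable spots)
  are reported as per-cell errors, not silently dropped.
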