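# nascentq

Quantification of translation sites in two-channel smFISH-IF images of
SunTag reporters, with a matched synthetic-image simulator for end-to-end
validation.

## The problem

In fixed cells expressing a SunTag translation reporter, single-molecule
FISH labels each reporter mRNA and immunofluorescence labels the nascent
SunTag epitopes. An mRNA bound by translating ribosomes appears as a red
focus coincident with a bright green focus; a released, fully
synthesized single SunTag peptide appears as a weak isolated green spot.
The per-cell **colocalized fraction** — the proportion of cytoplasmic
mRNAs whose protein-channel signal amounts to at least one single
peptide — measures translational engagement, and its change under
puromycin, emetine and anisomycin treatments reports on nascent-chain
release.

`nascentq` implements the whole measurement chain for users who want to
run, probe, or validate this analysis:

- **Simulation** — `sample_ground_truth()`, `render_stack()`,
  `generate_experiment()`: two-channel 3D stacks (107.5 nm x-y / 300 nm
  z voxels) with known per-mRNA translation states drawn from
  drug-condition presets (`condition_presets()`), free single peptides,
  a Gaussian PSF, and Poisson + read noise.
- **Detection** — `bandpass_filter()`, `detect_candidates()`,
  `fit_spot()`, `filter_spots()`, `detect_spots()`:
  Laplacian-of-Gaussian detection and 3D Gaussian fitting,
  `I = A (2π)^{3/2} σ_xy² σ_z`.
- **Quantification** — `select_free_peptides()`,
  `calibrate_single_peptide()`, `quantify_translation_site()`,
  `classify_association()`: the idealized single-peptide unit
  `I_single`, nascent-chain counts `N = I_ts / I_single`, association at
  `N ≥ 1`.
- **Statistics** — `cell_summary()` (6–35 mRNA inclusion filter),
  `condition_summary()` (mean ± SEM), `two_sample_ttest()` (Welch),
  `run_experiment()` for the full pipeline.
- **ROI quantification** — `average_projection()`, `roi_mean()`,
  `normalize_to_control()` for average-projection ROI measurements
  normalized to a control group.
- **Diffusion** — `rms_displacement()`, `time_to_reach()`,
  `displacement_curve()` for the `⟨x²⟩ = 2nDt` spatial-resolution
  argument.

## Worked example

One simulated untreated cell through the full chain
(`analysis/02_detect_quantify.R`):

```r
library(nascentq)
geom   <- default_cell_geometry()
gt     <- sample_ground_truth(condition_presets()$untreated, geom, 20, seed = 42)
stacks <- render_stack(gt, geom, seed = 43)
an     <- analyze_cell(stacks, experiment_config())
```

prints

```
Ground truth: 20 mRNAs (10 translating), 28 free peptides
Detected: 21 mRNA spots, 38 protein spots, 28 free peptides
Single-peptide unit: I_single = 785.7 counts (CV 0.17, n = 27)
Cell: 21 mRNAs, 10 associated, fraction 0.48 (truth 0.50)
```

All 28 released single peptides were found and calibrated into a
single-peptide unit within 2% of the generating value (800 counts); the
cell's colocalized fraction (0.48) recovers the ground-truth translating
fraction (0.50) up to one spurious mRNA detection. The diffusion
calculator (`analysis/05_diffusion.R`) prints the companion scale
argument:

```
1D RMS displacement after 60 s: 122.96 um
Time to reach 100 um (1D): 39.68 s
```

— a released protein outruns any labeling pulse by orders of magnitude.

The numbered scripts under `analysis/` run the complete study: `01`
writes a small on-disk demo dataset (TIFF + CSV + manifest), `02` the
walkthrough above, `03` the 24-cells-per-condition experiment with
per-cell dot plot and pairwise Welch tests, `04` the ROI quantification
demo, `05` the diffusion curves. Outputs land under `results/`.

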