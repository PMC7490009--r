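Package: nascentq
Title: Translation-Site Quantification for Single-Molecule FISH-IF Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and quantification pipeline for two-channel
    smFISH-IF (single-molecule RNA FISH plus immunofluorescence) imaging of
    SunTag translation reporters. Generates synthetic two-channel 3D stacks
    with known per-mRNA translation states, detects diffraction-limited
    spots by Laplacian-of-Gaussian filtering, fits them with 3D Gaussians,
    calibrates the integrated intensity of a single released SunTag
    polypeptide, counts nascent chains per mRNA by intensity normalization,
    and aggregates per-cell colocalized fractions across drug conditions.
    Also provides average-projection ROI quantification with normalization
    to a control group, and the mean-squared-displacement diffusion
    calculator used to reason about the spatial resolution of metabolic
    labeling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
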