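Package: perfusim
Title: Smeared-Field Finite-Element Modelling of Tumor Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-driven modelling of interstitial fluid pressure and
    perfusion velocity in growing solid tumors. Quantifies two-channel
    fluorescence sections (a CD31-like vascular stain and a Hoechst-like
    perfusion stain) into gridded heatmaps of vasculature coverage,
    capillary diameter and perfused area; maps the heatmaps to smeared
    (homogenised) capillary and extracellular transport parameters; and
    solves a two-domain Darcy finite-element pressure problem on a
    polar-meshed, time-evolving tumor geometry, with capillary-wall
    connectivity coupling, inverse-distance field transfer between
    meshes, and analytic screened-Poisson benchmarks. Includes a seeded
    synthetic-data generator (contours, heatmaps, pseudo-immunofluorescence
    images with rasterised ground truth) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    EBImage,
    tiff
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
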