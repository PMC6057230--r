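Package: visocm
Title: Visible-Light Optical Coherence Microscopy Simulation and Amyloid
    Plaque Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthetic spectral-domain optical coherence microscopy (OCM) of
    amyloid-plaque-bearing brain tissue, together with the full analysis
    chain needed to quantify the pathology: voxelized tissue phantoms with
    hyperscattering plaques, white-matter tracts, vessels and cell bodies;
    simulation of raw spectral interferograms with configurable sensitivity,
    roll-off and dispersion; reconstruction by k-space resampling, spectral
    shaping and Fourier transform; surface-referenced en-face projection and
    depth-resolved attenuation mapping; plaque segmentation, morphometry,
    plaque-load and contrast-to-noise analysis; synthetic DAB/hematoxylin
    histology with color deconvolution and stack registration; mosaic
    planning and stitching for millimetre-scale fields of view; and
    two-sample Kolmogorov-Smirnov group statistics with Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
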