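Package: mifish
Title: Simulation, Spot Detection and Combinatorial Decoding for Multi-Color DNA FISH
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing combinatorial multi-color DNA FISH (miFISH)
    experiments in which multiple chromosomal loci are visualized in a single
    hybridization round by spectral barcoding with dual- and single-color
    oligonucleotide probes. Provides a ground-truthed simulator of multi-channel
    3D image stacks and bead calibration fields, difference-of-Gaussians spot
    detection with two-stage maximum-likelihood Gaussian localization, chromatic
    aberration correction from bead fields, nuclei segmentation with G1 gating
    and normalized lamina distances, decoding of dual-color barcodes into
    per-homolog probe allocations, spline-based chromosome-trace geometry with
    curvature analysis, and validation against Hi-C contact matrices and A/B
    compartment calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
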