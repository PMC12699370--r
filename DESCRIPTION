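Package: curvassay
Title: Membrane Curvature, Deformability Cytometry and Densitometry for
    Curvature-Sensing Protein Assays
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative image-analysis pipeline for studies of
    curvature-sensing cytoskeletal proteins such as non-erythroid spectrin.
    Provides signed and smoothed curvature estimation along closed cell
    outlines, cell segmentation and sub-pixel boundary extraction from
    fluorescence micrographs, per-channel boundary intensity profiling,
    classification of protein-enriched boundary regions and comparison of
    their curvature distributions, deformation-index (DI = H/W) cytometry
    from cross-flow junction video frames, gel and lipid-strip densitometry
    with dilution-corrected binding ratios, closed-form design calculators
    for spherical supported lipid bilayer (SSLB) assays, and seeded
    synthetic phantom generators with analytic ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
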