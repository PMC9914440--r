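Package: sptnano
Title: Single-Particle Tracking and STORM Nanocluster Quantification for
    Membrane Transporter Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification stack for membrane-protein lateral diffusion and
    nanoscale clustering. Links frame-stamped quantum-dot localizations into
    trajectories, computes mean-squared-displacement curves, diffusion
    coefficients, explored areas, synaptic dwell times and compartment labels
    against marker masks; post-processes STORM localization streams (sliding
    window drift correction, repeated-detection merging, histogram rendering,
    density-threshold nanocluster segmentation); quantifies widefield punctate
    images (background flattening, cluster counting, surface/total and
    ratiometric readouts); and provides the matching statistical layer
    (control-median log normalization, Welch-t / Mann-Whitney selection, and a
    balanced Monte-Carlo Mann-Whitney procedure for clustered data). A seeded
    synthetic-data generator emulates the imaging data so every stage is
    verifiable without raw acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
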