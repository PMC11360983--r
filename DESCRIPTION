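Package: topoquant
Title: Topographic Index Quantification for Axon Terminals in 3D Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the fine-scale dorsoventral position of single-neuron
    axon terminals inside a reference neuropil from multi-channel 3D
    fluorescence stacks. Computes the per-voxel and per-clone Topographic
    Index TI = mean of di/(di+vi), performs ROI intensity-ratio
    quantifications (e.g. nuclear pMad normalized to Elav, GRASP normalized
    to presynaptic split-GFP expression), and runs one-way ANOVA with
    Fisher's LSD post hoc comparisons. Includes a ground-truth synthetic
    stack generator for end-to-end validation, minimal multi-page TIFF
    input/output, and a config-driven command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
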