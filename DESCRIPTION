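Package: spincolocal
Title: Object-Based Synaptic Puncta Colocalization and Spinal Nociception Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for multichannel immunofluorescence and
    multiplex in situ hybridization images of spinal dorsal horn tissue, and
    for the accompanying electrophysiological and behavioral readouts.
    Detects fluorescent puncta by thresholding and 8-connected labeling,
    applies physical-size filters, and performs object-based colocalization
    between two channels using morphological dilation and an overlap-fraction
    rule, reporting cluster densities per region of interest and
    percent-reduction group comparisons. Implements the RNAscope cell-calling
    rule (dot counting within an expanded nuclear area with a minimum-dot
    positivity threshold) and coexpression tabulation, Hill-equation
    concentration-response fitting with optional fixed-zero baseline and
    EC-fraction computation, and the percent-maximal-possible-effect
    statistic for withdrawal-threshold time series. A seeded synthetic-data
    generator produces ground-truth-carrying puncta fields, FISH fields,
    dose-response tables and behavioral cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
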