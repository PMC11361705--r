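Package: proxiquant
Title: Quantification of Streptavidin Versus Antibody Imaging and
    Proximity-Labelling Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify fluorescence imaging of biotin-ligase
    (TurboID) fusion proteins detected with streptavidin versus anti-tag
    antibodies, and the matching proximity-labelling proteomics workflow.
    Includes a ground-truthed synthetic-scene generator (spherical granules
    with volume or peripheral-shell labelling, nuclear-pore punctae,
    anisotropic Gaussian PSF, Poisson and read noise), sum/max z-projection,
    line-profile extraction with diameter at 50 percent fluorescence,
    diameter quotients and double-peak detection, maximum-signal fold-change
    statistics, an antibody-accessibility score with increment binning, and
    a label-free quantification (LFQ) enrichment pipeline (valid-value
    filter, log2 transform, downshifted-normal imputation, Student's t-test
    against an untagged control, increment binning, nuclear-pore component
    mapping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
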