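Package: cctopo
Title: Topography of the Corpus Callosum from Probabilistic Tractography
Version: 0.1.0
Authors@R: person("cctopo", "developers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for midsagittal corpus-callosum (CC) topography
    derived from probabilistic tractography streamline counts. Computes
    population-based probabilistic tractography maps by voxelwise
    normalization, multi-threshold binarization and averaging over sample
    units; parcels the CC into bilateral passage fields by left-right product
    thresholding with hole-free boundary tracing; quantifies left-right
    symmetry by voxelwise regression; and fits longitudinal linear
    mixed-effects models of field size and streamline density with
    Benjamini-Hochberg false discovery rate control. Includes a synthetic
    longitudinal cohort generator with known topographic, sex and age
    structure for validation, TSV/JSON/NIfTI input-output and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
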