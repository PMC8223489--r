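Package: hexpaint
Title: Quantification of Hexagonal Peptide Patterns on DNA Origami from
    DNA-PAINT Localization Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for DNA-PAINT single-molecule localization
    data of peptide-patterned DNA origami structures: quality filtering and
    redundant cross-correlation drift correction of localization tables,
    super-resolution rendering, detection of individual origami structures
    as regions of interest, per-structure calling of peptide docking sites
    via smoothed-image local maxima, and summary statistics (sites per
    structure, site occupancy, mean nearest-neighbor distances). Includes a
    registry of hexagonal pattern designs, a synthetic DNA-PAINT acquisition
    simulator with ground truth for benchmarking, and helpers for
    gel-dosimetry occupancy and luminescence viability arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
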