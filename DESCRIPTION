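Package: dropevo
Title: Droplet-Microfluidic Screening Analytics for Directed Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for droplet-microfluidic directed-evolution screens of
    cellulose-overproducing bacteria: Poisson single-cell encapsulation design,
    droplet micrograph quantification, fluorescence-activated droplet sorting
    (FADS) gate statistics, three-component Gaussian-mixture strain comparison,
    UV dose-survival and CFU serial-dilution assay math, and an end-to-end
    in-silico screening-campaign simulator with a fully parameterized
    synthetic-data generator for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
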