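Package: rohscan
Title: Genome Scan of Inbreeding Depression from Runs of Homozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from SNP-chip genotypes,
    estimates variance components and a genome-wide heterozygosity-depression
    covariate under a single-step repeatability animal model, and tests each
    shared ROH for a carrier versus non-carrier effect on litter size with a
    one-sided test. Includes a pedigree gene-dropping simulator that generates
    genotypes, ROH structure and repeated litter-size records with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
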