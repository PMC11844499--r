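Package: opscreen
Title: Optical Pooled Screen Image Analysis with In Situ Sequencing Decoding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of optical pooled CRISPR screens read out by
    in situ sequencing (ISS). Detects sequencing-by-synthesis (SBS) spots from
    cross-cycle intensity variance, registers imaging cycles by phase
    correlation of the DAPI channel, calls bases with a median-derived channel
    crosstalk correction, genotypes single cells by dominant-barcode codebook
    lookup, quantifies image phenotypes (mean immunofluorescence and integrated
    telomeric native-FISH spot intensity), matches cells across magnifications
    through stage coordinates with morphology verification, and compares
    per-sgRNA phenotype distributions against control cells with Mann-Whitney U
    tests and Bonferroni correction. Includes a synthetic-screen simulator with
    full ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CRISPR, PooledScreens, CellBasedAssays, Sequencing, Preprocessing
RoxygenNote: 7.3.3
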