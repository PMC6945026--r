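Package: repeatdepth
Title: Copy-Number Estimation for Large Tandem-Repeat Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and cross-method comparison of copy number for large
    tandem-repeat arrays such as ribosomal DNA (rDNA). Implements relative
    read-coverage estimation from whole-genome sequencing alignments with a
    maximum-likelihood GC-bias correction, droplet digital PCR Poisson
    quantification, single-molecule molecular inversion probe (smMIP) unique
    capture-event counting against a normalization plasmid, pulsed-field
    (CHEF) gel band-size conversion, and FISH spot-intensity quantification,
    together with replicate-error statistics for judging the methods and a
    fully deterministic synthetic-data generator so that every stage can be
    exercised offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    truncnorm,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
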