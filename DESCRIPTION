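Package: paralogr
Title: Gene/Pseudogene Disambiguation Toolkit for Short-Read Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for clinical variant detection in
    a gene whose 3' exons are nearly identical to a pseudogene (the PMS2/PMS2CL
    situation). Provides a synthetic paralog-locus and read simulator,
    permissive seed-and-extend realignment with paired-read rescue,
    distinguishing-base read partitioning, ploidy-aware (diploid and
    tetraploid) SNV/indel genotyping, read-depth HMM copy-number calling at
    baselines of two or four, CNV and tetraploid-indel sensitivity
    simulations, dosage-aware concordance statistics with Clopper-Pearson
    intervals, allelic-dropout QC, and the reflex-testing decision engine with
    beta-binomial reflex-rate extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
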