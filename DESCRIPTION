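Package: clonesucc
Title: Clonal Succession Analysis for Lentivirally Marked Serial Xenotransplants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing clonal dynamics of tumor-initiating cells
    tracked by lentiviral integration sites (IS) through serial
    xenotransplantation. Implements a Yule (linear birth) process model of
    clone growth with binomial seeding and subsampled detection; LAM-PCR
    integration-site table filtering (enzyme-replicate merging, relative
    abundance cutoff, cross-lineage collision removal); clonal succession
    statistics (generation exclusivity, detected-once fractions, dominance
    persistence, pairwise overlap); conservative confidence bounds on the
    number of engrafted clones and supremum p-value homogeneity tests over
    nuisance-parameter rectangles; and single-hit Poisson maximum-likelihood
    estimation of tumor-initiating cell frequency from limiting-dilution
    assays. A synthetic-data generator emulates the serial transplantation
    design under clonal-succession, fixed-hierarchy and stochastic scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
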