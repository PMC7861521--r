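Package: loadscore
Title: Per-Individual Deleterious Load Scores and Phenome-Wide Association Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-individual deleterious load scores: counts of
    derived alleles weighted by a per-site conservation score such as phyloP.
    Calibrates candidate deleteriousness scores (phyloP, GERP++, CADD,
    fitCons) against derived allele frequency spectra, computes weighted and
    unweighted load scores by genomic subset and by frequency/score strata,
    runs a phenome-wide association scan across continuous, ordinal, nominal,
    binary and phecode-style phenotypes with covariate adjustment and
    Bonferroni control, and tests for an excess of nominally significant
    associations against a permutation null. Includes a synthetic-data
    generator with known ground truth based on the stationary allele
    frequency distribution under purifying selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    nnet,
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
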