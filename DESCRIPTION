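Package: mirnorm
Title: Normalizer Selection and Quality Control for Circulating miRNA RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and normalization workflow for RT-qPCR profiling of
    circulating (blood plasma) microRNAs. Implements haemolysis detection from
    the miR-23a-3p/miR-451a delta-Cq rule and from absorbance spectra
    (oxyhaemoglobin band scoring), exogenous spike-in control evaluation with
    per-stratum z-scores, sex-stratified age adjustment, minus-delta-delta-Cq
    normalization, and the BestmiRNorm combinatorial algorithm that scores every
    non-empty subset of a candidate normalizer panel on three stability metrics
    (two-sample Kolmogorov-Smirnov distance, mean absolute deviation of group
    means from zero, mean of group standard deviations) with weighted rank
    aggregation. Also provides reference implementations of the geNorm,
    BestKeeper and NormFinder stability algorithms for benchmarking, and a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
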