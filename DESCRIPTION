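Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Validates candidate reference (housekeeping) genes for RT-qPCR
    normalization from quantification-cycle (Cq) data. Implements the geNorm
    pairwise-stability algorithm (M values, stepwise exclusion, normalization
    factors and the V(n/n+1) pairwise-variation criterion), the NormFinder
    model-based variance decomposition (intra- and inter-group variation with
    shrunken group effects), and a geometric-mean consensus ranking across the
    two methods. Includes quality-control filtering on RNA integrity (RQI) and
    absorbance ratios, technical-replicate aggregation, standard-curve fitting
    with amplification-efficiency estimation, transformation of Cq values to
    relative quantities, and a synthetic Cq-data generator that emulates a
    factorial plant growth study (tissue, inoculation, temperature, sampling
    week) with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
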