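Package: metaqtl
Title: Meta-QTL Analysis on Consensus Genetic Maps
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of quantitative trait loci (QTL)
    compiled from independent mapping studies. Builds consensus genetic
    map coordinates by anchor-marker interpolation, re-estimates QTL
    confidence intervals with the Darvasi-Soller population-size rule,
    projects QTL onto the consensus map, and detects meta-QTL per
    chromosome either by an EM-fitted Gaussian mixture with known
    per-QTL variances and multi-criterion model selection (AIC, AICc,
    AIC3, BIC, AWE) or, on sparse chromosomes, by exact dynamic
    programming over contiguous clusters. Includes physical anchoring of
    meta-QTL intervals, gene extraction from GFF3 annotations,
    class-distinguishing variant detection in multiple alignments,
    marker-trait validation statistics, and a synthetic-data generator
    emulating multi-study grain-weight QTL compilations in rice.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
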