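Package: ribostall
Title: Codon-Resolution Analysis of Ribosome Stalling from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for codon-resolution analysis of ribosome profiling
    footprint data under amino-acid limitation: per-codon ribosome
    dwell-time estimation with a Poisson log-linear site model, positional
    density metrics (metagene profiles, 5'/3' ramp indices, polarity
    scores), stall-site peak calling with codon-context and enrichment
    analyses, genome-wide codon usage and positional codon-bias tables, a
    first-order protein-turnover kinetic model linking stalling to
    proteome fold changes, and auxiliary assay analytics (polysome
    profiles, tRNA-charging and delta-delta-Ct qPCR). Includes a
    fully-specified synthetic-data generator with planted ground truth for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
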