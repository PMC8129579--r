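Package: patternseq
Title: Function-Based Temporal Pattern Analysis of Staged RNA-Seq Time Courses
Version: 0.1.0
Authors@R: person("patternseq", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Selects differentially expressed genes in multi-stage expression
    time courses against a designated progenitor baseline using a bounded-area
    statistic with a log-normal null fitted from biological-replicate
    variability, clusters seed and candidate genes annotated to the same
    functional term into Temporal Patterns with leaf-first redundancy
    reduction over a term hierarchy, assigns time breaks with a
    20-percent-of-pattern-mean rule, summarizes Temporal Patterns into signed
    Main Patterns, and tests stage-grouped category enrichment with one-sided
    Fisher tests under Benjamini-Hochberg FDR control. Ships a synthetic-data
    generator with planted temporal ground truth so the whole pipeline is
    testable end to end, plus TSV/GMT readers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
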