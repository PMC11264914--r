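Package: ruleout16S
Title: Species-Level Rule-Out Probabilities for 16S rRNA Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes, for each 16S rRNA amplicon read and each candidate
    bacterial species, the probability that the read could not have arisen
    from that species' type strain. Observed mismatches in the sequenced
    region are extrapolated to the full-length gene with a beta-binomial
    model under a Jeffreys prior, and a hard (97.5 percent gene identity)
    or soft (exponential curve with half-maximum at 99.1 percent identity)
    species criterion converts the full-gene mismatch distribution into a
    rule-out probability. Includes semi-global alignment of reads against
    a type-strain reference database, primer-based variable-region
    extraction, detection of species indistinguishable within a region,
    and a synthetic-data generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
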