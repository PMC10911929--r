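Package: coamplikon
Title: Passenger-Gene Coamplification Calling and Collateral Dependency Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate "collateral lethal" vulnerabilities created by
    passenger-gene coamplification in cancer genomes. Calls high-level
    amplifications and homozygous deletions from copy-number segment files with
    platform-specific log2-ratio cutoffs, lifts calls to genes, merges amplified
    segments into amplicons and splits their members into oncogenes and
    passengers; summarises coamplification frequency and passenger load across a
    cohort; stratifies CRISPR-screened cell lines by coamplification status and
    screens every gene for differential dependency with a Wilcoxon rank-sum
    test; and provides correlation, over-representation and preranked
    enrichment analyses, disorder-region nomination, and a fully seeded
    synthetic cohort generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
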