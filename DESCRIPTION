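Package: spliceprof
Title: Junction-Level Profiling of Alternative and Aberrant Splicing from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the junction-level description of a gene's alternative
    splicing profile from RNA-seq splice-junction counts, aimed at diagnostic
    interpretation of splicing variants. Junctions observed in each sample are
    typed against a reference transcript model (exon skipping, exonic or
    intronic splice-site shifts, partial intron retention, alternative first
    exons), named with a compact delta/triangle shorthand and an HGVS-style
    RNA change string, quantified as a percentage of the physiological
    counterpart junction, and filtered and tiered by read support and
    alignment overhang. Additional components predict coding consequences
    (frame, premature termination, nonsense-mediated decay candidacy),
    enumerate the transcripts generated by a tandem direct multi-exon
    duplication with independently spliced internal events, compare a variant
    carrier's junction profile against a control cohort to produce structured
    splicing evidence, and simulate junction-count cohorts with a packaged
    CDH1-like event profile for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
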