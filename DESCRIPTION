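Package: tcrtrace
Title: Chain-Pattern Classification and Rearrangement Traceability for
    Single-Cell TCR Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and per-cell classification of single-cell
    T-cell receptor (TCR) V(D)J contig tables (10x Cell Ranger and AIRR
    Rearrangement dialects). Calls each chain functional or
    non-functional, collapses contigs into per-cell chain profiles,
    assigns each cell one of 23 chain-pattern categories and a
    single/multiple/abnormal TCR status, and produces per-sample and
    per-group summaries with the standard two-group and multi-group
    hypothesis tests. Embeds ordinal topology models of the human and
    mouse TRA and TRB loci (gene order, transcriptional orientation,
    D-J-C cluster membership, recombination-signal-sequence spacer
    classes) and uses them to decide which same-chromosome mechanisms
    (transcription from a T-cell receptor excision circle, or
    inversional recombination of the reverse-oriented TRBV30/TRBV31
    segment) can explain cells carrying multiple same-locus
    rearrangements, with a brute-force excision simulator as the
    correctness reference. Includes a synthetic contig-table generator
    with truth labels for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    car
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
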