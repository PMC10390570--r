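# tcrtrace

Chain-pattern classification and rearrangement traceability for
single-cell TCR repertoires.

## What problem this solves

Single-cell V(D)J sequencing returns, per cell barcode, assembled contigs
of T-cell receptor alpha (TRA) and beta (TRB) chains. Under strict allelic
exclusion each T cell expresses one functional β and one functional α
chain — but real data contain many cells with zero, or with two or more,
functional chains per locus (allelic-inclusion / dual-TCR cells), plus
abundant chains that cannot pair at all. Treating all of these as ordinary
clonotypes distorts repertoire analyses. `tcrtrace` is for immunologists
and computational biologists working with 10x-style or AIRR-format scTCR
data who need to:

* QC contig tables with four fixed screens (`is_cell`, `high_confidence`,
  chain ∈ {TRA, TRB}, `productive` ≠ None);
* call every chain **functional (F)** — productive *and* using a
  functional (non-pseudogene, non-ORF) V segment — or **non-functional
  (N)**, and collapse contigs to distinct per-cell chains at
  V(D)JC + CDR3 resolution;
* label each cell with one of **23 chain-pattern categories** (4
  single-chain, 10 two-chain, 8 same-locus three-chain, plus "others") and
  a **TCR status**: *abnormal* (no β(F)+α(F) pair possible), *single*
  (exactly one β(F) and one α(F)), or *multiple* (≥3 functional chains
  spanning both loci);
* summarize samples and groups (group averages are unweighted means of
  per-sample percentages) and run the standard test battery (two-tailed t
  / one-way ANOVA / Mann–Whitney / Kruskal–Wallis, dispatched by
  Shapiro–Wilk and Levene screens);
* decide, for cells with several **same-locus** rearrangements, which
  same-chromosome mechanisms could explain them: transcription from a
  T-cell receptor excision circle (TREC) created by a second rearrangement
  on the same chromosome, or inversional recombination of the
  reverse-oriented V (human TRBV30 / mouse TRBV31) — checked by rules over
  an ordinal model of the TR loci (gene order, orientation, D–J–C
  clusters, 12/23 RSS classes) and verified against a brute-force excision
  simulator.

A synthetic contig-table generator with per-cell truth labels
(`generate_sample()`) supports end-to-end parameter-recovery testing, and
`simulate_rearrangement_process()` reproduces the sequential biallelic
rearrangement arithmetic (first-attempt productive fraction 1/3,
second-attempt (1 − 1/3) × 1/3 = 2/9 at p = 1/3).

## Worked example

```r
library(tcrtrace)

# a synthetic 1000-cell sample with planted TREC-beta cells and QC noise
cfg <- synth_config(1000, seed = 42,
                    mechanism_plant_rates = c(trec_circle_beta = 0.05),
                    qc_noise = c(not_cell = 0.02, low_confidence = 0.01,
                                 wrong_chain = 0.02, productive_none = 0.03))
g <- generate_sample(cfg, "sample1.csv")

rec <- read_contig_table("sample1.csv", "tenx_csv")
qc  <- apply_qc_filters(rec)
qc$report
#> Contig QC report
#>   input: 2082  kept: 2002
#>   dropped not_cell:        20
#>   dropped low_confidence:  10
#>   dropped wrong_chain:     20
#>   dropped productive_none: 30

profiles <- build_cell_profiles(qc$kept, species = "human")
head(classify_cells(profiles)[, 1:5], 3)
#>        barcode pattern_code  pattern_name chain_group   status
#> 1 CELL000001-1            5 TRB(F)+TRB(F)         two abnormal
#> 2 CELL000002-1            8 TRA(F)+TRA(F)         two abnormal
#> 3 CELL000003-1           11 TRB(F)+TRA(F)         two   single

summarize_sample(profiles, "sample1")
#> <sample_summary> sample1: 1000 cells, 2002 unique chains, 53.400% functional (single/multiple 83.708/16.292)
```

53.400% of cells can assemble a functional receptor; among those, 16.292%
could assemble more than one (the generator planted 5% TREC-β cells, and
the default pattern mixture contributes further multi-functional cells).
Tracing the multi-rearrangement cells recovers the planted mechanism with
role assignment — which join sits on the excised circle and which on the
chromosome:

```r
tr <- trace_sample(profiles, "human")
tr[tr$mechanism %in% "trec_circle_beta", ][1:2, c("barcode", "mechanism",
                                                  "circle_event", "chromosome_event")]
#>        barcode        mechanism               circle_event           chromosome_event
#> 7  CELL000017-1 trec_circle_beta TRBV13-TRBD1-TRBJ1-5-TRBC1  TRBV2-TRBD2-TRBJ2-1-TRBC2
#> 10 CELL000023-1 trec_circle_beta TRBV19-TRBD1-TRBJ1-6-TRBC1 TRBV7-6-TRBD2-TRBJ2-4-TRBC2
```

Both calls are consistent with the TREC mechanism: the circle-resident
join uses the upstream DJC1 cluster and a 3′ V, the chromosome-resident
join the downstream DJC2 cluster and a 5′ V.

Cohort aggregation works on cell-level data or directly on per-sample
percentages; the packaged `table1_samples.tsv` carries published
per-sample values:

```r
tab <- read.delim(system.file("extdata", "table1_samples.tsv", package = "tcrtrace"))
aggregate_group(tab[tab$group == "thymus_total", ], "thymus_total")
#> <group_summary> thymus_total (5 samples): functional 49.407%, single/multiple 80.070/19.930

compare_groups(list(old   = tab$pct_multiple[tab$group == "old"],
                    young = tab$pct_multiple[tab$group == "young"],
                    frail = tab$pct_multiple[tab$group == "frail"]))
#> <test_result> anova_one_way: statistic = 12.82, p = 0.001737 [**]
```

The three human peripheral-blood groups differ significantly in their
multiple-TCR percentage, the old group being highest (13.668 on average).

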