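---
title: "Chain-pattern classification and rearrangement traceability of single-cell TCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain-pattern classification and rearrangement traceability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrtrace)
```

## The problem

Single-cell V(D)J sequencing recovers, per cell barcode, the assembled
transcripts ("contigs") of T-cell receptor alpha (TRA) and beta (TRB)
chains. Under strict allelic exclusion every T cell should express one
functional beta and one functional alpha chain; in practice a sizeable
fraction of cells shows zero, or more than one, functional chain per locus.
`tcrtrace` provides a reproducible pipeline for (i) quality-controlling
contig tables, (ii) classifying each cell by its chain pattern and its
ability to assemble a functional receptor, (iii) summarizing cohorts, and
(iv) asking, for cells that carry several rearrangements of the *same*
locus, which physical mechanisms could have produced them from at most two
chromosomes.

## Quality control

Four screens are applied to every contig row, in a fixed order that also
fixes the attribution of multi-failure rows: `is_cell` not true;
`high_confidence` not true; chain outside \{TRA, TRB\}; `productive`
neither true nor false (e.g. `None`). Flag literals are compared
case-insensitively (`T`/`F` from AIRR files are accepted); a flag column
absent from the input dialect passes its criterion, because one cannot
screen on an absent field, while an unrecognized literal fails it — the
conservative reading when the input is malformed. TRD/TRG and multi-locus
calls are `wrong_chain`: the analysis concerns alpha/beta T cells only.

## Functional and non-functional chains

A chain is **functional (F)** only when its contig is annotated productive
*and* its V segment is a functional gene in the packaged locus tables.
IMGT-style ORF-class segments are counted as non-functional, a conservative
choice: an ORF V may rearrange and transcribe but is not expected to yield
a working receptor, and counting it functional would inflate dual-TCR
calls. Chains that pass QC but lack a V or J call are retained as **N** —
they still occupy a chain slot for pattern counting — with a warning.

Contigs within a barcode are deduplicated at full V(D)JC-plus-junction
resolution: two chains count as different types iff the tuple
(locus, V, D, J, C, CDR3 amino-acid junction) differs. Junction inclusion
prevents conflating independent rearrangements that happen to reuse the
same segments; when duplicates differ in UMI count the better-supported
contig is kept.

## The 23 pattern categories and TCR status

Each cell is labelled by the multiset of its distinct chains over
(locus × status): four single-chain categories, ten two-chain categories,
eight same-locus three-chain categories, and a final **others** category
(code 23). "Others" absorbs every mixed three-chain combination (for
example TRB(F)+TRA(F)+TRA(N)) and all cells with four or more distinct
chains: the explicit three-chain list covers only same-locus triples, so
mixed triples — which certainly occur — must fall through. The same
convention is applied to same-locus four-chain cells. This matters when
comparing pattern tables across studies and is therefore stated
prominently here.

TCR status partitions cells by their pairing potential:

* **abnormal** — no TRB(F) or no TRA(F): nothing can pair;
* **single** — exactly one TRB(F) and one TRA(F), regardless of extra
  non-functional chains;
* **multiple** — both loci contribute a functional chain and at least
  three functional chains are present, so more than one functional
  receptor could be assembled.

A cell with three TRB(F) and no TRA(F) is *abnormal*, not multiple: the
definitions are about assemblable beta+alpha pairs. `is_functional_cell()`
is exactly `status != "abnormal"`. Cells whose every contig was dropped at
QC never reach classification and are excluded from all denominators.

```{r patterns}
head(pattern_labels(), 4)
assign_pattern(new_cell_profile("demo", data.frame(
  locus = c("TRB", "TRA"), v_call = c("TRBV19", "TRAV14"), d_call = "",
  j_call = c("TRBJ1-5", "TRAJ33"), c_call = "", junction_aa = c("CA1F", "CA2F"),
  status = c("F", "F"))))
```

## Cohort summaries and tests

Per-sample summaries report cell counts, distinct chain identity keys
("unique sequences" — defined here as distinct (locus, V, D, J, C,
junction) tuples among kept contigs, an explicit operational choice since
the quantity is rarely defined in published tables), the percentage of
cells able to assemble a receptor, and the single/multiple split *among
functional cells*. Group rows are **unweighted arithmetic means of the
member samples' percentages**, not pooled-cell ratios — this is forced by
how cohort "Average" rows are conventionally computed, and the packaged
`table1_samples.tsv` fixture reproduces a published table's averages to
three decimals under exactly this rule. Reported percentages use half-up
rounding to 3 decimals (`round_half_up()`), matching spreadsheet/SPSS
output; base R's round-half-even would differ on exact ties.

`compare_groups()` dispatches the standard battery: two-tailed t test for
two normal groups (Student when Levene's test with mean centring accepts
equal variances, Welch otherwise), one-way ANOVA for three or more normal
homoscedastic groups, and Mann–Whitney / Kruskal–Wallis otherwise.
Normality is screened per group by Shapiro–Wilk at α = 0.05; the screens
are standard choices, stated here because the dispatch rule alone does not
pin them down. Groups with fewer than three observations cannot be
Shapiro-tested and are dispatched to the non-parametric branch, except for
the degenerate all-identical case, which is allowed through so that
identical samples give the expected t = 0, p = 1. Labels: `*` p < 0.05,
`**` p < 0.01.

## The locus model

`load_locus()` returns ordinal topology models of human and mouse TRA and
TRB: gene order, transcriptional orientation, TRB D–J–C cluster membership
(TRBD1–TRBJ1.x–TRBC1 and TRBD2–TRBJ2.x–TRBC2), RSS spacer classes
(Vβ 23 | Dβ 5′12/3′23 | Jβ 12; Vα 23 | Jα 12), and functionality. Ordinals,
not coordinates, are stored: every mechanism argument below needs only
relative order, and ordinals avoid genome-assembly coupling. Gene order
follows IMGT locus representations; the human tables are near-complete at
gene level, the mouse V sets are simplified to representative family
members (sufficient because all downstream logic is order- and
orientation-based, and the synthetic generator draws from these same
tables). The TRA model lists TRAV/DV dual-name genes under their TRAV
alias and ignores the embedded TRD cluster. Jα ordinals follow genomic
order — TRAJ61 is the most 5′, TRAJ1 the most 3′ — so numeric gene names
invert positional intuition. Gene calls are normalized by stripping allele
suffixes and resolving ambiguous multi-gene calls to the 5′-most member
(with a warning).

Each TRB locus carries exactly one V segment in reverse transcriptional
orientation 3′ of both clusters: human TRBV30, mouse TRBV31.

## Same-chromosome mechanisms for multiple rearrangements

A cell with three or more distinct same-locus rearrangements cannot be
explained by two chromosomes carrying one rearrangement each. Two
mechanisms can put a second *transcribable* V(D)J join on one chromosome:

1. **TREC-circle transcription.** A first, complete rearrangement is
   excised onto a T-cell receptor excision circle by a second rearrangement
   on the same chromosome whose V lies 5′ of the first V and (for TRB)
   whose D–J–C cluster is the downstream one; the circle retains the first
   join intact and can be transcribed. `trb_trec_compatible(a, b)` is true
   when `a` (DJC1, downstream V) can be the circle-resident join excised by
   `b` (DJC2, upstream V); `tra_trec_compatible` requires `b`'s V–J
   interval to nest `a`'s join (V 5′ of `a`'s V, J 3′ of `a`'s J).
2. **Inversional recombination.** The reverse-orientation V joins by
   inverting, not deleting, the intervening DNA, so both joins persist on
   the chromosome. Feasibility requires the reverse-V event to use DJC2 and
   the forward-V partner DJC1. The cluster assignment is this package's
   choice, validated against the excision oracle rather than taken from any
   published figure: simulation shows the other assignments are physically
   impossible (a forward V joining DJC2 deletes DJC1; an inversion onto
   DJC1 flips DJC2 out of joining orientation).

Role assignment (which event is circle-resident) is inferred purely from
positional feasibility — transcripts carry no timestamps — and both
assignments are reported when both are feasible. Non-functional chains
participate identically to functional ones.

### The brute-force excision oracle

`brute_force_excision_oracle()` is the correctness reference for the rule
set: it simulates the locus as its ordinal segment sequence, applies each
rearrangement in a scheme's chronological order on its assigned chromosome
(deletional joins excise the open interval onto a tracked circle,
inversional joins invert it in place), enforces that each physical segment
joins at most once, and accepts iff every event's complete join ends up on
a final chromosome or intact on a circle. One modelling choice: segments
carried into an inverted interval are marked orientation-flipped and take
no further part in joining (a single-inversion model; nested rearrangement
of inverted DNA is not represented). The test suite proves the rules and
the oracle equivalent exhaustively on a reduced toy locus (4 V including
one reverse, 2 clusters × 2 J) and on ≥500 random event pairs per species
on the packaged maps.

`classify_cell_mechanism()` assembles per-cell verdicts: with two
same-locus events `two_chromosomes` is always additionally feasible; with
three, a cover needs one compatible pair plus a singleton; with four, two
disjoint compatible pairs; five or more distinct same-locus events cannot
be covered by two chromosomes under the supported mechanisms and are
`unexplained` — as is any cell where no pairing scheme works.

## The synthetic-data generator

`generate_sample()` emulates a 10x-style contig table: per-cell chain
multisets drawn from configured 23-pattern weights, V/(D)/J/C drawn
uniformly from the locus tables with cluster-consistent TRB D/J/C,
non-functional chains realized either as non-productive contigs or as
productive contigs with pseudogene/ORF V (an even split), random CDR3
junctions of 8–20 amino acids (purely to make identity keys distinct — no
biological junction model), planted mechanism cells whose event pairs are
verified against the excision oracle at generation time, and QC-failing
noise rows that reuse real barcodes. The default pattern weights are a
qualitatively thymus-like mixture — about half of the cells can pair a
functional beta with a functional alpha, single-chain dropouts are common,
three-plus-chain cells are a small minority — chosen once as realistic
study conditions; no published per-pattern frequency table exists to copy.

What the generator does **not** emulate: skewed V/J gene usage (a usage
table hook exists, but no estimates are shipped), transcript/UMI depth,
doublets, ambient contamination, or barcode errors. Passing recovery tests
therefore demonstrates correctness of the classification and traceability
logic under clean, known-truth conditions — not robustness to every
artefact of real libraries.

`simulate_rearrangement_process()` models the sequential biallelic attempt
process: with per-attempt success probability p = 1/3, a fraction 1/3 of
cells is productive on the first attempt and (1 − 1/3) × 1/3 = 2/9 on the
second; the simulator reproduces both at n = 100 000 within three standard
errors.

## Numerical and design choices, problem sizes

* Percentages: half-up rounding, 3 decimals; undefined splits (no
  functional cells) are reported as `NA`, never as 0.
* Frequency-recovery tests compare observed pattern frequencies to
  configured weights with simultaneous (Bonferroni-adjusted across the 23
  categories) binomial 95% bounds at n = 5000 cells.
* Planted-mechanism recovery is checked at n = 2000 cells with plant rates
  10% / 5% / 2% (TREC-β / TREC-α / inversion); recovery is ≥99% by
  construction, and the chance same-chromosome compatibility rate among
  unplanted multi-chain cells is measured and reported by the test.
* Determinism: a configuration (including seed) fully determines generator
  output and pipeline bundles, byte for byte.

## Limitations

* The functional-V table treats ORF segments as non-functional; studies
  counting ORF as functional will report slightly higher F tallies.
* Mouse locus tables are family-representative, not exhaustive; real mouse
  data with uncommon V genes may need table extension before traceability.
* Mechanism calls are *feasibility* statements about locus topology, not
  probabilistic inferences; no population frequency of each mechanism is
  estimated.
* The "unique sequences" column is defined operationally here and may not
  match other tools' definitions (reads, contigs, or clonotypes).
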