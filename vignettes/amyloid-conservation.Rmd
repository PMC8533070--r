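---
title: "Methods: scoring, calling and measuring conserved amyloidogenicity"
author: "amylofam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, calling and measuring conserved amyloidogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylofam)
```

## The question and the model

Many amyloid-forming proteins — among them barrier nucleoporins with
large intrinsically disordered, FG-repeat-rich domains — raise the same
evolutionary question: is the ability to aggregate an accident of one
sequence, or a property the family has kept? This package operationalizes
that question as a pipeline over an ortholog family:

1. **Per-residue scoring.** Two tracks per sequence, both in $[0,1]$:
   a *beta-arch cumulative score* (the propensity of each residue to sit
   inside a strand–loop–strand motif of the kind found in amyloid
   fibrils) and a *disorder score*. Tracks normally come from external
   predictors through a generic `seq_id / position / score` TSV carrier
   (`read_score_table()`); the package also ships simplified stand-in
   scorers (below) so everything runs self-contained.
2. **Region calling.** A residue is *disordered* when its disorder score
   is strictly greater than the cutoff (default 0.3 — the strict
   comparison is deliberate and tested). An *arch region* is a maximal
   run of residues with cumulative score $\ge$ the arch threshold
   (default 0.575; inclusive, so a score exactly at the published tool
   threshold qualifies). An arch region is *amyloidogenic* when at least
   half of its residues (configurable `overlap_fraction`) lie inside
   disordered segments — our quantification of "an arch located in an
   unstructured region", which the underlying rule leaves unquantified.
   A protein is a *potential amyloid* iff it has at least one
   amyloidogenic region.
3. **Curation.** Before column statistics, the ortholog set is filtered
   in a fixed order: manual exclusion list, one sequence per species
   (longest; ties to the smallest id), removal of short C-terminal-only
   fragments, removal of over-long outliers.
4. **Projection and the conservation profile.** Amyloidogenic calls are
   projected through gap-aware residue-to-column maps onto the multiple
   alignment. For column $c$,
   $$\mathrm{af}(c) \;=\; \frac{\#\{\text{rows with a residue at } c
   \text{ inside an amyloidogenic region}\}}{\#\{\text{rows with a
   residue at } c\}},$$
   i.e. the fraction of sequences in which the amino acid at that
   position belongs to an amyloidogenic region. The denominator counts
   only non-gap rows: "the amino acid at that position" presupposes the
   sequence has one there. Columns whose gap fraction exceeds
   `gap_mask_fraction` (default 0.5) are masked out of all downstream
   statistics — "a lot of gaps" is not quantified by the source
   convention, so the majority rule is ours and configurable.
5. **Conserved regions and the contrast.** Conserved amyloidogenic
   regions are maximal runs of at least `min_conserved_run` (default 5)
   unmasked columns with $\mathrm{af}(c) \ge$ `conservation_threshold`
   (default 0.7). For each such region `conservation_contrast()` reports
   the mean amyloid fraction, the mean per-column residue identity
   (frequency of the modal residue among non-gap rows), and their
   difference; a positive difference means aggregation propensity is
   conserved more strongly than the sequence itself.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `arch_threshold` | 0.575 | score | published arch-predictor operating point; `>=` |
| `disorder_cutoff` | 0.3 | score | published disorder convention; strictly `>` |
| `overlap_fraction` | 0.5 | fraction of arch residues | neutral majority rule for "located in"; 0⁺ = any overlap, 1 = containment, both tested |
| `gap_mask_fraction` | 0.5 | fraction of rows | majority rule for "gap-dominated column" |
| `conservation_threshold` | 0.7 | fraction of sequences | "present in almost all sequences" needs a number; 0.7 of curated rows |
| `min_conserved_run` | 5 | columns | suppresses single-column flickers; ~minimum strand length |
| `length_outlier_ratio` | 1.5 | × median length | "significantly longer" quantified robustly via the median |
| `fragment_min_fraction` | 0.5 | × median length | "short" quantified as below half the median |

The last four rows are package conventions for criteria that the
underlying methodology describes only qualitatively; each is exposed in
`analysis_config()` and echoed in every run manifest. Raising any
threshold can only shrink the corresponding called set — a monotonicity
property the test suite checks on random inputs.

## The stand-in scorers

Faithful reimplementation of the external arch and disorder predictors
is out of scope; the bundled scorers exist so the pipeline, tests and
simulations run with no external binaries, and every track they produce
is labelled `standin_simplified`. `scan_arches()` enumerates all
strand–loop–strand placements (strands 4–9 residues, loops 1–15), scores
a candidate as the mean of a bundled, clearly-synthetic beta-aggregation
propensity scale over both strands minus 0.5 per strand proline, and
maps it through a logistic `plogis((raw - 0.5)/0.1)`. The constants are
fixed once by a calibration contract: poly-Q and poly-N 30-mers must
exceed the 0.575 threshold while poly-P and poly-E 30-mers stay below
0.2. The per-residue *cumulative* reduction is the **maximum** normalized
score over all covering candidates — the source material never defines
its reduction, and max preserves "at least one arch" semantics (this
choice is recorded in track provenance). `disorder_track()` is a
windowed mean (window 21) of a synthetic disorder scale, min–max
rescaled per sequence so the 0.3 cutoff stays meaningful for an
arbitrary scale; a compositionally constant sequence degenerates to 0.5
everywhere.

## What the simulator emulates — and what it does not

`simulate_family()` generates the package's reference study conditions:
a 600-residue ancestor drawn from a disorder-biased background
(G/S/Q/N/E/K/P-rich with FG dipeptides every 25 residues, echoing a
barrier-nucleoporin-like composition), two implanted aggregation-prone
motifs (Q/N/hydrophobic-rich) at positions 150 (length 60) — the
geometry of a main mid-protein amyloidogenic region — and 320 (length
40); 20 independent descendants (star phylogeny) with per-site
substitution probabilities 0.3 outside and 0.1 inside motifs (motif
substitutions stay within the aggregation-prone class) and indel events
at rate 0.02 per non-motif site (lengths 1–5). The true alignment is
built from recorded residue homology to ancestral coordinates, so
column-level ground truth is exact.

Three kinds of curation targets are appended with known labels: two
same-species duplicates (trimmed by 80 C-terminal ancestral positions,
comfortably more than the ~15-residue standard deviation of indel length
jitter, so the primary is always the longest of its species), one
C-terminal fragment (the last third of a fresh descendant), and one
over-long outlier. The outlier carries its extra ancestor-length of
background sequence as an *internal* insertion after ancestral position
50 rather than a C-terminal tail: an appended tail would place its
insert columns at the alignment end and shift the column midpoint used
by the C-terminal-fragment rule, whereas an internal, isoform-like
insertion leaves the fragment geometry intact. Indels are forbidden
inside motifs so truth regions stay contiguous — a documented simulator
simplification.

`simulate_tracks()` replaces the predictors on synthetic data: arch
scores 0.8 inside true regions and 0.3 outside, disorder 0.6 everywhere
except an ordered N-terminal 50-residue stub at 0.2, plus Gaussian noise
(sd 0.1), clipped to $[0,1]$.

What passing on these families shows: the interval algebra, coordinate
projection, curation rules and conservation statistics are correct, and
the pipeline recovers implanted signal under realistic noise and 30%
background divergence. What it does not show: anything about the
accuracy of real arch/disorder predictors, about alignment quality
(true alignments are used; real MSAs have errors precisely in the
low-complexity regions at issue), or about tree-structured phylogenetic
correlation, which a star phylogeny ignores (real families would need
fewer effective independent sequences than the row count suggests).

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere inside the package; BED
  export converts to 0-based half-open, and the conversion round-trips
  exactly (scores survive to 1/1000 granularity, the BED score scale).
* All-gap columns get amyloid fraction 0 and identity 0, and are always
  masked (gap fraction 1).
* Region sets are kept sorted and disjoint at every stage; ties in the
  arch candidate ordering break by start, then span length.
* Score tables are validated, not repaired: non-contiguous positions or
  scores outside $[0,1]$ are errors.
* Sequences too short to host any arch placement yield an empty
  candidate set, not an error; `is_potential_amyloid()` is then `FALSE`.
* Curation of fewer than 3 sequences skips the outlier rule with a
  warning rather than trusting a 2-point median. The outlier median is
  computed once, before any drop: re-computing it after each removal
  would make the filter order-dependent and, on contrived length sets,
  non-idempotent.
* Every source of randomness (simulation, track noise) flows through an
  explicit integer seed; two runs with the same seed are byte-identical,
  which the test suite asserts on the full output tree.

## Problem sizes

The package's reference checks run the full pipeline over 20 seeds at
the default family size (20 primaries + 4 curation targets, 600-residue
ancestor, ~1500 alignment columns), which takes well under a minute on
one core; oracle-equivalence checks use 100 random instances of length
up to 200 (tracks) and up to 20×200 (alignments). These sizes were
chosen to exercise every code path at a scale where brute-force oracles
remain exact and fast.

## Known limitations

* The stand-in scorers are calibrated toys; real analyses should feed
  external predictor output through `read_score_table()`.
* `run_pipeline()` projects calls onto the *supplied* alignment after
  curation (dropping rows); the canonical protocol realigns the curated
  set first, which requires an external aligner and is left to the
  caller.
* The identity baseline is modal-residue frequency; a similarity-matrix
  weighted identity would be less brittle to conservative substitutions
  but requires choosing a matrix, so plain identity is the default and
  the contrast should be read accordingly.
* Per-protein region BEDs are written as one combined BED file keyed by
  the sequence id column.
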