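---
title: "Benchmarking membrane-helix predictions: metrics, reconciliation and fixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking membrane-helix predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbench)
```

## The problem

Roughly a fifth to a third of the proteins coded by a genome are helical
membrane proteins, yet they account for only a small fraction of solved 3D
structures. Sequence-based predictors therefore carry much of the burden of
annotating them, and they are judged on two distinct questions:

* **topography** — where along the amino-acid sequence do the membrane
  helices sit?
* **topology** — on which side of the membrane do the N-terminus and the
  loops between helices lie? (`o` denotes the extracellular face, `i` the
  other side.)

`tmbench` is the evaluation engine for this comparison: given reference
annotations derived from structures, one prediction set per method, and a
selection of benchmark sequences, it computes a hierarchy of scores per
method. Everything is expressed over per-residue state strings (`M`, `i`,
`o`, plus `L` for PDBTM membrane loops and `U` for unassigned), with helix
segments as 1-based inclusive maximal `M` runs.

A deliberately non-trivial part of the design is that the package also
generates its own test data: synthetic membrane topologies whose
predictions are derived from the references by *logged* edits, so that
every metric value has an independently computable expectation. The
benchmark engine is thereby testable offline, without any structure
database or external predictor.

## Reference conventions

Two annotation traditions exist for membrane segments in structures, and
the package treats their differences mechanically:

* OPM-style annotations orient the membrane sides (inside/outside). A
  manually curated variant (`opm_adjusted`) is accepted as a fourth input
  convention but never recomputed — it is the product of visual curation,
  not an algorithm.
* PDBTM-style annotations label the two membrane faces without saying
  which is inside, and keep a distinct *loop* state for short
  membrane-dipping segments. `promote_loops()` turns those loop runs into
  membrane helices (merging with adjacent helices when they touch), and
  `map_sides()` recovers the inside/outside orientation by comparing
  against the OPM annotation of the same chain.

`map_sides()` uses a per-chain majority vote over all residues where both
annotations carry a side label. A vote is the least-assumption rule, and
it is honest about failure: an exact 50/50 split raises an error rather
than guessing. The achieved agreement fraction is reported so callers can
audit low-confidence mappings. Boundary positions are *not* harmonised
between the two conventions (they differ by a couple of residues per helix
end on real data); they remain distinct reference choices.

Re-entrant ("half-membrane") helices are called from flank context: a
helix whose nearest side labels on both flanks are equal enters and leaves
the membrane on the same face. Terminal helices with a single resolvable
flank are conservatively full-transmembrane. After loop promotion, an
isolated promoted run is always half-membrane (that is what a PDBTM
membrane loop is), while a merged run is re-classified from its flanks.

## The metric hierarchy

**Matching.** Per-segment scores require pairing observed with predicted
helices. The pairing is one-to-one — a predicted helix can satisfy only
one observed helix, so merged and split predictions are penalised — and
maximises the number of pairs with overlap ≥ `min_overlap`, breaking ties
by total overlap and then towards the leftmost observed helix. Because
segments in each list are disjoint and sorted, any two pairs with positive
overlap cannot cross, and an exact dynamic programme over the two lists
finds the optimum; an exhaustive-enumeration oracle in the test suite
confirms optimality on thousands of random instances. `min_overlap`
defaults to 3 residues, the historical benchmark convention, and is
exposed as a parameter rather than hidden.

**Per protein.** Q<sub>ok</sub> is the percentage of chains where every
observed helix is matched *and* no predicted helix is spurious.

**Per segment.** Sensitivity = matched/observed, specificity =
matched/predicted, pooled over all chains' segments.

**Boundaries.** Each matched pair contributes two end deviations. Three
variants are reported: % of ends exact, % within ±2 residues, and the mean
absolute deviation in residues. (These three definitions are this
package's own; they are stated explicitly in the report columns.)

**Per residue.** Q<sub>2</sub> and MCC on the two-state (M vs not-M)
confusion counts, and the Zemla-style segment overlap score Sov for the M
state, which rewards segment-level agreement with a tolerance term δ and
is harder to inflate than per-residue accuracy (predicting an entirely
helical chain scores highly on Q2 but poorly on Sov). MCC returns 0 when
any marginal of the confusion matrix is empty — the documented convention
for degenerate all-positive or all-negative predictions.

**Topology.** Orientation compares the side of the first sided residue;
per-segment topology marks an observed non-membrane segment correct when a
strict majority (>50%) of its residues carries the correct predicted side;
localisation requires fully correct topography *and* all segments on their
correct sides; per-residue topology is 3-state agreement. The observed
segmentation defines the units, since prediction segmentation errors are
already charged to the topography scores. Nothing in the scorer assumes
alternating sides, so a prediction that correctly reproduces a re-entrant
topology (same side on both flanks of a half-membrane helix) scores
perfectly.

**Unassigned states.** Topography-only methods emit no sides. `U` counts
as non-membrane in the two-state scores, and any position where either
string is `U` leaves the 3-state denominator. Scores that are undefined
for a method (orientation of a sideless prediction, Sov of a chain without
membrane helices) are `NA` — reported as not-applicable, never silently 0.

**Aggregation.** Per-protein flags are pooled over proteins; per-segment
scores over segments; boundary scores over matched ends; per-residue
scores are computed per protein and averaged with equal protein weight, so
long chains do not dominate. These granularities are a design choice of
this package and are stated in the function documentation.

## Dataset selection

Sequence redundancy is removed with Hobohm algorithm 2 over a supplied
pairwise percent-identity matrix (alignment computation is upstream — the
package consumes numbers, not alignments): repeatedly remove the sequence
with the most neighbours above the threshold until no similar pair
remains, with a deterministic tie-break (remove the lexicographically
greatest id). The no-similar-pair contract is asserted on every run.

The similarity *ladder* (20% to 100% in steps of 5) is built by successive
refinement: the 100% level retains everything, and each lower level
reduces the survivors of the level above. This makes the per-level sets
nested, so the retained-set size is non-decreasing in the threshold by
construction. The alternative — reducing the full matrix independently at
each level — does not guarantee that property: greedy max-degree removal
is not monotone under edge deletion, and counterexamples arise even on
family-structured matrices. The nested ladder was chosen because
consistency across similarity levels is exactly what a precomputed ladder
is for.

Attribute filters (chain class, kingdom, structure family, helix profile,
experimental method, resolution, submission year) combine as a
conjunction; NMR entries carry no resolution and always pass the
resolution cutoff. The default configuration mirrors the standard
benchmark conditions: helical membrane chains only, 30% similarity,
resolution ≤ 3.5 Å, x-ray or solution NMR, curated OPM-adjusted
references. Soluble decoy panels are cut to the least-similar decile
(ceiling rounding) of candidates by their maximum identity to the membrane
set, ties broken by id.

## The synthetic generator and what it does (not) show

`generate_dataset()` emulates the composition of a structure-derived
benchmark corpus: by default ~46% helical membrane chains, ~9%
β-barrel-like and ~45% soluble decoys, mirroring the make-up of the
reference corpus this kind of benchmark draws from. Helical chains have
1–5 helices of 15–30 residues (the canonical membrane-spanning length)
separated by 5–20 residue loops; each helix is re-entrant with probability
0.1, which makes a realistic minority of chains (roughly one in six) carry
at least one half-membrane helix. Sides alternate across full helices and
repeat around re-entrant ones. Decoys carry no membrane annotation
(all-`U` references): their role is to provide false-positive targets, and
pretending to know their sidedness would only fabricate topology
statistics. Amino-acid content is cosmetic (hydrophobic-biased inside `M`
runs, polar elsewhere); no metric reads it, and the sequences should not
be mistaken for realistic proteins.

One seed drives a per-protein sub-seed stream, so enlarging a dataset
never reshuffles earlier chains, and equal seeds give byte-identical
output files.

`perturb()` derives a prediction from a reference through an explicit
error model — per-helix deletion, merging of adjacent helices, clamped
boundary jitter, spurious-helix insertion, whole-chain side flips — and
logs every applied edit with its realised magnitude. `replay_log()`
reconstructs the prediction from the log by an independent route
(membrane-mask arithmetic rather than segment transformations), and
`expected_scores_from_log()` computes every metric through literal
brute-force code paths: exhaustive matcher, per-position loops, a direct
transcription of the Sov formula. The central correctness property of the
package is that the fast implementations reproduce this oracle exactly
(counts) or to 1e−9 (ratios) across hundreds of seeded draws.

What passing these tests shows: the metric implementations compute their
definitions correctly on topologies with the full structural vocabulary
(bitopic, polytopic, re-entrant, decoy). What it does not show: anything
about the *biological* difficulty of real predictions — synthetic errors
are independent and unstructured, whereas real predictors err
systematically (e.g. around signal peptides, which this package does not
model, or by consistently mis-placing boundaries at helix caps).

## Numerical and degenerate-input choices

* Scored quantities with empty denominators are `NA` ("not applicable"),
  propagated to report cells, never zero-filled.
* A chain with no observed and no predicted helix is vacuously correct for
  Q<sub>ok</sub>; Sov on a chain without observed membrane segments is
  undefined and the chain is excluded from the Sov mean.
* All randomness flows from explicit integer seeds; the RNG state of the
  calling session is saved and restored around generator calls.
* The human-readable score table rounds to integers (mean absolute
  deviation to one decimal); the TSV written next to it keeps full
  precision.
* Test and oracle problem sizes (chains of one to five helices, 500
  oracle draws, 1000 matcher/Sov draws, 100 ladder matrices) were chosen
  to exercise every code path combination while keeping the whole suite
  in the tens of seconds.

## Known limitations

* The one-to-one matcher charges a merged helix once as a match and once
  as a miss; benchmarks that want partial credit for merges need a
  different matching rule.
* Per-segment topology uses the strict-majority rule; a 50/50 segment is
  wrong by definition, which penalises predictions that are half-right on
  long loops.
* `map_sides()` votes per chain, not per segment; chains whose two
  annotations disagree structurally (different helix counts) can still
  map, with a low agreement fraction as the only warning.
* Signal peptides are not modelled or scored separately.
* The manual curation behind adjusted reference sets cannot be reproduced
  computationally; it is consumed as data.
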