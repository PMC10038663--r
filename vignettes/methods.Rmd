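---
title: "Methods: time-resolved GRN construction from expression and H3K27 chromatin state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved GRN construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During an embryonic induction assay, a signalling tissue is grafted onto
competent ectoderm and the responding tissue is profiled at fine time
resolution (0, 1, 3, 5, 7, 9, 12 h) against paired uninduced controls.
`chronogrn` reconstructs, from such a time course, a signed gene regulatory
network (GRN): which transcriptional regulators plausibly activate or
repress which targets, at which hour, through which chromatin element. The
inputs are (i) per-gene expression across time on two platforms (RNA-seq
FPKM at 0/5/9/12 h; NanoString nCounter counts at 1/3/5/7/9/12 h in
triplicate), (ii) H3K27ac and H3K27me3 ChIP peak sets for induced and
uninduced tissue at three epochs (5/9/12 h), (iii) CTCF peaks delimiting
regulatory neighbourhoods, (iv) a genome and gene annotation, and (v) a
transcription-factor motif library.

## Expression direction calls

RNA-seq calls use fold-change rules on FPKM: *up* when induced FPKM > 10
and induced/uninduced > 1.5; *down* when uninduced FPKM > 10 and the ratio
< 0.5. The 0 h sample exists only for uninduced tissue, so time-zero
expression is called against the 5 h induced sample: *up* requires 0 h
uninduced FPKM > 10 with a ratio > 1.5 over 5 h induced, and the 5 h
uninduced value both > 10 and above the 5 h induced value. A zero
denominator is treated as a +Inf ratio, which can only satisfy the up
clauses — this avoids NaN propagation and can never produce a spurious
down call.

NanoString lanes pass QC (600 fields of view; binding density in
[0.05, 2.25]) and are normalized in two steps: a positive lane
normalization factor (PLNF; dataset average of the six positive-probe
geometric means over each lane's own geomean) followed by a lane-specific
factor (LSNF) computed identically from the two housekeeping probes of the
PLNF-scaled data. Per lane, background (mean + 2 SD of the eight
normalized negative probes) is subtracted, negatives clipped to zero, and
zeros replaced by 1. Differential calls use the ratio of triplicate means
(up ≥ 1.2, down ≤ 0.8) with a two-tailed equal-variance t-test at 0.05.
When the pooled variance is exactly zero the test degenerates; we fix
p = 0 for unequal means and p = 1 (no call) for equal means, so the
zero-noise synthetic world is deterministic.

A note on the normalization's invariance, since it anchors one acceptance
property: scaling a single lane's raw counts by a factor *f* cancels
exactly against that lane's own positive geomean, so its normalized counts
equal those of an identical unscaled lane *in the same dataset* to machine
precision — this is the property the test suite asserts at 1e-9. What is
*not* invariant is the absolute level across datasets: the PLNF reference
is the dataset average of geomeans, so perturbing one of *n* lanes shifts
every normalized count by a common factor ≈ 1 + (f−1)/n (about 1% at 36
lanes). Ratios, and hence all fold-change calls, are unaffected.

The two platforms are consolidated per gene: a gene is kept unless the
platforms give *opposite* nonzero calls at a shared time point (5, 9,
12 h); a call against "none" is not a contradiction. This is deliberately
the weakest criterion consistent with "agreement" — requiring
same-direction calls at ≥ 1 shared time would discard genes whose change
falls between the RNA-seq time points. Retained profiles take RNA-seq
calls at 0/5/9/12 h and NanoString calls at 1/3/7 h.

## Chromatin-state indexing

Peaks are filtered for enrichment over input (p < 1e-5, fold change > 1.2,
q-score > 3; strict, as printed), then the union of the four sets
(mark × condition) at each epoch is merged into unique sites with bedtools
`merge -d 100` semantics (transitive, book-ended intervals merge; the
merge is reimplemented and checked against an O(n²) closure oracle because
its count/collapse bookkeeping is part of the site provenance contract).
Each site's joint pattern — H3K27ac/H3K27me3 presence in induced and
uninduced tissue by ≥ 1 bp overlap — is one of 16 states: *activation*
(indices 1–3; the induced tissue gains acetylation and/or loses
methylation), *repression* (4–6; the reverse), *poised* (7–12; a bivalent
tissue is involved), *no change* (13–16). Index 7 (methylated → bivalent,
i.e. acetylation gained while methylation persists) is the
activation-like poised class used for the main network. The numbering
within categories is a package convention exposed as a configurable table;
the category partition (3/3/6/4) and the printed ranges are invariant.
Network modes select indices {1,2,3,7} (main network), {1..7}
(subnetworks) or {1..10} ("changing" sites).

## Loci, motifs, edges

Each candidate gene's regulatory locus runs between the highest-signal
CTCF peaks within 500 kb (configurable) on either flank, using the peaks'
outer edges — the inclusive choice, so a boundary-adjacent site is never
dropped; a missing flank is capped at gene boundary ± window. The window
anchors at the gene body rather than the TSS (the source procedure leaves
the anchor ambiguous; the gene body is the inclusive choice); ties in
signal break
toward the nearer, then leftmost peak. Sites overlapping the locus by
≥ 1 bp belong to it; a site may belong to several loci.

Site sequences are scanned on both strands with position weight matrices
under a base-2 log-odds score against a uniform background, with a total
pseudocount of 0.1 apportioned by background (the FIMO default); hits
require score > 10, the "confidence score" cutoff, taken to be the scanner
score column rather than −log10 p (flagged: the alternative reading would
change hit density). Ambiguous bases contribute 0. Heterodimer motifs
("X::Y") map to every constituent present in the candidate set; motifs
whose TF maps to no candidate are kept but contribute no edges.

Edges follow the regulatory rule table. At an activation-class site of a
target whose direction at time *t* is nonzero, every motif-bearing
regulator with a nonzero direction at *t* or at the immediately preceding
time point ("simultaneously or just before", read literally) contributes
an edge: positive when co-regulated, negative when opposed. At
repression-class sites the signs are reversed and an unexpressed regulator
contributes nothing. Chromatin epochs serve network time points as
0–5 h → 5 h, 7–9 h → 9 h, 12 h → 12 h; the 0 h network borrows the
earliest epoch (no dedicated 0 h chromatin exists — nearest-epoch
fallback, configurable). Duplicate interactions from multiple sites of the
same target collapse to one edge per (regulator, target, sign, time) with
supporting sites unioned; genes with neither inputs nor outputs anywhere
are pruned.

Subnetworks resolve a single target into its elements: sites of indices
1–7 across the three epochs are merged across time (gap 500 bp), each
merged site becomes a node named `<gene>_siteN` in coordinate order, and
TF → site edges are emitted at the times the site's epoch state supports,
under the same rule table with the owner gene's direction as target
direction.

## Network metrics

Outdegree counts outgoing interactions (a self-loop once;
sign-distinct parallel interactions separately by default — they are
distinct interactions — with a switch to collapse them, since the source
convention is not stated). Betweenness centrality is the unnormalized
directed sum CB_i = Σ σ_su(i)/σ_su over ordered pairs with at least one
path, σ counting distinct shortest directed paths; parallel edges collapse
to single arcs and self-loops are ignored for path topology; unreachable
pairs contribute 0. Two independent routes are implemented in C++ — a
Brandes-style BFS accumulation and a depth-first enumeration of all simple
paths — and the test suite proves them identical on *every* digraph with
up to five nodes (2^20 graphs) plus sampled larger ones. Core genes are
ranked by betweenness with outdegree tiebreak; the core flag marks genes
at or above a quantile (default top 10%) in both metrics.

## The synthetic world

The generator emulates the full input bundle at desk scale with a planted
ground truth. Genes tile a 10 kb grid (two chromosomes); each tile carries
a high-signal CTCF peak on each flank (plus a low-signal decoy that the
highest-signal rule must reject), three 240 bp regulatory sites and a
2 kb gene body. The per-side CTCF search window in the scenario's matched
pipeline configuration is 4 kb — a scaled stand-in for the 500 kb used at
genome scale; the default on `build_locus()` itself remains 500 kb.

Expression follows two trajectory classes: *pre-expressed* genes (on at
0 h, repressed afterwards: uninduced FPKM 30 vs induced 5, NanoString
fold change 0.5) and *induced* genes switching from baseline to induced
FPKM 30 vs 5 (NanoString 1000 vs 500) at an onset hour cycled over the
time grid; decoy genes never change and must be pruned. Intended means
sit 3–4 log-SD from every threshold at the default noise, so calls are
threshold-robust. FPKM noise is log-normal with SD `noise_sd`; NanoString
counts get per-lane uniform scale factors (default [0.7, 1.4]) and
Poisson counting noise, the latter gated on `noise_sd > 0` because
`noise_sd = 0` defines the exactly deterministic world the recovery
property is stated in. Assays carry 6 positive, 8 negative and 2
housekeeping probes, matching the normalization's assumptions.

Planted regulation is a ring over the non-decoy genes ordered by onset
(plus chords when more relationships are requested), so every non-decoy
gene participates and the planted timed-edge set — derived by applying the
rule table to the planted structure — is exactly what a correct pipeline
must return. Regulator motifs are near-delta PWMs (consensus count 10^5)
whose score can only clear the >10 cutoff on an exact consensus match;
after planting, every site sequence is re-scanned and any chance consensus
occurrence is destroyed by a deterministic single-base edit. Zero-noise
recovery with precision = recall = 1 is therefore structural, not a seed
accident. Sub-threshold decoy peaks (an H3K27me3 "peak" failing the
enrichment filter on an active site) are planted so that skipping the
filter would flip sites to poised and lose edges — the recovery test is
sensitive to that failure mode. Decoy motifs mapped to no gene exercise
the TF-mapping filter.

What a green recovery test does establish: every stage's coordinate
arithmetic, filtering, state classification, locus assignment, scanning,
rule application and pruning compose correctly. What it does not: realism
of peak shapes, read-level noise, motif degeneracy, linked loci sharing
sites, or the biological truth of the rule table itself.

## Numerical and design choices

* Strict inequalities throughout the filters, as printed.
* Fold changes with zero denominators are +Inf (up path only).
* Zero-variance t-tests: p = 0 (unequal means) / p = 1 (equal).
* Merge gap 100 bp (sites), 500 bp (cross-epoch subnetwork merge).
* Betweenness unnormalized; no (n−1)(n−2) division.
* The BioTapestry export is a documented minimal CSV/XML dialect with a
  bundled round-trip parser; fidelity to the external GUI's importer is
  not a contract the suite can test.
* CLI configuration files are JSON (no YAML parser among the supported
  dependencies).

## Known limitations

Published-scale results (hundreds of regulators, thousands of
interactions) require the full primary datasets and upstream alignment
and peak calling, which are out of scope; all validation is on synthetic
scenarios. The motif scanner reports no p/q-values (the score cutoff is
the only knob, as in the source procedure). The per-index numbering
inside categories is a convention; analyses that depend only on the
category partition and the printed ranges are unaffected.
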