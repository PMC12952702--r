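---
title: "Methods: disorder annotation, enrichment statistics and DOT analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder annotation, enrichment statistics and DOT analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrscope)
```

This vignette documents the models, parameter choices and numerical
conventions behind `idrscope`, in the spirit of a methods section: what each
stage computes, which knobs matter, and what the synthetic benchmarks do and
do not establish.

## 1. Region calling

Disorder evidence enters as one score per residue in [0, 1] (predictor
outputs or binary labels; the package deliberately accepts any per-residue
table rather than a vendor-specific format, since published pipelines
differ in their predictors and consensus rules).  Segmentation is a
three-parameter rule:

* `threshold` (default 0.5): residues with score ≥ threshold are
  disorder-positive.  0.5 is the conventional midpoint for probability-like
  predictor outputs; binary 0/1 labels pass through unchanged.
* `max_gap` (default 0): maximal positive runs separated by at most this
  many negative residues are merged, absorbing the gap.  The default
  applies no smoothing — smoothing choices belong to the predictor, not the
  caller — but the knob is exposed because consensus pipelines often bridge
  1–3 residue gaps.
* `min_len` (default 1): merged runs spanning fewer residues are dropped.
  The well-known ≥ 25-residue rule is *not* applied here: it defines which
  IDRs are eligible for compositional-bias typing and is enforced
  downstream (`cb_min_len`), so that short disordered linkers still appear
  in disorder-content statistics.

The complement is emitted as ordered regions, so every protein is tiled
exactly — an invariant the test suite checks against a brute-force
run-length scan on randomized profiles.

Group summaries report two means on purpose: the *per-protein* mean (each
protein's disorder percentage, averaged unweighted) describes the typical
protein of a class; the *per-residue* mean (total disordered residues over
total residues) describes the residue pool and up-weights long proteins.
Box statistics (min, Q1, median, Q3, max) are computed on per-protein
percentages with type-7 (linear interpolation) quantiles — box-plot
conventions differ between tools, so one is fixed for reproducibility —
and outliers use the Tukey 1.5·IQR fences.

`fallback_disorder_score()` is labelled demo plumbing: a logistic of
windowed Kyte–Doolittle hydropathy and charge content.  It exists so the
pipeline can be exercised without an external predictor and carries no
accuracy claim.

## 2. IDR typing

Long IDRs (≥ 25 residues, `cb_min_len`) are classified by sliding-window
composition over windows of `window = 25` residues (step 1), with
precedence **RS > G-rich > poly-P/Q > charged > noncharged**:

| rule | default | rationale |
|---|---|---|
| RS-like: some window with (R+S) ≥ `rs_frac` and ≥ `rs_min_dipeptides` RS/SR dipeptides | 0.40 / 3 | RS domains of SR splicing factors are dipeptide-repeat-like, not merely R/S-rich; the dipeptide count rejects segments where R and S are segregated |
| G-rich: some window with G ≥ `g_frac` **or** ≥ `g_min_motifs` motif matches (RGG, [RSY]GG, R[AGT][AGTFIVR], Gly runs) | 0.30 / 2 | composition and motif routes are alternative signatures of Gly-rich IDRs; both are implemented with an OR and the route is visible in the motif table. RGG matches are a subset of [RSY]GG matches, so motif counting deduplicates by span — otherwise a single RGG would satisfy the count by itself |
| poly-P/Q: a P or Q homorepeat ≥ `homorepeat_len` | 5 | homorepeats shorter than 5 are ubiquitous background |
| charged: some window with D/E/K/R ≥ `charged_frac` | 0.35 | roughly 1.5× the vertebrate background charged fraction (~0.23) |
| noncharged: any residue's region-wide frequency ≥ `bias_fold` × background | 3.0 | catch-all for single-residue bias (N/S/T/H-rich etc.) |

Only the 25-residue minimum is a literature constant; the remaining values
are this package's defaults, chosen so the rules are selective on the
vertebrate background composition (see §5) and exposed in full through
`typing_params()`.  The precedence order mirrors how the field reports
these classes: RS-like is singled out for SR/RES families even though
arginine is charged, so RS outranks charged.

Classification inspects only the region's own residues (context
invariance), and `X` residues are excluded from denominators so frequency
statistics remain well-defined.

**SS-IDRs.**  A disordered region qualifies when ≥ `ss_overlap_frac` (0.5)
of its residues lie in H- or E-runs of length ≥ `ss_min_elem` (4 — about
one helical turn / a minimal strand; shorter runs are predictor noise).
The SS-IDR call overrides the CB label as the *primary* subtype, but the CB
call is retained in a separate column (`cb_subtype`), since SS and CB
percentages are reported side by side and it is not established that the
two classes are exclusive.

## 3. PTM statistics

Enrichment is **residue-level**: a residue with ≥ 1 PTM annotation is one
PTM-bearing site, every other residue is one non-PTM site, matching the
phrasing "sites hosting PTMs … sites without PTMs".  All residues count —
no attempt is made to restrict to modifiable residues, which would import a
per-PTM-type alphabet into a site-level test.  The pooled 2×2 table
(a = PTM∩IDR, b = noPTM∩IDR, c = PTM∩ordered, d = noPTM∩ordered) is tested
with the exact Fisher test; the reported statistic is the *sample* odds
ratio ad/bc (∞ when bc = 0 and ad > 0), not the conditional-MLE odds ratio,
because the sample OR is what the printed counts imply directly.

The per-protein density comparison treats the two compartments of one
protein as paired observations — densities share the protein's annotation
depth, which an unpaired test would ignore — so the default is the paired
Wilcoxon signed-rank test on density differences (zero differences dropped,
exact null for ≤ 25 informative tie-free pairs, tie-corrected normal
approximation with continuity correction otherwise).  The choice of paired
over unpaired is an assumption, recorded here, and an unpaired variant is
available (`paired = FALSE`).  Proteins lacking either compartment have an
undefined density and are excluded with a message.  Tests are two-sided by
default.

Type-level tables are **annotation-level** (PTMs, not residues):
`ptm_idr_ratio()` reports, per PTM type, the fraction of its annotations
falling inside IDRs; `ptm_type_distribution()` reports each type's
percentage of all annotations in scope, summing to 100 within every
stratum.

## 4. Mutation analysis

"Flanking" is |Δposition| ≤ 5 inclusive on the same protein.  Per-family
counts use *distinct mutated residues* inside IDRs (a residue hit by two
records counts once); per-tumor-type counts use mutation records, exploded
over their tumor-type sets.  Phenotype grouping is a plain group-by on the
provided ontology identifiers — no ontology reasoning.

No standard test exists for "proteins with mutations near PTMs", so the
package supplies a permutation null and labels it as its own choice: the
observed statistic is the number of proteins with ≥ 1 flanking pair; each
replicate redraws every protein's mutation positions uniformly within that
protein (optionally within the same region kind, preserving the
ordered/disordered split), and `p = (1 + #{null ≥ obs}) / (1 + n_perm)`.
Given a seed the p-value is reproducible bit-for-bit.

## 5. Background composition

The "normally expected" amino-acid frequencies used by the noncharged-bias
rule are an average vertebrate composition, shipped as a documented,
renormalised constant and replaceable via a two-column TSV
(`read_background()`), since no single canonical source table exists.

## 6. Evolutionary stage (DOT)

Disorder calls of each ortholog are mapped through its aligned sequence:
non-gap columns inherit the residue's region kind (1 = disordered,
0 = ordered), gaps are missing, and columns with > 50 % missing states are
unscored (parsimony on nearly-empty columns is noise; the threshold is a
parameter).

Ancestral reconstruction method is not dictated by the underlying
biology here; **Fitch parsimony** was chosen over likelihood reconstruction
because it is deterministic, assumption-light for a binary character, and
exhaustively testable (the suite compares every tree shape with ≤ 6 leaves
and every leaf labeling against brute-force minimisation over ancestral
assignments).  Internal counting uses Hartigan's generalisation, so
polytomies are scored exactly; missing leaves are treated as the full state
set, which provably equals pruning them for a binary character.

*Changes per node* is defined as Σ per-column minimum changes / (edge count
× scored columns) — a normalisation this package fixes and prints in its
output headers, since "changes per node" is reported in the literature only
as a resulting range (0.01–0.08).  Under the generator's default per-edge
flip rate of 0.05 the simulated families land inside that range.

The SS-IDR comparison set contains reference SS-IDR positions that are
*adjacent to order*: within `adjacency_cols = 1` alignment columns of an
ordered reference column, or at columns where ≥ `ortholog_ordered_frac =
0.5` of non-missing ortholog states are ordered.  Both cutoffs are
parameters because "adjacent" is not otherwise quantified.  Group A (those
columns) is compared with group B (other disordered reference columns) by a
two-sided Mann–Whitney U on per-column change counts — exact by
enumeration over group assignments when both groups have ≤ 8 observations
(ties allowed, U counts ties as ½), tie-corrected normal approximation with
continuity correction otherwise.  The comparison is omitted with a notice
when a group is empty or no column varies.

*Net gain of disorder* requires a single reconstruction per column, so
ambiguity is resolved by a fixed convention: DELTRAN (a node inherits its
parent's state whenever optimal, pushing changes toward the leaves) with
root ties resolved to ordered (state 0).  Per clade — each internal node,
named by its lexicographically smallest descendant leaf — the report sums
0→1 minus 1→0 events over the clade's edges and scored columns.  Any such
convention biases individual reconstructions; only differences between
clades and signs of large totals should be interpreted.

Input trees must be rooted; unrooted Newick trees are midpoint-rooted with
a logged notice, as parsimony bookkeeping (not the score itself) depends on
a root.

## 7. The synthetic generator

`sim_config()` defaults define the package's reference study: 500 proteins,
lengths 200–600, target disorder fractions 0.3–0.7 laid out as alternating
ordered/disordered segments (ordered spacers ≥ 10 residues so distinct
IDRs never fuse); 110 planted 50-residue segments per CB subtype (at most
one per protein); disorder scores 0.9/0.1 ± Gaussian noise (σ = 0.05,
clipped to [0, 1]); PTMs as per-residue Bernoulli draws with ordered rate
0.01 and the disordered rate solving a target odds ratio of 3; a Poisson
mean of 2 mutation records per protein with 30 % forced within ±5 of a PTM;
and 12-taxon Yule families whose columns evolve from the reference
protein's true states with per-edge flip probability 0.05.  One master seed
drives independent per-stage streams, so any stage regenerates identically
in isolation and datasets are byte-identical across runs.

Two emission compositions are fixed, documented constants: a
disorder-promoting background (enriched in P, Q, S, N, A, G; depleted in
hydrophobics) and a globular background.  The disordered background is
deliberately kept below every typing threshold in expectation — e.g. its
charged (D/E/K/R) content is ~0.10 versus the 0.35 window threshold, and
its expected G-motif count per segment is ≪ 2 — because the generator's
purpose is a *fair* recovery benchmark: planted segments, not background
drift, must carry the compositional signal.  The planted compositions
(R/S-rich with abundant RS dipeptides; P/Q-rich with guaranteed Q⁷ and P⁶
runs; G-rich with RGG-generating R content; E/K/D-rich) are conversely
chosen to be unambiguous under the precedence rules.

What the generator does **not** emulate: realistic amino-acid substitution
processes (ortholog residues are re-emitted independently per state — no
exchange matrices, no rate heterogeneity), indels (alignments are gap-free
by default; the DOT stage handles gaps as missing when given real
alignments), predictor-like autocorrelated score errors, position-specific
PTM sequon preferences, and realistic tumor-type frequencies.  Passing the
recovery benchmarks therefore demonstrates algorithmic correctness and
calibration of the statistics under the stated model — not predictor
accuracy or biological recall on real proteomes.

## 8. Problem sizes and determinism

The shipped tests run the reference study at its default size (500
proteins) for the enrichment and motif-recovery checks, smaller replicas
(25–120 proteins, 6–10 taxa) for pipeline and property tests, 1 000 random
profiles for the segmentation oracle, all ≤ 6-leaf tree shapes for the
parsimony oracle, and 200-column groups on a 16-leaf tree for the DOT rate
contrast — sizes chosen to exercise every code path at comfortable
desk-scale runtimes.  Every stochastic step takes an explicit seed; no test
or script depends on global RNG state.

## 9. Known limitations

* Disorder and secondary-structure prediction are out of scope: the
  package consumes per-residue outputs and inherits their biases.
* CB typing thresholds are heuristics standing in for unpublished
  scheme details; conclusions sensitive to a threshold should be re-run
  across a grid (all thresholds are config-exposed).
* The flanking permutation test conditions on observed PTM positions and
  mutation counts only; it does not model mutational sequence context.
* Parsimony undercounts changes on long branches; `changes_per_node` is a
  lower-bound-flavoured rate, which the simulated-events bound makes
  explicit.
* Dataset-scale published figures (overall disorder percentages, per-type
  PTM ratios, mutated-protein counts) depend on retrieved database
  snapshots and external predictors and are not reproduced here; the
  package's claims are the algorithmic and statistical properties its
  tests compute.
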