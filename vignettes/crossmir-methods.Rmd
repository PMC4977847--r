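---
title: "Models and methods behind crossmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crossmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crossmir)
```

crossmir studies putative cross-kingdom miRNA regulation: a plant miRNA
ingested with food surviving into the consumer's circulation and repressing
animal transcripts. The package implements the computational side of that
question as a pipeline of five stages — hybridization prediction,
screening/ranking, interaction-network weighting, module-level functional
analysis, and tissue-expression tiering — and pairs every stage with a
synthetic-data generator that plants the structure the stage is supposed to
find. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic benchmarks do and
do not demonstrate.

## 1. The duplex energy model

Hybridization between a miRNA and a candidate site is modeled as a single
contiguous intermolecular duplex: a set of base pairs that is non-crossing
when the miRNA is read 5'→3' and the target antiparallel, with no
intramolecular structure and no multiloops. This is the structure space of
the classic miRNA-target hybridization tools, and it makes the minimum free
energy computable by an exact dynamic program.

Energies are additive over consecutive pair steps:

* **Stacked steps** cost a nearest-neighbor free energy from a 6×6 table
  over the admissible pair types AU, UA, CG, GC, GU, UG. The Watson–Crick
  entries are Turner-style values between −0.93 and −3.42 kcal/mol; steps
  involving one G:U wobble are set to −1.30, tandem wobbles to −0.50.
  The table ships as a versioned parameter file
  (`inst/extdata/stack_energies.tsv`) so the values are swappable; it must
  satisfy the symmetry `ΔG(p1→p2) = ΔG(flip p2 → flip p1)` and all
  Watson–Crick stacks must be strictly negative (checked at load).
* **Bulges** (L unpaired bases on one strand) cost `3.8 + 0.5·L` kcal/mol,
  **internal loops** (L1, L2 on the two strands) `4.0 + 0.3·(L1+L2)`, and
  each helix end adds `0.45`. Penalties are linear so the dynamic program
  can treat uncapped gaps as prefix minima of the energy matrix minus a
  linear drift, giving amortized O(|m|·|w|) transitions per window; capped
  gaps use bounded scans. The traceback re-identifies each optimal step by
  energy search instead of storing a predecessor matrix.

Absolute agreement with any particular external folding tool is a
non-goal; what is guaranteed — and tested against a brute-force enumeration
of every admissible pairing — is that the program returns the exact minimum
of this energy function. A window with no admissible pairing yields an
infinite-energy sentinel, not an error, and only stabilizing duplexes
(MFE < 0) are ever reported as hits.

Structural caps are profile properties, not model properties: scanning is
done uncapped, and the plant screening profile later rejects structures
with internal loops above 5 nt per side or bulges above 9 nt, while the
human profile leaves structure free. Cap semantics on the loop are
per-side, matching how the screening stage measures the traceback
structure (longest single bulge; longest internal-loop side).

## 2. Scanning, seed rule and coordinates

Transcript regions are scanned with a 40-nt window (wide enough for a
21-nt miRNA plus maximal bulges) at stride 1. Overlapping windows find the
same site repeatedly, so hits are reduced to local minima: a hit is
retained iff no overlapping hit has a lower MFE, ties going to the
leftmost. Coordinates are 0-based half-open on the region; miRNA positions
are 1-based only in seed terminology.

The seed rule requires miRNA positions 2–8 (seven nucleotides) to be each
paired Watson–Crick — G:U wobbles are excluded from the seed, the stricter
of the two common readings — with contiguous target bases. The wobble
tolerance elsewhere in the duplex is governed solely by the energy model.

## 3. The empirical p-value

No analytic null exists for "best duplex energy of a miRNA against a
transcriptome", so the package calibrates one per miRNA: windows tiled from
the scanned regions are shuffled preserving dinucleotide composition
(Altschul–Erikson Eulerian-path shuffling, so stacking statistics are
retained), the best (lowest) MFE across a drawn set of windows is recorded
per shuffle replicate, and a minimum-Gumbel distribution is fitted to those
scores by the method of moments (`β = sd·√6/π`, `μ = mean + γ·β`, with β
floored at 1e−6 so a degenerate null produces a step function rather than
a division by zero). A hit's p-value is the fitted probability that the
null best score is at least as low.

Two parameters matter. `n_shuffles` (default 100) sets the fit's sampling
error. `windows_per_shuffle` (default 30) sets how many windows each null
replicate takes its minimum over; the Gumbel family is the limit law of
such minima, and the approximation visibly improves from best-of-10 to
best-of-30. The package's uniformity benchmark therefore pools fresh null
p-values across five independently calibrated miRNAs (100 each, n = 500)
and requires the empirical CDF to stay within 0.1 of uniform in sup norm;
single-miRNA checks can exceed that bound for occasional sequences whose
null is less Gumbel-like, which is a property of the extreme-value
approximation rather than of the implementation. The screening cutoff
p ≤ 0.05 is a configurable default, not a calibrated constant.

## 4. Screening, ranking and three-level validation

The filter cascade (`apply_filters()`) is a pure conjunction — energy,
p-value, seed, caps — so it is idempotent and monotone in each threshold;
both properties are tested. Ranking is per miRNA by p-value, then MFE,
then gene id; the tertiary key exists only to make the order total and
deterministic under input permutation.

The validation harness asks three nested questions of each known target:
is its region in the input mRNA set at all, did the primary scan hit it,
and did the hit survive screening — with the per-miRNA rank attached to
survivors. The implication chain (refined ⇒ primary ⇒ present) holds on
every record by construction and is asserted in tests. Summaries count
ranks within the top 10 and top 50 per miRNA; ranks are per-miRNA rather
than pooled, the natural reading when each miRNA's candidate list is
ranked independently. The `top_k_rank` profile field (default 50) is the
rank threshold downstream selection would use; on the planted benchmark it
is far from binding, since every clean planted target ranks in the top 10.

## 5. Network weighting by iterated adjacency multiplication

The node-weighting scheme starts every gene at weight one and repeatedly
multiplies the weight vector by the 0/1 adjacency matrix. Iterating
`B ← A·B` literally diverges whenever the spectral radius of A exceeds
one, so the package renormalizes the total weight to N after each
multiplication — making the scheme exactly power iteration toward the
principal (Perron–Frobenius) eigenvector of A, which is what repeated
adjacency multiplication measures. Convergence is declared when the
largest per-node change falls below `tol = 0.005`; the iteration count is
data-dependent (17 on the default planted network) and is reported rather
than assumed. A bipartite or slowly-mixing graph that fails to converge
within `max_iter` yields a flagged result with a warning, never a silent
one. Isolated nodes receive weight 0 in this mode (nothing flows into
them); an entirely edgeless graph keeps its initial weights untouched.

Standard damped PageRank (d = 0.85, dangling mass spread uniformly,
scaled to total N for comparability) is available behind `mode =
"damped"` for users who want the random-surfer model; the two agree on
which nodes are hubs but not on the weight profile, and the default is the
adjacency-iteration mode described above.

Bridge genes are the top-k weights (k = 15 by default), ties broken by
degree then id. Modules are the connected components left after deleting
the bridges; components below `min_size = 3` are reported separately as
residue rather than as modules, a choice that keeps "module" meaning a
unit worth testing for enrichment — on the planted benchmark no residue
arises, so the choice is inert there by construction.

## 6. Module enrichment and cross-species similarity

Enrichment is the one-sided (over-representation) hypergeometric upper
tail, per term, with the complete network as the background — modules are
never tested against the genome, only against the network they came from.
Gene→term annotations are propagated up `is_a` ancestry before testing
(the true-path rule) by default; the flag exists because propagation
changes the counts and some annotation corpora arrive pre-propagated.
Benjamini–Hochberg adjustment is applied across the terms tested within
one module (the family a reader of a per-module table implicitly assumes);
results are reported at adjusted-p < 0.1. The BH step is delegated to
`stats::p.adjust`, with tests pinning the step-up behavior.

Slim mapping takes each term to every slim category among its transitive
`is_a` ancestors — a slim term maps to itself, terms reaching no slim
category land in an explicit `unclassified` bucket, and cycles are a
load-time error. Functional similarity between two category profiles
(e.g. the slim signatures of two species' enriched functions) is reported
as both the Jaccard index and the overlap coefficient on the support
sets, with the shared categories listed; the pipeline also emits pairwise
module-to-module similarities.

## 7. Tissue tiers

With an expression matrix over the eight reference tissues (brain, heart,
kidney, liver, lung, spleen, stomach, small intestine), a gene is
"expressed" in a tissue when its value exceeds `detect_thresh` (default
1, in the units of the matrix). Genes expressed in at least seven of the
eight tissues are ubiquitous (housekeeping-like); in exactly one,
tissue-specific, assigned to that tissue; in an intermediate number with
a clear peak (max z-score across tissues above 1), highly expressed.
Genes below threshold everywhere form a `not_expressed` bucket, and
intermediate genes without a peak fall into `other`. Both thresholds are
package inventions — no canonical values exist — and are exposed as
arguments; the defaults are chosen so that the three generated tiers are
cleanly separable (see below).

## 8. What the synthetic generators emulate

Every pipeline input has a generator, and every planted feature is
emitted in a truth table, so each stage can be scored without reading
generator internals. All generators are pure functions of the
configuration seed.

* **miRNAs/transcripts** emulate a curated miRNA set and a 3'UTR/CDS
  collection: uniform random RNA with planted sites that are exact
  reverse complements of their miRNA, optionally corrupted by a seed
  mismatch (partner of miRNA position 5 replaced by a non-pairing base),
  a G:U wobble outside the seed, or an inserted target-side bulge. The
  defaults (25 miRNAs of 21 nt) mirror a plant-miRNA study's scale.
* **The network** emulates an interaction network around predicted
  targets: 11 dense Erdős–Rényi modules of 48 genes (intra-module edge
  probability 0.155, repaired to connectivity), no direct inter-module
  edges, and 15 bridge hubs each wired to 36 module genes spread evenly
  across all modules — so hubs dominate both degree and eigenvector
  weight by construction, at roughly the 543-node / 2450-edge scale of
  the motivating study. Stratified hub wiring matters: hubs sampling
  modules unevenly can lose an eigenvector-weight contest against nodes
  of the densest module.
* **Annotations** are a random acyclic `is_a` DAG whose roots double as
  the slim list, background gene-term assignments at rate 0.04, and one
  planted term annotating 80 % of a chosen module's genes.
* **Expression** plants the three tiers directly (on-level 20 in all
  tissues; single-tissue peak 40; 2–6 tissues at 5 with one peak at 40)
  plus truncated Gaussian noise (sd 0.3).

What passing these benchmarks shows is that each stage recovers exactly
the structure it is specified to recover, with correct arithmetic and
deterministic behavior. What it does not show: real UTRs are not uniform
random sequence (composition bias changes the null energies), real
interaction networks are not block-ER with clean hubs (module boundaries
blur and weight contests are closer), real GO corpora are deeper and
denser than a 128-term DAG, and real expression is compositional and
correlated across tissues. Performance claims on real data need real
data.

## 9. Problem sizes, numerics, and other fixed choices

The test and benchmark suite uses a 10-miRNA / 15-transcript screening
fixture, the full-scale (543-node) planted network, 200 null modules for
type-I control, 400 genes for tier recovery, 500 random pairs for the
DP-vs-enumeration comparison, and a 5-miRNA × 100-score pool for p-value
uniformity; the end-to-end determinism check runs a moderate 8-miRNA
configuration twice and compares bytes. These sizes are the package's
choice of a thorough-but-quick benchmark; all are configuration, not
constants.

Numerical and tie-break decisions, collected: DP ties resolve to the
first-found optimal cell (deterministic); overlap reduction prefers lower
MFE then leftmost start; rank ties fall back to gene id; bridge ties to
degree then id; the Gumbel scale is floored at 1e−6; hypergeometric tails
come from `stats::phyper` (log-space, exact to ~1e−14 against direct
combinatorial summation); module ordering is by size then first gene id.
Degenerate inputs are defined, not exceptional: empty hit tables pass
through filters, a zero-validated summary flags its undefined fraction, an
edgeless graph keeps unit weights, deleting no bridges yields one module,
terms absent from the background score p = 1, and all-zero genes classify
as not expressed.

## 10. Known limitations

The energy model is deliberately compact: no dangling-end or terminal-AU
corrections, no coaxial stacking, no length-30 loop asymmetry tables, and
a single wobble-stack constant. The p-value is calibrated per miRNA
against shuffled windows of the supplied transcriptome — it measures
surprise relative to composition, not biological functionality. Target-site
accessibility (local secondary structure of the mRNA) and multi-site
cooperativity are out of scope, as are overlapping community structures in
the network stage and full OBO semantics (only `is_a` is honored) in the
ontology.
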