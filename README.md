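# crossmir

Cross-kingdom microRNA analysis in R: seed-anchored miRNA→transcript
hybridization prediction and screening, validated-target ranking, iterated
PageRank bridge-gene identification with module decomposition of a gene
interaction network, and per-module GO enrichment with cross-species
functional-similarity scoring — plus synthetic-data generators with planted,
recoverable structure so the entire pipeline can be exercised and scored
without any external database.

The package targets the question of whether diet-derived plant miRNAs could
plausibly regulate genes in the consuming animal: which animal transcripts a
plant miRNA could hybridize to, which of those candidates survive stringent
thermodynamic and seed screening, how the resulting target genes organize
into an interaction network, and what the functional footprint of that
network's modules looks like across species and tissues.

## The methods at the core

**Duplex minimum free energy.** For a miRNA `m` (5'→3') and a target window
`w` read antiparallel, the package minimizes the free energy over all
purely intermolecular, non-crossing pairings forming one contiguous duplex:

    E(S) = Σ_steps ΔG°stack(p_t, p_{t+1})            paired steps
         + Σ_bulges  (3.8 + 0.5·L)                    one-sided gaps, kcal/mol
         + Σ_loops   (4.0 + 0.3·(L1+L2))              two-sided gaps
         + 0.45 per helix end

with a Turner-style nearest-neighbor stack table over the six admissible
pair types (AU, UA, CG, GC and the weaker G:U wobbles), loaded from a
versioned parameter file. The dynamic program is exact — it provably equals
exhaustive enumeration of all admissible pairings — and runs in compiled
code with amortized O(|m|·|w|) transitions.

**Seed rule and screening.** A hit passes the seed rule iff miRNA positions
2–8 are all paired Watson–Crick (no G:U) to contiguous target bases. The
screening cascade retains hits with MFE ≤ −25 kcal/mol, calibrated p-value
≤ 0.05, an intact seed, and (in the plant profile) internal loops ≤ 5 nt
per side and bulges ≤ 9 nt; the human profile leaves structure uncapped.
Per-miRNA p-values come from a minimum-Gumbel (extreme-value) fit, by the
method of moments, to best-hit energies of dinucleotide-preserving shuffles
of the scanned windows. Targets are ranked per miRNA by p-value, then MFE,
then gene id.

**Network weighting and modules.** An undirected interaction graph with 0/1
adjacency A is weighted by iterated matrix multiplication: starting from
every node at weight one, `B ← A·B` with the total renormalized to N each
step (power iteration toward the principal eigenvector of A), stopping when
the largest per-node change drops below 0.005; standard damped PageRank
(d = 0.85) is available behind a flag. The top-15 weights are the bridge
genes; deleting them decomposes the graph into connected components, the
modules.

**Module function.** Each module is tested against the whole-network
background with the upper-tail hypergeometric test per GO term,
Benjamini–Hochberg adjusted within the module, reported at adjusted-p <
0.1. Enriched terms map to generic (slim) categories along transitive
`is_a` ancestry, and two category profiles are compared by Jaccard/overlap
coefficients. Target genes are classified into ubiquitous / highly
expressed / tissue-specific tiers from an expression matrix over eight
tissues.

## Worked example

Everything runs on generated data with planted, recoverable structure:

```r
library(crossmir)

cfg    <- synth_config(seed = 42, n_mirnas = 10, n_transcripts = 15,
                       region_len = 150)
mirnas <- gen_mirnas(cfg)
tr     <- gen_transcripts_with_sites(cfg, mirnas)   # truth table included

hits    <- predict_targets(mirnas, tr$regions)
calibs  <- calibrate_nulls(mirnas, tr$regions, n_shuffles = 100,
                           seed = 420, windows_per_shuffle = 10)
hits    <- add_pvalues(hits, calibs)
refined <- rank_targets(apply_filters(hits, filter_profile("plant")))
refined
#> # A tibble: 11 × 12
#>   mirna_id gene_id region target_start   mfe       pvalue  rank
#> 1 mir001   G001    CDS              60 -38.0 0.0000000880     1
#> 2 mir002   G002    UTR3             60 -47.9 0.00000713       1
#> 3 mir003   G003    CDS              60 -48.2 0.000000331      1
#> ...
```

Each of the ten planted clean sites is recovered at its planted offset
(position 60), with strongly stabilizing energies far below the
−25 kcal/mol cutoff; the corrupted plantings (seed mismatch, 10-nt bulge)
are screened out as intended. The three-level validation harness confirms
this quantitatively:

```r
clean <- subset(tr$truth, corruption == "none")
rec   <- validate_three_level(clean[, c("mirna_id", "gene_id", "region")],
                              tr$regions, hits, refined)
validation_summary(rec)
#>   n_validated n_in_top10 n_in_top50 frac_top50
#> 1          10         10         10          1
```

The network stage, at the default study-scale configuration (11 planted
modules of 48 genes, 15 bridge hubs, ~2450 edges):

```r
g <- build_graph(gen_network(synth_config(seed = 42))$edges)
w <- pagerank_weights(g, "paper")
glance(w)
#>   n_nodes iteration_count final_perturbation converged mode
#> 1     543              17            0.00496 TRUE      paper

modules <- decompose_modules(g, select_bridges(w, g, 15))
glance(modules)
#>   n_modules n_module_genes n_bridges n_residue
#> 1        11            528        15         0
```

The weight iteration converges (largest per-node change below 0.005) in 17
iterations, the 15 planted hubs are exactly the top-15 weights, and
deleting them yields exactly the 11 planted modules with no residue.
`run_pipeline()` chains every stage (hybridize → screen → validate →
network → enrich → tissues) into a run directory of TSVs with a
deterministic log and a JSON summary; `autoplot()` methods and
`plot_enrichment()` give quick ggplot2 views of weights, modules and
enriched terms.

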