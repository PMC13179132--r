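# coregulomics

Temporal multi-omics co-regulation analysis for stage-resolved quantitative
proteomics, transcriptomics and phosphoproteomics — the kind of data
produced by profiling stem-cell-derived embryo models (gastruloids) across
developmental stages in replicate. The package is aimed at computational
biologists who have feature-by-sample abundance matrices and want to move
from "which proteins change" to "which proteins move together, which
outsiders move with known complexes, where protein decouples from RNA, and
which kinases drive the phosphosite dynamics".

## What it computes

**Co-regulation network.** After ratio normalization (each feature's
abundance over its per-species geometric mean, log2), Pearson correlations
are computed for every unordered protein pair in memory-bounded blocks,
with p-values from the t transform of *r* (df = *n* − 2). Edges keep pairs
with |*r*| ≥ 0.95 and Benjamini–Hochberg adjusted *p* < 0.01, BH taken over
the *full* pair universe. A label-shuffling permutation null (50,000 pairs
× 10 shuffles by default) provides an empirical-FDR diagnostic for the
threshold.

**Cooperative proteins.** For each network node outside a known complex,
the edge set is partitioned into a 2×2 table — *a*: candidate–module edges,
*b*: other edges touching the module, *c*: candidate edges elsewhere, *d*:
the rest (*a*+*b*+*c*+*d* = |E|) — and scored with a one-sided Fisher's
exact test, BH-adjusted across all (candidate, module) pairs jointly.
Withheld-member validation and Jaccard clustering of shared cooperative
sets are included.

**RNA–protein discordance.** Per gene and stage,
D = protein log2 fold change − RNA log2 fold change; |D| ≥ 1 classifies a
gene as protein- or RNA-abundant at that stage. Complex-level medians,
paired stage-transition tests, and TF–target retrieval (transcripts
tracking a factor's protein profile at *r* ≥ 0.9) build on the same
records.

**Kinase activity.** Phosphosite log2 ratios are protein-subtracted per
sample; kinase–substrate enrichment z-scores follow
z = (s̄ − p̄)√m / δ over row-mean-centred site values with a ≥ 2 substrate
cutoff, and an |*r*| ≥ 0.5 kinase–substrate correlation network links
kinase profiles to their annotated sites.

**Synthetic ground truth.** A seeded generator plants co-regulated
modules, anticorrelated module pairs, cooperative satellites, per-gene
discordance offsets and kinase-driven phosphosite programs, so every stage
of the pipeline is validated by parameter recovery. See the methods
vignette (`vignettes/temporal-coregulation.Rmd`) for the model and every
default.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
conditions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential.R
Rscript analysis/03_network.R
Rscript analysis/04_cooperativity.R
Rscript analysis/05_discordance.R
Rscript analysis/06_phospho.R
```

The network step prints:

```
network: 65 nodes, 231 edges, 47.6% positive, degree 7.1 +/- 10.0
complex-annotation enrichment ratio: 18.9-fold over all possible pairs
moduleA: 10/10 members in network, 100% of possible edges, 100% positive; mean pairwise r = 0.986
```

meaning the filter kept 231 of 2,080 tested pairs, both planted 10-member
modules were recovered as complete positive cliques, and edges are ~19×
enriched for shared complex membership over the all-pairs expectation (the
45 within-module pairs among all 2,080). The cooperativity step then
reports:

```
top hit for moduleA: SAT_MODULEA_01 (a = 10 edges to module, BH p = 0.00748)
withheld members MODULEA_01, MODULEA_02 rank 1, 2 among candidates for the reduced module
```

— the planted satellite is the top-ranked cooperative protein for its
module (it carries edges to all 10 members), and deliberately withheld
complex members are recovered as the top two candidates. The discordance
and phospho steps close the loop:

```
planted-offset recovery RMSE = 0.058 log2 units
peak |KSEA z| per kinase: KIN_ACT = 5.81, KIN_NULL1 = 2.05, KIN_NULL2 = 1.64
```

the planted 2-log2-unit offsets are recovered to well within a tenth of a
unit, and the one active kinase separates cleanly from the silent ones.

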