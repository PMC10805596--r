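---
title: "Cluster-profile coexpression and cross-species conservation: methods"
author: "scProteoNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-profile coexpression and cross-species conservation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model behind each stage, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## 1. From counts to coexpression

**Normalization and profiles.** Raw counts are scaled per cell to counts
per million (CPM); cells with zero total counts are left all-zero and
reported, never silently repaired. Analysis then moves to cluster space:
the genes × clusters matrix of mean CPM per transcriptional cluster. The
assumption is that clustering and cluster→class annotation (excitatory
neurons, inhibitory neurons, non-neuronal glia) are trusted upstream
inputs.

**The fold-change-profile transform.** Per-cell correlation in
single-cell data is dominated by dropout. Instead, each gene's profile
over $n$ clusters is replaced by the vector of all $n(n-1)/2$ pairwise
log2 fold changes between cluster means, with pseudocount 1 CPM. Two
genes are coexpressed when these vectors correlate (Pearson). Two
properties matter:

- *Robustness*: a low-quality cluster corrupts only the $n-1$ entries
  that involve it.
- *Effective dimension*: the $n(n-1)/2$ entries derive from $n$ cluster
  means, so the transform carries roughly $n-1$ degrees of freedom. Null
  correlations between unrelated genes therefore have spread
  $\approx 1/\sqrt{n-1}$, not $1/\sqrt{n(n-1)/2}$. This drives every
  power consideration below: with 12 clusters, chance correlations reach
  0.5; with 60 clusters they rarely exceed 0.25. The method is built for
  atlases with dozens to hundreds of clusters.

**Edge calling.** Edges are the top `quantile` fraction of gene pairs by
*signed* correlation — coexpression here means positive coregulation, and
anti-correlated pairs are excluded (configurable in principle by ranking
on a transformed weight; the package ranks signed $r$). Exactly
$\lceil q\,\binom{g}{2} \rceil$ edges are returned for $g$ paired genes;
genes with zero-variance profiles cannot be ranked and are excluded with
a report. Ties at the cutoff are broken by canonical (lexicographic) pair
order so edge sets never drift between runs. Defaults follow the study
settings: $q = 0.05$ for a full network, $q = 0.20$ for the smaller
species-specific networks.

**Selective networks.** A gene enters a selective network when its mean
CPM over target cells is at least `minRatio` (default 1.2, i.e. "at
least 20% overexpressed") times the mean over control cells, boundary
inclusive: a gene at exactly 1.2× is retained. The ratio uses raw means;
a pseudocount argument exists (default 0) but is off because adding it
would move the 1.2 boundary — a gene at 120 vs 100 CPM must pass.
All-zero genes never pass.

**Motif filtering.** All connected 3-node subgraphs (open 2-paths and
triangles) are enumerated; the filtered network keeps genes with multiple
systematic interactions — degree ≥ 2, which for a simple graph coincides
with centering an open 2-path — and then only the edges among retained
genes, dropping retained genes left edgeless so the result is a
well-formed network. A bare path A–B–C therefore filters to an empty
network by design.

**Modules.** Communities are found by greedy modularity maximization
(Clauset–Newman–Moore) on the unweighted graph, with the merge dendrogram
cut at maximal modularity and ties broken toward fewer communities
(plain CNM stalls on zero-gain merges — a clique would otherwise split
off a singleton). Node order is canonicalized first, so partitions are
deterministic. Weighted or multi-resolution detection is out of scope.

**Relative connectivity.** Observed degree divided by the node's mean
degree across `nRandom` uniform $G(n,m)$ random graphs on the same node
and edge counts. The null is size-matched but *not* degree-preserving —
a degree-preserving null would force every ratio to 1.

## 2. Cross-species conservation

An interaction is conserved when its orthologue-mapped counterpart exists
in all three species networks (human, macaque, mouse; human identifiers
are the reporting reference). Orthologue tables must be strictly
one-to-one; genes without a complete triple are ignored.

The null model randomizes **all three** species networks per replicate —
a symmetric null; randomizing a single network would condition on the
other two and give a narrower (less honest) null — using degree-preserving
double-edge swaps with $10 \times |E|$ attempted swaps per replicate, a
standard mixing heuristic. Replicate $r$ uses seed $\text{seed} + r$, so
results are independent of execution order. The score is
$((N_\mathrm{true}/N_\mathrm{random}) - 1)\times 100$ with
$N_\mathrm{random}$ the **mean** of the null counts (the mean, not the
median, is what a count-ratio score normalizes by); when the null mean is
zero the score is reported as undefined (`NA`), never infinite. Per-gene
"expected" conserved degree is the mean over replicates of that gene's
conserved degree; empirical p-values use the add-one correction
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\mathrm{random})$ so no
gene gets $p = 0$ at finite replication; genes are called significantly
conserved at $p < 0.05$. Gene-set conservation densities reuse the exact
same replicates (they are stored in the result object), so observed and
null densities are always computed under one randomization stream.

## 3. Differential expression and variability

Class comparisons use the two-sided Wilcoxon–Mann–Whitney rank-sum test
on CPM, with exact enumeration of all $\binom{m+n}{m}$ assignments when
both groups have ≤ 8 observations (handling ties by permuting the
observed values) and the normal approximation with tie and continuity
correction otherwise. Log2 fold changes use pseudocount 1 CPM; multiple
testing is Bonferroni by default (Benjamini–Hochberg available);
significance requires adjusted $p < 0.05$ and $|\log_2 FC| > 0.25$.
These two thresholds are conventions of the standard single-cell
toolchain rather than derived quantities, and both are arguments.

Variability flags apply the twofold rule at cluster level: a gene is
"up" in a cluster when its mean there exceeds twice its median across
cluster means, "down" below half. The median is over cluster means, not
over cells, because the heatmap this rule supports reports cluster
averages. Per-class variability percentages count clusters flagged in
either direction by default, with a `direction` argument to restrict to
up or down only — the underlying convention is ambiguous, so both
readings are available. Cluster similarity uses cosine distance with
average linkage; cosine is scale-invariant, so cluster depth differences
do not reshape the dendrogram, and zero profile vectors are an error
rather than an arbitrary distance.

## 4. The synthetic-data generator

Counts for gene $g$ in a cell of cluster $k$ are negative binomial with
mean
$\mu_{gk} = \text{baselineMean} \cdot B_{gk} \cdot M_{m(g),k} \cdot O_{gk}$
and shared size parameter (`dispersion`), then zeroed independently with
probability `dropoutRate`. $B_{gk} \sim \text{lognormal}(0, 0.3)$ is
background cluster-to-cluster heterogeneity; each planted module $m$
shares one latent factor
$M_{m,k} \sim \text{lognormal}(0, \log(\text{effectSize}))$ per cluster,
which is exactly what makes module genes' cluster profiles correlate
(`effectSize = 1` plants nothing); $O_{gk}$ applies a fold ≥ 1 to genes
of an overexpressed set in clusters of its target class. Defaults
(`baselineMean = 5`, `dispersion = 2`, `dropoutRate = 0.3`) give
overdispersed, zero-inflated counts of realistic sparsity for
single-nucleus data. Cells are assigned to clusters round-robin; every
configuration must give each cluster at least 20 cells, keep module gene
sets disjoint, use at least 3 clusters and cover all three classes.

**Species triplets.** Three datasets share one configuration; conserved
structure enters only through shared module membership (each species
draws its own latent factors — conservation means shared *regulatory
grouping*, not shared realized expression), with independent noise seeds
per species. Conserved modules get sizes from the greedy decomposition of
`nConserved` into binomial coefficients (100 → sizes 14, 4, 3; within-pair
counts are exact). The remaining genes form a common pool that *every*
species partitions into its own planted modules with exactly
`nSpeciesPrivate` within-module pairs, the three partitions mutually
pair-disjoint (strided-permutation construction, verified at build time).
Covering all pool genes in every species matters: a gene left
structureless in a species has deflated profile variance, and rank-based
edge calling then concentrates spurious edges on precisely those genes —
in real transcriptomes essentially every gene belongs to some regulatory
program in every species, and the generator mirrors that.

**What the generator does not emulate:** realistic read-depth and
library-size distributions, gene-length and GC effects, batch structure,
doublets, ambient RNA, expression-dependent dropout, or the upstream
clustering procedure itself. Passing tests on this generator therefore
demonstrate the correctness and calibration of the pipeline's own
machinery — exact edge counts, preserved degree sequences, recovery of
planted structure at stated effect sizes, a centered permutation null —
not that any particular biological dataset will show such structure.

## 5. Validation fixtures and their sizes

The test suite and the acceptance script exercise the pipeline end to end
at sizes chosen by power analysis of the transform (the $1/\sqrt{n-1}$
null spread above), not by runtime convenience alone:

- *Module recovery*: 160 genes × 1500 cells × 60 clusters, three planted
  20-gene modules at effectSize 2, top 5%. Sixty clusters puts chance
  gene–module alignments ($\sim 1/\sqrt{59}$) far below planted
  correlations (~0.8), and 160 genes makes the 570 planted pairs ≈ 4.5%
  of all pairs, so the called top 5% sits in a genuinely non-random tail —
  the regime the full-data threshold is meant for.
- *Conserved-edge recovery*: 71 genes (21 conserved-module genes + 50
  pool genes carrying ten private quintets per species) × 600 cells × 24
  clusters, top 20%. The chance that a noise pair lands in the top 20% of
  all three species scales with the cube of the noise-slot fraction and
  linearly with the pair count, so the gene complement is exactly the
  planted structure and nothing more.
- *Null calibration*: a 200-gene triplet (larger conserved counts mean
  smaller relative Poisson noise in the permuted-orthologue score), 50
  orthologue permutations × 20 degree-preserving replicates.
- *Pipeline determinism*: 2000 genes × 3000 cells × 12 clusters, the
  full stage chain run twice and compared byte-for-byte.

## 6. Degenerate inputs and edge cases

Zero-count cells: kept, all-zero, reported. All-zero genes: dropped from
fold-change profiles with a report; flagged neutral in variability.
Zero-variance profiles: excluded from correlation ranking. Networks whose
degree sequence admits no double-edge swap (e.g. a triangle): returned
unchanged with a notice. Empty selective sets: a warning, not an error.
Edgeless networks: module detection refuses; singleton communities are
reported separately from modules. Orthologue tables with any duplicated
identifier: rejected outright.

## 7. Known limitations

Quantities reported by the original study at atlas scale (cell counts,
curated gene-set sizes, specific p-values, the fraction of significantly
conserved genes in real data) depend on external data resources and are
not reproduced here. Pearson correlation on fold-change profiles inherits
the cluster count as its effective sample size; with few clusters the
network stage is underpowered no matter how many cells are sequenced.
Greedy modularity has a resolution limit and can absorb weakly attached
nodes into large communities. The conservation score normalizes by the
null mean; for very sparse networks with near-zero null counts the score
is unstable and is reported as undefined at exactly zero.
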