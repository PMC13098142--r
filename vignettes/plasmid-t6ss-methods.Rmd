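---
title: "Detecting and tracing plasmid-encoded T6SSs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracing plasmid-encoded T6SSs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t6sscope)
```

`t6sscope` studies how type VI secretion systems are distributed over, and
exchanged between, plasmids and chromosomes. This vignette is the package's
own account of the models it implements, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the places
where a genuine design choice had to be made.

## The detection model

The unit of analysis is an *ordered gene table*: one row per gene on a
replicon, with a 0-based ordinal, a label, and a category. All detection
rules count genes, not base pairs, because the cluster criterion in the
MacSyFinder tradition is expressed in intervening genes. Spans are
half-open `[start, end)` in ordinal space.

`scan_clusters()` groups consecutive T6SS hits whenever the number of genes
strictly between them is at most `max_intervening_genes` (default 20,
strand-agnostic), then discards groups with fewer than `min_distinct_genes`
(default 2) distinct components, demoting their members to isolated-gene
candidates. Classification is by *distinct* component count — a cluster
with eight hits but seven distinct components is incomplete — because the
completeness notion refers to how much of the machine is present, not to
copy number. The completeness threshold is 8 of the 14 canonical
components; clusters whose distinct set is exactly one of
{tssD,tssI}, {tssD,evpJ}, {tssI,evpJ}, {tssD,tssI,evpJ} are orphan islands
(hcp-vgrG, hcp-PAAR, vgrG-PAAR, hcp-vgrG-PAAR).

Two island types cannot come out of the scan: hcp-hcp and vgrG-vgrG have
one distinct component and are filtered by the ≥2-distinct rule. They are
reconstructed in `find_isolated_genes()` by pairing same-component isolated
hits that lie within the same gap threshold of each other. Isolated
*hcp*/*vgrG* genes are everything left over. Together this gives the
partition property: every T6SS hit is either a cluster member or an
isolated gene, never both, never neither.

Replicons are linear by default; `circular = TRUE` merges a cluster
spanning the origin. Annotation tables as exported by annotation pipelines
are linear, so the default is off.

Subtype assignment (i/ii/iii) is a lookup of user-supplied diagnostic
marker labels in priority order. No marker catalogue ships with the
package: the diagnostic markers are a property of the HMM profile set used
upstream, not of the gene-order analysis, so hard-coding one would invite
silent mismatches.

## Replicon traits

A plasmid is a **megaplasmid** when its length reaches 5% of the median
genome size of the host's taxonomic family, boundary inclusive. The family
median is metadata supplied by the caller — the package performs no
database lookups. **Transmissibility** is the standard trichotomy:
relaxase and mating-pair formation system ⇒ conjugative; relaxase only ⇒
mobilizable; otherwise non-transmissible. The fourth flag combination (MPF
without relaxase) is not named by the trichotomy; it is classified
non-transmissible — such a plasmid cannot initiate its own transfer — and
flagged with a warning so it never disappears silently.

GC divergence is `100 * (plasmid GC − host chromosome GC)` in percentage
points, summarized per cohort by medians. Hosts with several chromosomes
should supply the length-weighted mean GC.

For cohort analysis each plasmid belongs to exactly one group:
`complete_T6SS` (at least one complete system, regardless of islands),
`orphan_only` (islands or isolated genes but no complete system), or
`neither`. Proportions of an empty group are reported as `NA`, not zero.

## MGE neighborhoods

`window_scan()` looks `window` genes (default 20) on *each side* of a locus
span, excluding the span itself; that is the symmetric reading of
"around the locus". MGE genes inside the span are reported separately and
do not set the `has_mge` flag, so a transposase embedded in a cluster is
not mistaken for an adjacent element. Windows truncate at replicon ends and
wrap on circular replicons. Family-level association between complete
clusters and orphan islands uses per-family 2×2 Fisher tests with BH
correction across families; families never observed in any window are
skipped rather than tested vacuously.

## Networks and communities

The transfer network is bipartite: replicon nodes vs homologous-protein-
cluster (HPC) nodes, one edge per (replicon, HPC) pair regardless of
protein multiplicity. Louvain modularity is not well defined on a
bipartite graph, so community detection runs on the weighted replicon
projection (edge weight = number of shared HPCs); this choice is recorded
in the function documentation and is the default analysis route. The
resolution parameter defaults to 1 and a seed is required, making the
heuristic reproducible. Singleton replicons are their own communities.

Host-range grades walk the taxonomy from species upward and report the
shallowest rank at which all community members agree: I (same species)
through V (same class), with `beyond_V` flagged when even the class rank
disagrees. PTU core proteomes are HPCs present in ≥ 80% of member
replicons (inclusive). ANI networks admit an edge only when the aligned
fraction of the shorter replicon is ≥ 0.5 (inclusive), with ANI as edge
weight; self-pairs are dropped and duplicate orientations collapsed.

## Patristic distances and ancestral states

`patristic_matrix()` computes tip-to-tip path lengths by a post-order
sweep that merges child-subtree depth lists at each internal node, so each
pair is combined exactly once at its most recent common ancestor; the test
suite checks it against `ape::cophenetic.phylo` as an independent oracle.

`closest_homolog()` reports, per plasmid tip, the minimum distance to any
tip of each compartment. When tip metadata carries identity-cluster ids
(near-identical proteins clustered at high identity/coverage), a companion
of the target compartment in the same cluster forces a distance of zero —
near-identical sequences in different genomic contexts are zero
evolutionary distance apart even if the tree, built on cluster
representatives, places them elsewhere. Without an identity-cluster
column the rule is inactive.

Ancestral reconstruction treats the genomic compartment as a two-state
character evolving under F81:

$$P(i \to j, t) = \pi_j + (\delta_{ij} - \pi_j)\, e^{-t/\nu},
\qquad \nu = 1 - \sum_k \pi_k^2,$$

with ν normalizing the expected substitution rate to 1. Equilibrium
frequencies default to the observed tip-state proportions (configurable to
0.5/0.5); no rate-scaler optimization is performed — the normalized model
keeps branch lengths in substitution units as supplied. Marginal
posteriors come from one post-order pass (partial likelihoods) and one
pre-order pass (outside likelihoods). State selection uses the MPPA rule:
add states in decreasing posterior order while the expected Brier-style
prediction error $f(k) = 1 + (1 - 2\sum_{\text{top-}k} p)/k$ keeps
decreasing. For two states this reduces to a closed form: keep both states
whenever the larger posterior is below 0.75; exact ties keep both. Ties
keeping both states is deliberate — an ambiguous node should not
manufacture a transition.

A branch counts as one transition exactly when the parent and child MPPA
sets are disjoint. This undercounts by construction: back-and-forth
switches on one branch cancel, and ambiguous nodes contribute nothing.
That conservatism is why transition recovery is validated at a *low*
switch rate (0.02 per unit branch length on trees of 100 tips with mean
branch length 1), where the recovered mean is within 20% of the planted
mean over 100 replicate trees; at high switch rates the inferred count is
a floor, not an estimate.

Degenerate inputs are handled explicitly: an all-zero-branch-length tree
with conflicting tip states is rejected as unidentifiable, and a
single-state tip set produces a (properly normalized) near-degenerate
equilibrium rather than a division by zero.

## Statistics

Fisher's exact test, BH correction and the Mann–Whitney U test are
delegated to base R's `fisher.test`, `p.adjust` and `wilcox.test` behind
thin wrappers that fix the package conventions: the reported odds ratio is
the sample odds ratio $ad/bc$ (with infinity on a zero denominator), not
the conditional MLE; the Mann–Whitney switch point between the exact
rank-permutation path and the tie/continuity-corrected normal
approximation is $n_x n_y \le 400$ with no ties. Every wrapper is checked
in the test suite against an independent enumeration oracle
(hypergeometric enumeration over the margin-constrained table family, the
step-up formula, full rank-permutation enumeration).

Sidedness deserves a note. Cross-tabs of cohort traits are tested
two-sided by default. The transmissibility comparison between
orphan-island plasmids and complete-system plasmids is the one headline
table where the published statistic corresponds to the one-sided
(orphan-enriched) test; the acceptance script therefore computes that
table one-sided, and this vignette is the record of that convention.

The gene-presence association is a *naive* GWAS: per-gene two-sided Fisher
with BH across genes, no population-structure correction. Constant genes
get p = 1 and a flag. Under label permutation the realized FDR at 0.05
stays within Monte-Carlo error of nominal (checked over 200 simulated
datasets). COG enrichment gates on both adjusted p < 0.05 and odds ratio
> 1, so strong depletion is never reported as enrichment.

## The synthetic-data generator

`simulate_replicons()` emulates the *inputs* of the analysis — annotation
tables with planted features — not bacterial genomes. Defaults describe
the cohort the package targets: ~30% of replicons carry a planted complete
cluster (8–14 distinct components, inter-hit gaps 0–3), ~25% an orphan
island with type weights favouring hcp-vgrG, ~15% an isolated gene; half
of planted loci get an IS gene within the 20-gene window; plasmid GC runs
3.5 percentage points (SD 1.5) below the host chromosome; plasmid sizes
are log-normal around 150 kb and chromosomes around 4.5 Mb, with family
median genome sizes fixed per host family. Planted features are separated
by more than the detection gap, so noise-free recovery is exact by
construction — which is precisely what makes the recovery suite a test of
the scanner rather than of luck. Each replicon draws from its own RNG
stream derived from (seed, replicon id): enlarging a simulation never
perturbs the replicons already present.

What the generator does **not** emulate: overlapping or nested loci,
annotation errors and missed hits, pseudogenization, strand structure of
operons, within-cluster gene order conventions, or realistic plasmid size
distributions per family (the size parameters are free choices, not
calibrated claims). Passing recovery tests therefore demonstrates the
algorithms are correct on clean inputs, not that detection on real,
noisy annotation is error-free.

`simulate_compartment_tree()` evolves the compartment character along a
random binary tree as a continuous-time symmetric two-state chain,
recording every true switch; `simulate_hpc_table()` plants transfer
communities whose members share a fixed number of HPCs, with noise adding
only private singleton clusters (spurious protein clusters never link
replicons — linking noise would change the planted truth, not blur it).

## Validation problem sizes

The test suite validates the scanner against a brute-force gap-merge
oracle on 1000 random tables of up to 500 genes; Fisher's test against
full enumeration for every 2×2 table with N ≤ 30; pruning posteriors
against exhaustive ancestral-assignment enumeration on 200 random trees of
up to 10 tips (relative tolerance 1e-10); planted-feature recovery on a
1000-replicon simulation; community recovery over 20 seeds at zero and
mild noise; transition recovery over 100 trees; GWAS calibration over 200
null datasets. These sizes were chosen so the whole suite exercises every
code path at depth while remaining comfortable to run on a laptop.

## Known limitations

* Subtype calling depends entirely on the user's marker table.
* The megaplasmid rule needs a family median genome size; replicons
  without one are excluded from megaplasmid tallies rather than guessed.
* Louvain on the projection can merge planted communities connected by
  chance homology if noise is made to link replicons; the generator's
  noise model deliberately does not do this.
* Transition counts are conservative (see above) and carry no uncertainty
  quantification; they are counts of confidently reconstructed switches,
  not rate estimates.
* The GWAS is naive by design; with strong population structure its FDR
  guarantee does not transfer to real cohorts.
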