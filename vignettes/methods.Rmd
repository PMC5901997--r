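---
title: "Methods: comparing microscopy and metabarcoding views of a diatom biofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing microscopy and metabarcoding views of a diatom biofilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A diatom biofilm — say, on the carapace of a sea turtle — can be profiled
in two very different ways. Under the light microscope one identifies and
counts siliceous frustules (valves) to a fixed depth, typically 400
valves, yielding a morphospecies-by-sample table of relative abundances.
Alternatively, a short barcode (a 312 bp fragment of the chloroplast
gene *rbcL*) is amplified and sequenced, reads are clustered into
operational taxonomic units (OTUs) at 95% similarity, and the result is
an OTU-by-sample read-count table.

The two channels disagree systematically, for reasons that are
biological, not technical noise:

* **Dead-frustule carryover.** Microscopy counts every frustule,
  including skeletons of dead cells glued into the biofilm; their DNA is
  gone, so metabarcoding never sees them.
* **Biovolume-dependent copy number.** The number of *rbcL* copies in a
  cell scales with its biovolume. A large cell (~1500–2000 µm³)
  contributes orders of magnitude more template than a tiny one
  (~15–20 µm³), while microscopy counts each as one valve.
* **Cryptic diversity.** A single morphospecies can hide several
  genetically distinct lineages. Microscopy cannot separate them;
  metabarcoding resolves them as distinct OTUs — and those lineages can
  have different ecologies, occupying different host individuals.

This package implements the full comparison pipeline (community
statistics on both channels), the cryptic-structure inference that links
pairwise OTU genetic distance to co-occurrence across hosts, an
ecological-guild profiler, and a synthetic-data generator that encodes
exactly the bias mechanisms above so that every stage can be verified
against ground truth.

## Community statistics

Both channels are expressed in relative abundances (percent per sample)
before any statistic is computed. Dissimilarity between samples is
Bray-Curtis, \(d(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} +
x_{jk})\), which is 0 for identical compositions and 1 for disjoint
ones.

**Ordination.** `nmds()` is non-metric multidimensional scaling
minimizing Kruskal's stress-1,
\(\sqrt{\sum(\hat d_{ij} - e_{ij})^2 / \sum e_{ij}^2}\), where the
disparities \(\hat d\) are the isotonic (pool-adjacent-violators)
regression of the configuration distances \(e\) on the rank order of the
input dissimilarities, with Kruskal's primary treatment of ties (tied
input distances are free to fit). The first start is classical metric
scaling; the remaining `n_restarts - 1` (default 19) are seeded random
configurations. Refinement uses the Guttman transform with step halving,
so accepted iterations never increase stress; convergence is declared
when the stress improvement drops below `tol` (default 1e-7) or after
`max_iter` (default 300) iterations. When all off-diagonal distances are
equal the configuration is arbitrary; the result is flagged `degenerate`
and the stress contract is void.

**Partitioning.** "k-means on Bray-Curtis distances" is mathematically
ill-posed — means live in Euclidean space, distances do not — so
`cluster_k_groups()` implements PAM-style k-medoids directly on the
distance matrix (BUILD initialization, then SWAP until no improving
swap, best of `n_restarts` by total within-cluster distance to medoid).
With the intended sample size (7 hosts, k = 3) the tests verify the
result against the exhaustive optimum over all medoid subsets. If a
Euclidean k-means is wanted it can be run on the NMDS coordinates.

**Mantel test.** Pearson correlation of the strictly-lower triangles,
with joint row/column permutation of one matrix; two-sided on |r|. With
7 or fewer samples all \(n!\) permutations are enumerated (5040 for
n = 7), making the p-value exact; otherwise 9999 random permutations are
used with the add-one estimator \(p = (1 + \#\{|r^*| \ge |r|\})/(1 +
N)\). Both r and r² are reported, since published "r² = x%" values are
ambiguous between the two conventions.

**Channel separation.** `compare_distance_sets()` reports the
conventional pooled-variance two-sample Student t test on the two
triangles *and* a permutation p-value obtained by shuffling entries
between the pooled triangles. Pairwise distances sharing a sample are
not independent, so the parametric p is kept for comparability with
published practice and the permutation p as the honest alternative. The
t statistic is computed directly (not via `t.test`) so that
zero-variance triangles yield ±Inf rather than an error.

## Genetic distances and OTUs

`mcl_distance()` computes the Tamura-Nei (TN93) distance with base
frequencies pooled over **all** sequences in the alignment — the
"composite" element of the maximum-composite-likelihood distances
popularized by MEGA (per-pair frequencies are available with
`pooled = FALSE`). With proportions \(P_1\) (A↔G), \(P_2\) (C↔T), and
\(Q\) (transversions) over the pair's effective sites:

\[d = -\frac{2\pi_A\pi_G}{\pi_R}\ln w_1 - \frac{2\pi_C\pi_T}{\pi_Y}
\ln w_2 - 2\Big(\pi_R\pi_Y - \frac{\pi_A\pi_G\pi_Y}{\pi_R} -
\frac{\pi_C\pi_T\pi_R}{\pi_Y}\Big)\ln w_3\]

with \(w_1 = 1 - \pi_R P_1/(2\pi_A\pi_G) - Q/(2\pi_R)\), \(w_2\)
symmetric for pyrimidines, and \(w_3 = 1 - Q/(2\pi_R\pi_Y)\). Sites with
a gap or `N` in either member of a pair are excluded for that pair only
(pairwise deletion — the conventional default of the tool the formula
mirrors; stated here because source descriptions are typically silent on
it). Pairs whose log arguments are non-positive are saturated and
reported as `NA`. Under balanced frequencies and uniform substitution
classes the formula collapses to Jukes-Cantor \(-\tfrac34\ln(1-4p/3)\),
which the tests exploit as a closed-form oracle; the implementation also
agrees with `ape::dist.dna(model = "TN93")` to machine precision.

`greedy_cluster()` is classic abundance-ordered greedy centroid
clustering: sequences in decreasing abundance (ties broken
lexicographically), each joining the first centroid at identity ≥ the
threshold (default 0.95), else founding a new OTU. Identity is the
fraction of identical effective sites, so the operation assumes aligned
or equal-length input; the read-curation pipeline that precedes OTU
clustering in real studies (quality trimming, chimera removal) is out of
scope here, and the generator produces indel-free sequences so the
identity map is exact.

`assign_taxonomy()` grants a rank by best-reference identity with
configurable cutoffs (defaults 0.97 species / 0.95 genus / 0.90 family /
0.80 class, else unassigned). These cutoffs are package defaults, not
literature constants — published studies rarely state theirs — and rank
is by construction monotone in identity. `nj_tree()` wraps standard
neighbor joining (via ape) with negative branch lengths clamped to zero,
as the lightweight substitute for likelihood phylogenies, which are
deliberately not reimplemented.

## Cryptic-structure inference

The core inference chain asks: do genetically similar OTUs co-occur on
the same hosts?

1. `spearman_cooccurrence()` — Spearman rank correlation (average ranks
   on ties) between every pair of OTU abundance profiles across hosts.
2. `fit_distance_cooccurrence()` — OLS of pairwise co-occurrence on
   pairwise genetic distance; a negative slope means close OTUs
   co-occur. Because pairs sharing an OTU are dependent, significance is
   Mantel-style (joint row/column permutation), exhaustive for ≤ 7
   OTUs.
3. `estimate_threshold()` — published analyses typically read the
   co-occurrence threshold off a scatter plot; here it is an explicit
   estimator. Candidates are midpoints between consecutive sorted unique
   distances; the winner maximizes the pooled two-sample t statistic
   between sub- and supra-threshold correlation sets (ties toward the
   smallest candidate, both sides non-empty, zero-pooled-variance
   splits counting as infinite separation). When a clean distance gap
   separates co-occurring from co-excluding pairs, the estimator returns
   the midpoint of that gap — the algorithmic equivalent of the visual
   reading.
4. `cluster_below_threshold()` — single linkage: groups are connected
   components of the graph with edges at distance < threshold, matching
   the "clustered below the threshold" language of the underlying
   analyses; group count is non-increasing in the threshold.
5. `coexclusion_test()` — statistic mean(within-group rho) −
   mean(between-group rho), p by random relabeling of group membership
   with sizes preserved (one-sided). Note the attainable minimum p is
   limited by partition symmetry: with equal-sized groups, relabelings
   that permute whole groups reproduce the same partition.

## The synthetic world

`synthetic_params()` defaults **are** the stated world of the intended
application, not knobs to be tuned:

| parameter | default | meaning |
|---|---|---|
| `n_hosts` | 7 | host individuals (turtles) |
| `n_morphospecies` | 15 | gives per-host richness ≈ 15, inside the observed 15–24 |
| `n_cryptic_lineages` | 60 | lineages hidden in the focal morphospecies |
| `n_groups` | 4 | habitat groups among those lineages |
| `seq_length` | 312 bp | rbcL barcode length |
| `delta_within` / `delta_between` | 0.015 / 0.10 subst/site | pairwise divergence targets; the gap brackets the empirically reported 0.04 threshold |
| `delta_morpho` | 0.30 | morphospecies-ancestor divergence; keeps cross-species TN93 defined and far above `delta_between` |
| `biovolume_range` | 15–2000 µm³ (log-uniform) | the small-*Labellicula* to large-*Entomoneis* span |
| `beta` | 1 | copy number ∝ biovolume |
| `phi` | 0.2 | dead-frustule weight in the microscopy mixture |
| `sigma` | 0.1 | lognormal co-occurrence noise |
| `valves` / `reads` | 400 / 30 000 | channel depths |
| `dirichlet_alpha` | 0.5 | community unevenness (dominance-prone) |

Values with no published counterpart (`phi`, `beta`, `sigma`,
`delta_morpho`, `dirichlet_alpha`) were chosen once, for realism, and
are documented here rather than revisited: `beta = 1` is the simplest
reading of "copy number depends on biovolume"; `phi = 0.2` makes dead
carryover visible but not dominant; `sigma = 0.1` keeps within-group
co-occurrence strong, which is what a *stated* co-occurrence structure
means; Dirichlet 0.5 produces the dominance structure typical of real
biofilm counts. The dead pool is uniform over morphospecies by default
(any fixed pool would do; it is configurable).

Sequences are built on a star-like genealogy: a random root,
morphospecies ancestors at `delta_morpho`, group ancestors at
`(delta_between - delta_within)/2`, and lineage tips at
`delta_within/2`, each step substituting an **exact** `round(rate × L)`
number of random sites. Divergence targets are thereby hit rather than
merely expected — with Binomial mutation counts the realized
between-group minimum occasionally fell into the within-group range,
which is a property of sloppy simulation, not of the world being
modeled. Mutations are substitutions only (no indels), so the alignment
is the identity map and identity/distance computations are exact.

Latent abundances: per host, a Dirichlet composition over
morphospecies; per host × morphospecies, one habitat group is active
(uniformly chosen among the groups present in that morphospecies —
single-group morphospecies are always active), its lineages receiving
Dirichlet(1) sub-weights perturbed by lognormal `sigma`. Microscopy is a
multinomial over morphospecies from the living composition mixed with
the dead pool at weight `phi`; metabarcoding is a multinomial over
lineages with probabilities ∝ abundance × biovolume^`beta`.
`expected_channel_bias()` provides the closed-form infinite-depth
expectations used as the generator's oracle in the tests.

**What a green test does and does not establish.** The generator
reproduces the *mechanisms* of channel disagreement, not any particular
dataset: it has no PCR or sequencing error, no chimeras, no indels, no
taxonomic misidentification, and its co-occurrence structure is sharper
than field data (groups are strictly exclusive within a host ×
morphospecies). Recovery results on it therefore establish that the
estimators are correct and coherent — not that they would recover
structure at these rates from real biofilm samples.

## Design decisions made where the design was open

* **Recoverable truth.** Lineages of the same habitat group but
  different morphospecies are genetically distant, so the partition the
  genetic-distance chain can recover is the morphospecies × group cell
  partition. With the default single focal morphospecies the two
  coincide on the focal subset, mirroring the restriction of the
  empirical analysis to one species' OTU neighborhood; the generator
  stores both labelings (`group`, `cluster`).
* **Greedy step in the end-to-end chain.** With `delta_within = 0.015`,
  within-group identity is 98.5%, so a 95% greedy step would collapse
  each cryptic group to a single OTU and erase the co-occurrence signal
  the threshold estimator needs. The end-to-end recovery tests therefore
  run that stage at similarity 1 (dereplication). Real 95% OTU sets
  demonstrably retain distinct sub-0.04 lineages because clustering
  operates on noisy reads, not on clean lineage haplotypes; collapsing
  is an artifact of desk-scale cleanliness.
* **Percent tables at printed precision.** Published percentage tables
  round to one decimal, so rows can sum to 100 ± 0.1; the percent-mode
  validator accepts that window, and `guild_profile()` echoes
  percent-mode input at input precision instead of renormalizing, so
  printed worked examples reproduce exactly. Tables produced by
  `to_relative_abundance()` still sum to 100 to machine precision.
* **Rounding of printed averages** is half-away-from-zero, the
  convention under which 209 095 / 7 prints as 29 871.
* **Seeding.** The pipeline expands one global seed into per-stage seeds
  by fixed offsets (documented in `pipeline_config()`), so stages are
  reproducible independently and the two channel sub-pipelines are
  order-independent by construction.

## Known limitations

* NMDS uses monotone regression over all pairs at once; very large
  distance matrices (thousands of items) would want a compiled
  implementation.
* The threshold estimator assumes a two-regime structure; smoothly
  decaying co-occurrence yields a defensible but less interpretable
  split (the full candidate scan is returned for inspection).
* `assign_taxonomy()` compares OTUs to every reference; for reference
  libraries of realistic size a k-mer prefilter would be the next step.
* The guild lookup ships genus-level defaults for biofilm genera; it is
  configuration, and size-at-genus rules cover only the cases where
  guild genuinely switches with cell size.
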