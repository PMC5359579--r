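---
title: "Community phylogenetics of clone-library surveys: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community phylogenetics of clone-library surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocomm)
```

`phylocomm` analyses multi-habitat 16S rRNA clone-library surveys: a
site-by-OTU count table, a rooted phylogeny over the OTUs, and per-site
metadata (habitat class plus pH, salinity, temperature, TOC, TN).  This
vignette documents the statistical models, the tunable parameters and
their defaults, the numerical choices, what the synthetic-data generator
does and does not emulate, and the package's known limitations.

## Sequence selection and OTU clustering

Pooled clone libraries are heterogeneous, so sequences are filtered
before clustering: a record is kept only if its **ungapped** length is
strictly greater than `min_len` (default 700 bp) and its residues contain
no IUPAC ambiguity codes.  The length filter counts residues, not
alignment columns, because the criterion concerns sequence length;
lowercase input is upper-cased on read, and filtering is idempotent.

Pairwise distances are uncorrected p-distances with **pairwise** gap
deletion (columns with a gap in either sequence are dropped for that pair
only) — the conservative convention; a Jukes–Cantor switch exists.  OTUs
are formed by furthest-neighbour (complete-linkage) agglomeration cut at
distance `1 − identity`: two clusters merge only if the maximum pairwise
distance between their members is at or below the cutoff.  The package
uses 0.97 identity for diversity analyses and 0.90 for networks, both
configurable.  Complete linkage guarantees that a coarser cutoff can
never produce more OTUs than a finer one on the same data.  Cluster
agglomeration is delegated to `stats::hclust`, whose merge order is
deterministic; OTU ids (`OTU_0001`, ...) are assigned in order of first
member appearance.

## Alpha diversity

The Shannon–Wiener index is `H' = -Σ p_i log p_i` in **nats** (natural
logarithm) by default — consistent with the magnitudes conventionally
reported for libraries of hundreds of clones — with the base exposed as
an option.  Faith PD is the branch-length sum of the minimal subtree
spanning a community's OTUs **including the stem to the root** (the
classic definition); an `include_root = FALSE` variant is provided.

Clone libraries differ widely in depth (tens to hundreds of clones), and
PD is strongly depth-dependent, so `rarefied_pd()` draws `depth` clones
without replacement from a habitat's pooled clones, computes the PD of
the OTUs hit, and repeats `n_subsamples = 1000` times with a seeded
generator; the mean and sd are reported.  The default depth is the
smallest habitat clone total among the habitats compared.  A
`diversity_table()` convenience assembles per-habitat library counts,
clone counts, Shannon mean ± sd, plain PD and rarefied PD; libraries
containing a single OTU can be excluded from the Shannon mean via
`exclude_single_otu` (they carry no evenness information).

## Phylogenetic species variability

PSV measures whether co-occurring taxa are more closely related than
chance.  With `C` the phylogenetic correlation matrix — `C_ij` = shared
root-to-tip branch length of tips i and j divided by their mean
root-to-tip depth — the statistic is
`PSV = (n·tr(C) − ΣC) / (n(n−1))` over the present tips: 1 for a star
phylogeny (no shared ancestry) and approaching 0 as relatedness
increases.  Non-ultrametric trees are accepted; for them the shared-over-
mean-depth ratio is an approximation, documented as such.

Two canonical community nulls are implemented, since randomization
schemes for PSV differ between studies:

* **null1** — shuffle tip labels across the whole phylogeny, preserving
  each habitat's membership pattern but destroying phylogenetic
  structure;
* **null2** — redraw each habitat's OTU set uniformly at random from the
  full OTU pool, preserving observed richness.

The one-sided p-value for clustering uses the add-one correction,
`p = (1 + #{null ≤ observed}) / (1 + n_rand)` with `n_rand = 999`, so p
is never exactly zero.  Because it is ambiguous whether significance
should be judged per habitat or for the across-habitat mean, both are
reported (per-habitat rows plus a pooled-mean comparison attribute).

## Beta diversity

Weighted UniFrac between two libraries is
`W(A,B) = Σ_i b_i |p_i^A − p_i^B|` over branches i, where `p_i^X` is the
fraction of library X's clones whose OTUs descend from branch i.  The
**normalized** variant (divide by `Σ_i b_i (p_i^A + p_i^B)`) is the
default: it bounds distances in [0, 1] as in the original weighted
UniFrac definition; the raw variant is selectable.  Each clone library is
one community; pooling co-located libraries is a site-grouping decision
left to the metadata.

PCoA is classical metric scaling: Gower double-centering of the squared
distances, eigendecomposition, axes ordered by eigenvalue.  Explained
fractions are relative to the **positive** eigenvalue sum, and the
magnitude of negative eigenvalues is reported separately rather than
corrected; a Lingoes correction flag exists.

PERMANOVA follows the distance-based decomposition: term sums of squares
are traces of hat-matrix projections of the Gower-centered matrix,
`pseudo-F = (SS_term/df_term)/(SS_resid/df_resid)`, and p-values come
from permuting site labels (`n_perm = 1000`, add-one correction).  With
several covariates, terms are assessed sequentially (Type I, in supplied
order) by default — matching single-factor-at-a-time reporting — with a
marginal mode available.  The implementation is cross-checked against
`vegan::adonis2` in the test suite.

## Indicator value analysis

For group g and habitat h, specificity
`A_gh = mean abundance of g in h / Σ_h' mean abundance of g in h'` and
fidelity `B_gh` = fraction of h's sites containing g; `IndVal = A·B`.
The abundance-based (classic Dufrêne–Legendre) specificity is the
default, on the 0–1 scale; a presence-based variant is available.  OTU
tables are converted to within-site relative abundances first, so deep
libraries do not dominate A; a plain abundance matrix is used as
supplied.  Group-level analysis operates on lineage-aggregated
abundances, with OTU-level analysis via `by = "otu"`.

A group's reported IndVal is its maximum over habitats.  Significance
permutes the site→habitat labels (habitat sizes fixed) and compares each
permuted **maximum** IndVal with the observed one — the max-statistic
construction that keeps the test valid for the reported quantity.

## Multivariate regression trees

The MRT relates the site-by-lineage relative-abundance matrix to
environmental covariates by greedy binary partitioning: each node picks
the (covariate, threshold) pair minimizing the total within-child
multivariate sum of squared Euclidean deviations from child means, with
candidate thresholds at midpoints between consecutive sorted covariate
values.  Euclidean geometry on relative abundances is the default (the
convention of the classic MRT software); ties in the split search are
broken toward the first covariate and lowest threshold, making the fit
deterministic.  Sites missing the splitting covariate follow the
majority child; no surrogate splits.

Growth is best-first (the leaf with the largest SS decrease splits
next), which yields a nested sequence of subtrees of every size; size is
then selected by 10-fold cross-validated relative error with the 1-SE
rule, the folds drawn from the seed.  Both the resubstitution explained
variance `1 − Σ_leaf SS / SS_total` and the CV error curve are reported,
since "variance explained" can legitimately mean either.

## Co-occurrence networks

Spearman rank correlations (midrank ties) are computed between the
profiles of all OTUs with total count strictly greater than 5; two-sided
p-values use the t approximation `t = ρ√((n−2)/(1−ρ²))`.  Profiles are
**within-site relative abundances** by default: with library sizes
spanning an order of magnitude, raw count profiles of even independent
OTUs co-rank through library depth (measured mean ρ ≈ +0.33 at 28
sites), which would flood the network with spurious positive edges; the
raw-count variant remains available via `profile = "count"`.

Edges require `ρ > 0.6` **and** `p < 0.01` (strict), positive
correlations only; no multiple-testing correction is applied by default
(Benjamini–Hochberg by flag), and a signed-network flag admits strong
negative correlations.  Topology indices are computed on the unweighted
graph, per connected component: diameter, average path length and the
number of geodesics (counting multiplicity over unordered connected
pairs) are reported for the largest component and component-weighted;
node indices are degree, betweenness (unnormalized geodesic fractions)
and closeness in both the normalized `(n_comp − 1)/Σd` and reciprocal-
farness `1/Σd` conventions, since closeness conventions differ between
network tools.

Module detection is an in-package two-phase Louvain optimizer: local
moves maximizing the modularity gain until none improves, then
aggregation of communities into super-nodes, repeated until Q no longer
increases; the node visit order is shuffled from the seed.  The returned
Q is evaluated from the modularity formula
`Q = Σ_c (e_c/m − (d_c/2m)²)` on the returned partition and is verified
against an independent evaluation (and `igraph::modularity`) in the test
suite.  Module–habitat association uses a two-sided Fisher exact test on
the 2×2 table (OTU in/out of module × detected/undetected in habitat).

## The synthetic community generator

`synth_spec()` defines the generative conditions; its defaults emulate a
six-habitat terrestrial survey of 28 clone libraries (peat 4, soil 2,
hot spring 2, lagoon 13, mangrove 4, estuary 3) over 100 OTUs in 10
lineages, with library sizes log-uniform in [50, 500] clones —
reflecting the order-of-magnitude depth differences typical of pooled
clone-library compilations.

* **Phylogeny** — a seeded pure-birth tree rescaled to unit depth;
  lineages are the `n_lineages` clades of the tree, so lineage identity
  is phylogenetically coherent.
* **Metadata** — habitat-specific covariate distributions: saline
  lagoons/estuaries/mangroves, organic-rich acidic peat, hot springs at
  65 ± 10 °C.
* **Abundances** — per-site expected abundance
  `exp(lineage baseline + lineage×habitat effect + Σ gradient
  coefficient × z-scaled covariate + noise)`, multinomially sampled at
  the library size.  Defaults: baseline sd 1, per-OTU sd 0.5, habitat
  effect sd 1.5, gradient coefficient sd 0.4, overdispersion 0.3.
* **Planted indicator** — lineage L01 exclusive to peat (expected
  abundance zero elsewhere, boosted inside), giving a ground-truth
  IndVal of 1.
* **Planted TOC step** — lineage L02 gains a +3 log-abundance shift at
  sites with TOC > 12 % dw, a ground-truth composition threshold for the
  MRT.
* **Planted pairs** — three OTU pairs share a per-site latent normal
  factor with strength 2.5 (comonotone mixing) and a fixed baseline that
  keeps their expected share near 2%, so zero-count ties stay rare.
  Comonotone mixing was chosen over explicit copulas because it
  guarantees the rank dependence that Spearman detects; at 28 sites the
  implied dependence is strong (latent rank correlation ≈ 0.95),
  matching the "robust correlation" regime the ρ > 0.6 threshold is
  meant to capture.

Exclusivity of planted indicators is absolute: it is applied after all
other effects, so an exclusivity-1 lineage has zero counts outside its
habitat in every realization.  All generators are bit-reproducible from
the spec seed, with each stage drawing from a derived child seed so
stages can be re-run independently.

Two identifiability notes.  First, in the default conditions the
habitat-level covariates are collinear by design (peat is simultaneously
the high-TOC, low-pH, high-TN habitat), so a regression tree may
legitimately express the planted TOC step through pH or TN — exactly as
in real surveys.  The parameter-recovery experiments therefore isolate
the TOC effect by switching off habitat effects and drawing TOC
independently of habitat; only then is "the root split is on TOC" a
well-posed claim.  Second, the generator emulates the *statistical*
structure of a survey, not its biology: no sequence evolution, alignment
error, chimeras, primer bias or compositional interactions beyond
multinomial closure.  Passing tests demonstrate that the estimators
recover planted structure under the stated model — not that the model
captures every property of real clone libraries.

## Numerical choices and degenerate inputs

* Permutation p-values always use the add-one correction and seeded
  generators; every stochastic routine takes an explicit seed and
  restores the caller's RNG state.
* `ρ = ±1` pairs get p = 0 directly (the t approximation degenerates);
  zero-variance profiles yield NA correlations and never form edges.
* Empty sites are excluded with a warning from relative abundance and
  UniFrac; all-zero count vectors are errors for Shannon; PSV requires
  at least 2 tips; PERMANOVA refuses single-group designs and numeric
  covariates with fewer than 3 distinct values.
* PCoA accepts semi-metric distance matrices; negative eigenvalue mass
  is reported, not silently corrected.
* MRT split-search ties break deterministically (first covariate, lowest
  threshold); residual sums of squares are clamped at zero against
  round-off in exactly separable designs.
* Newick branch lengths are written with 10 significant digits; a
  read–write round trip preserves them to that precision.

## Problem sizes used in the test suite

The packaged tests exercise the estimators at the survey's natural scale
(28 sites, ~100 OTUs) and verify the metric implementations against
brute-force oracles on small random instances (8–12 tips or sites, where
exhaustive enumeration is feasible); calibration checks use 500–1000
null simulations with 199 permutations each.  These sizes were chosen so
the whole suite documents the package's statistical behaviour while
remaining quick to run routinely.

## Known limitations

* Tree estimation, multiple alignment and taxonomy assignment are out of
  scope: the phylogeny, alignment and lineage labels are inputs.
* The Spearman/threshold network ignores compositional dependence beyond
  the relative-abundance normalization (no SparCC-style correction) and
  applies no multiple-testing correction by default, by design.
* PSV's correlation matrix is exact for ultrametric trees only.
* The MRT has no surrogate splits and treats covariates as numeric only.
* IndVal assumes habitat classes are exchangeable under the null;
  strongly unbalanced habitat sizes reduce the test's resolution
  (a 2-site habitat cannot yield small per-habitat p-values on its own).
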