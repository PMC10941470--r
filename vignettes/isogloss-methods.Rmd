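---
title: "Methods: flora-corrected nomenclature distances, isogloss clustering, and spatial association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flora-corrected nomenclature distances, isogloss clustering, and spatial association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isogloss)
```

This vignette documents the statistical models behind the package, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical conventions adopted
where more than one reasonable choice existed.

## The data model

The basic record is a triple *(unit, species, name)*: survey unit `u`
recorded vernacular name `n` for species `s`. Landrace (farmers' variety)
inventories have no species structure; their records carry a single-taxon
sentinel so the same container serves both kinds of data. Names are
normalized before any comparison: Unicode NFKC, quote characters stripped
(the enclosed text kept), whitespace collapsed, case folded. Matching
downstream is **exact token equality**. Historical sources mark borrowed
or compound name segments with quotes, which is why `"Oozu" nishiki` and
`Oozu nishiki` must compare equal; beyond that, no cognate or
edit-distance matching is attempted — identifying cognates is a research
task in its own right, and silently fuzzy matching would manufacture
lexical signal. This is a documented choice, not a property of the
sources.

## The flora-corrected distance

Historical name surveys are unbalanced: each place was surveyed for
whatever grew there and whatever the interviewees cared to name. Regional
flora tracks altitude, temperature and precipitation, so a naive lexical
distance between two units conflates cultural divergence with innate
ecological difference. The index

$$D = 1 - \frac{a}{A}$$

compares only the $A$ species *commonly included in both units' surveys*
and counts in $a$ those with *at least one* shared name. Two properties
follow directly:

* **Flora correction.** Species surveyed in only one unit never enter the
  comparison, so a mountain and a coastal unit are compared on their
  common species only.
* **Synonym capping.** A species contributes at most 1 to $a$ no matter
  how many synonyms either unit records, so culturally salient species
  with rich synonymy do not dominate the index. No additional weighting is
  applied; the definition's at-least-one-shared rule is implemented
  literally.

$D$ is symmetric with range $[0,1]$ and $D(u,u) = 0$; it is **not** a
metric (the triangle inequality is not asserted or relied upon anywhere).
When two units share no surveyed species ($A = 0$) the pair is
**undefined**. Strict mode raises an error telling the caller to merge or
drop units; lenient mode (the default) masks the pair and the clustering
stage refuses masked matrices. No distance is ever imputed for an
undefined pair — imputation would fabricate linguistic signal where the
data contain none. Arithmetic is double precision; $A$ is bounded by the
species roster (hundreds), so exact rational arithmetic would buy nothing.

For landrace inventories the Jaccard distance on whole per-unit name sets
is used instead: with one crop there is no flora to correct for, and the
name inventory itself is the object of comparison.

## Ward clustering and pruning

Distance matrices are agglomerated with the Lance–Williams Ward
recurrence. Sources that merely say "Ward linkage" are ambiguous between
two dialects; the package implements both and defaults to **ward.D2**, the
textbook Ward objective applied to squared distances with merge heights
reported on the distance scale. `ward.D` (the recurrence applied to raw
distances) is available for comparability with older analyses. Ward is
monotone under this recurrence, so dendrograms have no height inversions.

Two determinism conventions make runs bit-reproducible across platforms:

* **Tie-breaking.** Among equally cheap merges, the pair whose clusters
  contain the lowest original leaf indices wins (compare the smallest
  contained leaf index, then the other cluster's).
* **Label semantics.** After pruning at depth $K$ (removing the $K-1$
  highest merges), groups are numbered by first appearance along the
  dendrogram's depth-first leaf order, so group 1 always contains the
  leftmost leaf.

Choosing $K$ is left to the analyst: pruning depth is a judgment about
branch heights and group sizes, not an algorithmic property, so
`cut_range()` simply returns the nested partitions for all requested
depths (partitions at $K$ and $K+1$ are provably nested).

## Indicator names

For a fixed partition, a name's indicator value for group $g$ is
$\sqrt{A_g B_g}$ where $B_g = r_g$ is the fraction of group-$g$ units
recording the name (fidelity) and $A_g = r_g / \sum_h r_h$ is the
group-size-corrected specificity. Using relative frequencies $r_g$ rather
than raw counts makes the statistic invariant to duplicating every unit,
which matters when groups have very different sizes. Only single target
groups are scored (no group combinations), matching the single-group
indicator labels such analyses report. Ties in the best group go to the
lowest label.

Significance uses a permutation null: labels are permuted uniformly over
units, the null statistic is the maximum over groups, and Monte Carlo
p-values carry the plus-one correction $p = (1 + \#\{ \text{perm} \ge
\text{obs}\}) / (1 + n_{perm})$, so $p \ge 1/(n_{perm}+1)$ always. For
two-group partitions an exhaustive mode enumerates all
$\binom{n}{n_1}$ distinct label arrangements and returns the exact
fraction. Defaults: `n_perm = 999`, `alpha = 0.05`, seed mandatory.

Two caveats are deliberate. First, no multiplicity adjustment is applied
by default: with hundreds of names tested simultaneously, users who need
family-wise control should adjust `p_perm` themselves (e.g.
`p.adjust`); the package reports raw permutation p-values because the
downstream use is descriptive labeling of groups, not confirmatory
testing. Second, permutation p-values on presence/absence data are
*discrete*: the achievable p-values form a finite set, so
$P(p \le \alpha) \le \alpha$ with equality only as ties in the statistic
vanish (many units, varied prevalences). The calibration test in the suite
checks validity and approximate attainment at 200 units, where
discreteness is mild.

The indicator analysis is intended for single-crop inventories. Applied to
a multi-species table, name-level indicators would be confounded by flora
differences between units — the very artifact the $D$ index removes — so
the pipeline refuses multi-species inputs unless explicitly forced.

## Spatial association

Partition maps and thematic layers are compared after sampling both at
grid centroids (the package consumes centroid tables or GeoJSON polygon
layers; it does not generate grids, and coordinates are assumed planar and
pre-projected). Deletion is **pairwise-complete per layer pair**: a
centroid missing in either layer of a pair is dropped from that pair only,
so different pairs may use different $N$ — thematic sources differ in
resolution and coverage, and global listwise deletion would throw away
most of the grid.

**V-measure.** With classes $C$ and clusters $K$ from the paired layers,
homogeneity $h = 1 - H(C|K)/H(C)$, completeness $c = 1 - H(K|C)/H(K)$, and
$v = 2hc/(h+c)$ ($\beta = 1$, the plain harmonic mean). Entropies use the
natural log; $h$, $c$, $v$ are ratios of entropies and hence base
invariant. Degenerate marginals score 1 ($h = 1$ when $H(C) = 0$, $c = 1$
when $H(K) = 0$), matching the reference implementations. In the batched
report the nomenclature partition plays the class role and the thematic
layer the cluster role, so high homogeneity reads as "the nomenclature is
uniform within each thematic polygon" and low completeness as "one
nomenclature group spans several polygons".

**Factor detector.** For numeric layers,
$q = 1 - \sum_h N_h \sigma_h^2 / (N \sigma^2)$ with **population**
variances (divide by $N_h$), so $q = 1 - SSW/SST$ holds exactly and $q$ is
invariant to affine transforms of the response. Refining a stratification
never decreases $q$. Significance defaults to a seeded permutation test
(same plus-one convention). The noncentral-F transform of the original
factor-detector method is available as an option: $F = \frac{(N-L)\,q}{(L-1)(1-q)}$
referred to a noncentral $F(L-1, N-L;\lambda)$ whose noncentrality is
estimated from the observed stratum means. Because the observed means
enter $\lambda$, this test is markedly conservative for strong
associations; the permutation route is the default for that reason.

## The synthetic generator

The generator exists so that every stage can be validated against planted
truth. Defaults mirror the scale of the motivating surveys: 69 units × 310
species (trees), 14 units × 722 varieties (two pools of 361), ~5,800 grid
centroids.

* **Flora gradient.** Units sit on a 1-D latent environmental coordinate
  $e_u \in [-1, 1]$; species $s$ enters unit $u$'s survey with probability
  $\mathrm{logit}^{-1}(\mathrm{logit}(\pi) + \gamma z_s e_u)$, $z_s \sim
  N(0,1)$. This is the simplest mechanism producing the unbalanced
  coverage the $D$ index is built to cancel. Baseline occupancy $\pi$
  defaults to 0.30 — enough that at survey scale every unit pair shares a
  usable set of commonly surveyed species, with record counts of the same
  order as the historical tree survey; gradient strength $\gamma$ defaults
  to 1 (moderate coverage imbalance).
* **Lexicons.** Each planted group holds one canonical name per species
  (distinct across groups by default; `shared_species_frac` lets a
  fraction of species share one name prefecture-wide). A unit replaces the
  group name with a private form with probability $\varepsilon$ (default
  0.05) and records an extra group-level synonym with probability $m$
  (default 0.10) — noise levels at which recovery of the planted partition
  is still essentially exact, chosen as a plausible rate of idiosyncratic
  local forms.
* **Landraces.** Group-exclusive variety pools carried by every home unit;
  with probability $\mu$ (default 0.10) a unit also carries each variety
  from adjacent pools (ring adjacency by default, configurable matrix) —
  mimicking seed transfer between neighbouring regions. Varieties still
  exclusive after migration are the planted indicators.
* **Grid.** Unit territories are unit squares on a near-square lattice;
  centroids are spread round-robin with uniform jitter. The `truth` layer
  reproduces the planted partition exactly (V-measure 1 by construction);
  `degraded` resamples a fraction (default 0.20) of labels uniformly; the
  numeric layer is the group mean plus Gaussian noise with
  $\sigma^2 = \mathrm{Var}(\text{means})\,(1-q^\ast)/q^\ast$, so its
  expected factor-detector q equals the target $q^\ast$ (default 0.8;
  $q^\ast = 1$ gives zero noise).

Everything is driven by one mandatory seed; outputs are byte-identical
across runs.

What the generator does **not** emulate: real phonology or toponymy (names
are structured tokens), spatially explicit dialect diffusion, irregular
municipal geometries, correlated thematic layers, or the survey-effort
heterogeneity of interview-based sources beyond the occupancy gradient.
Passing the recovery tests therefore shows the pipeline is correct and
well-calibrated under its own assumptions — not that any particular field
dataset satisfies them.

## Validation design and problem sizes

The test suite checks every computational claim against an independent
route: the $D$ matrix against a brute-force double loop over species and
name sets; Jaccard against explicit set algebra and `vegan`; Ward heights
and topology against `stats::hclust` (both dialects); V-measure against a
mutual-information recomputation (to $10^{-12}$) and scikit-learn;
the q-statistic against an ANOVA sum-of-squares decomposition (to
$10^{-12}$); indicator values against per-name loops, and exhaustive
permutation p-values against the hypergeometric count. Property tests
cover symmetry, ranges, nestedness of cuts, permutation invariance,
monotonicity sweeps, and null calibration. End-to-end recovery runs at the
full survey scale (69 × 310; 14 × 722; 5,800 centroids; q averaged over
50 grid draws); oracle sweeps use 100–200 random instances at small sizes
(≤ 8 units, ≤ 50 labels) where brute force is exact and fast. The whole
suite completes in well under a minute.

## Known limitations

* Exact-token matching understates similarity between cognate name
  variants; the index is a lower bound on lexical affinity.
* Undefined ($A = 0$) pairs must be resolved by the analyst (merge or
  drop); there is no automatic repair.
* The exhaustive permutation mode covers two-group partitions only;
  multi-group exact enumeration falls back to Monte Carlo.
* The noncentral-F significance route is conservative by construction;
  treat its p-values as upper bounds.
* Point-in-polygon labeling uses even-odd ray casting on planar
  coordinates; boundary points follow file order and no CRS handling is
  attempted.
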