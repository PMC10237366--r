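---
title: "Seasonal community cohesion from presence-only niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal community cohesion from presence-only niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecohesion)
```

This vignette documents the models behind the package, the assumptions they
make, the tunable parameters and why their defaults are what they are, and
the numerical and design choices a maintainer would want spelled out.

## The question and the pipeline

Communities are sets of species that co-occur in space. Whether a community
holds together across the annual cycle — its *cohesion* — can be probed
with presence-only data by building one distribution model per species per
season, reducing the maps to a common coarse grid, clustering species by
occupancy, and asking how the clusters and the underlying niches move
between two anchor months (June and December, the solstice months when
turnover from migration is smallest). The pipeline stages are:

1. **Cleaning** — split records by month, spatially thin to one point per
   km, drop species–season samples with fewer than 10 records.
2. **Niche models** — minimum-volume ellipsoids (MVEs) in environment
   space with a 75% data-inclusion threshold; binary maps by the
   Mahalanobis cutoff; continuous suitability by `exp(-m²/2)`.
3. **Accessible-area modes** — *neutral* maps keep all suitable habitat in
   the study domain; *constrained* maps additionally zero habitat on
   biogeographic slopes where the species was never observed.
4. **Hexagonal PAM** — tiered coverage rule (70/50/30% at breakpoints
   10/40 cells) converts cell-level maps to hexagon-level presence.
5. **Clustering** — k-means on occupancy vectors, K chosen by the gap
   statistic; cross-season best-match overlap classified
   stable / split / diffuse (thirds bands), minimum cluster size 5.
6. **Niche similarity** — Schoener's D per resident species, randomized
   cross-species null, Welch, Wilcoxon, Spearman and Fisher tests.
7. **Motifs** — grade-of-membership decomposition of the site × species
   matrix for a range of K.

## Minimum-volume ellipsoid niche models

### Model and assumptions

For a species–season sample the environmental values at occurrence cells
form a point cloud in d-dimensional environment space (d = number of
layers). The niche estimate is the minimum-volume ellipsoid
`{x : (x − μ)' Σ⁻¹ (x − μ) ≤ c}` enclosing at least `⌈τ·n⌉` of the n
distinct points. The ellipsoid family assumes a unimodal, convex response
to the environment; presence-only fitting assumes occurrences sample the
niche interior (detection thins but does not bias the cloud). τ < 1 guards
against vagrants and misidentifications at the cloud's fringe.

### Fitting

The enclosing ellipsoid of a given subset is computed by Khachiyan's
barycentric coordinate ascent with away steps (C++, tolerance `1e-7` on
the duality gap); for subsets smaller than 2d a moment ellipsoid (mean,
covariance, cutoff at the farthest point) is used instead, and the method
is recorded in the model object. The cutoff c is always re-tightened to
the farthest retained point, so the coverage invariant is exact.

Choosing *which* `⌈τ·n⌉` points to enclose is a combinatorial problem.
The package solves it exactly — enumerating every subset in C++ — whenever
`choose(n, ⌈τ·n⌉) ≤ 5·10⁴`, because iterative heuristics demonstrably land
in local minima on small instances (we measured volumes up to 25% above
the optimum). For larger n it uses iterative trimming (fit, rank by m²,
keep the `⌈τ·n⌉` closest, refit to a fixed point, ≤ 20 rounds), followed
for n ≤ 60 by a deterministic swap refinement that exchanges kept against
dropped points while the volume shrinks. Trimming's bias toward the
current ellipsoid's shape matters less as n grows and the covered subset
stabilizes.

Degenerate inputs are rejected explicitly: fewer than d + 1 distinct
points ("insufficient records"), or a layer with zero variance across the
points ("degenerate layer"). Duplicate environmental rows are removed
before fitting, protecting invertibility of Σ.

### Continuous surface

The literature rarely states a functional form for continuous output of an
ellipsoid model. Any strictly decreasing function of m² yields the same
binary map and the same cell ranking; the package uses `exp(-m²/2)`
(a Gaussian kernel in Mahalanobis distance), max-rescaled to 1. Schoener's
D values depend on this convention; it is stated here so users comparing D
across packages know what was integrated.

## Accessible-area clipping

A species observed only on one side of the barrier ridge gets its
constrained map zeroed on the other side. Two deliberate semantics:

* Cells outside the study **domain** are NODATA (unmodeled).
* Cells inside the domain but outside the species' slopes are **zero**
  (asserted absence), not NODATA.

The second choice keeps the hexagon tier rule's denominator identical in
both modes, which guarantees the containment property "constrained
occupancy ⊆ neutral occupancy" at the PAM level. Treating the slope clip
as NODATA would shrink denominators for ridge-straddling hexagons and can
flip them to present only in constrained mode — an artifact, not ecology.

Likewise Schoener's D normalizes surfaces over the union of valid cells,
treating NODATA on one side as zero suitability: two species restricted to
opposite slopes then get D = 0 (disjoint ranges) rather than an error.

## The hexagonal array and tier rule

Flat-top regular hexagons of area A = 164.8 km² (centroid spacing
`sqrt(2A/√3)` ≈ 13.8 km), lattice anchored at the lower-left corner of the
region's bounding box. Cells are assigned to the hexagon whose center is
nearest their centroid — for a regular hexagonal lattice this *is* the
containing hexagon; distance ties break to the lowest hexagon id, giving a
deterministic partition. The tiered rule (70% of assigned cells when
n ≤ 10, 50% when 11–40, 30% when > 40, comparisons inclusive, n = 0 means
absent) is intentionally stricter where hexagons see few modeled cells.

## Clustering, the gap statistic, and stability bands

k-means (Euclidean, best of 25 restarts, seeded) runs on the binary
occupancy rows. K is selected by the gap statistic with reference sets
drawn uniformly over each feature's observed range
(`cluster::clusGap`, `spaceH0 = "original"`, B = 50 by default) and the
rule "smallest k with Gap(k) ≥ Gap(k+1) − SE(k+1)"
(`cluster::maxSE`, method `Tibs2001SEmax`).

Stability clustering uses **residents only** (species observed in both
seasons): migrants exist in one season's matrix but not the other's, and
letting them perturb the resident partition would confound the
cross-season comparison. The overlap fraction of a June cluster is the
largest share of its members landing in a single December cluster;
the reverse direction is always computed and reported alongside, since the
bands are not symmetric. Bands take 66%/33% as exact thirds: stable
f > 2/3, split 1/3 < f ≤ 2/3, diffuse f ≤ 1/3, unknown below 5 shared
species. The UPGMA dendrogram (average-linkage `hclust`, Euclidean by
default with Jaccard offered, exported as Newick via `ape`) is a
visualization aid only.

## Niche-similarity statistics

* **Observed** — D between each resident's June and December surfaces.
* **Null** — D between a random June species and a *different* random
  December species, 1000 draws by default; excluding self-pairings keeps a
  species' own conservatism out of the null.
* **Observed vs null** — Welch two-sample t (zero-variance degenerate
  inputs return p = 1 by convention when means agree).
* **Categories** — pairwise two-sided Wilcoxon rank-sum between stable /
  split / diffuse record groups; exact when the combined sample is ≤ 50
  and untied, normal approximation with continuity correction otherwise;
  per-category mean D with 95% t-based CI.
* **Effort bias** — Spearman correlation of D against |June − December
  record counts|; rank-based because no linearity is plausible; undefined
  (reported as NA) for constant inputs, refused below n = 3.
* **Migrant subsets** — the migrant-associated species set is compared
  against 500 random same-size subsets: categories are tallied for the set
  and for each subset, and a 2 × C Fisher's exact test contrasts the set's
  tally with the rounded mean random tally (zero columns dropped). In the
  synthetic system there are no taxonomic clades, so "migrant-associated"
  means residents sharing a June cluster (clustered over all June species)
  with at least one migrant — a documented stand-in for clade membership.

## The grade-of-membership model

Presences are treated as unit counts and the site × species matrix X is
modeled as `x_ns ~ Σ_k ω_nk θ_ks`, with site memberships ω (rows on the
simplex) and motif compositions θ (rows on the simplex), fitted by EM:
responsibilities `r_nsk ∝ ω_nk θ_ks`, then row-normalized multiplicative
updates. Defaults are a convergence tolerance of 0.1 on the log-likelihood
change and 10 random restarts; both knobs are exposed, and coarse
tolerances like 0.1 are conventional for this model family because motif
maps stabilize long before the likelihood's last decimals.
Initialization is symmetric Dirichlet(1), seeded; mixture probabilities are
floored at `1e-12` inside logarithms; empty sites are dropped with a
message; K = 1 uses the closed-form MLE. EM's monotone log-likelihood is
asserted in tests on every run. Fits are label-symmetric, so comparisons
(including the recovery tests) first match motifs by maximizing summed θ
correlations over permutations.

## The synthetic study system

The generator emulates, with known ground truth: smooth spatially
autocorrelated environmental layers (Gaussian-kernel-smoothed white noise,
kernel width 10 cells, plus low-order trends and shared latent fields that
induce realistic inter-layer correlation, all |r| < 0.95); an elevation
ridge splitting the domain into two slopes; species with ellipsoidal
niches whose suitable set is the 0.95 χ² Mahalanobis region; a per-species
December niche displacement of `seasonal_shift` environmental SD units in
a random direction; migrants present in one season; slope-restricted
species (centers drawn on their own slope); and imperfect detection
(each suitable cell yields a record with probability `detection_rate`).

Generator defaults — 100 × 100 km of 1-km cells, 9 layers, 40 species,
shift 0.5 SD, 30% migrants, detection 0.5 — are the package's desk-scale
study conditions: a few dozen species and ~80 hexagons keep every stage
inspectable while exercising all code paths (migrant exclusion, slope
restriction, record-count filtering).

What the generator does **not** emulate: checklist-level effort structure
(records arrive pre-cleaned), real geographic coordinate systems,
multimodal or non-convex niches, spatial aggregation of observers, and
taxonomy. Passing tests therefore demonstrate correctness of the machinery
and recoverability of ellipsoidal truth — not that real niches are
ellipsoids, nor anything about a particular avifauna.

Coordinates are a local projected system in km, origin at the domain's
lower-left corner, cell centroids at (i − ½, j − ½) km; months are coded
6 and 12 only. Thinning distance is Euclidean km and "within 1 km" removal
is strict (points exactly 1 km apart both survive), which is what keeps a
full 1-km lattice of detections intact. Raster layers are exchanged as
ESRI ASCII grids (text, georeferenced header), regions as GeoJSON,
occurrences as CSV, and ground truth plus a checksummed manifest as JSON.

## Problem sizes and determinism

The test suite runs entirely on generated data: landscapes of 40–80 km,
4–9 layers, 8–24 species for module tests; 60-species/100-hexagon planted
blobs for gap-statistic recovery; 150 × 40 matrices for membership
recovery; and two full pipeline runs (a seasonal-shift run and a
zero-shift run) at 50–60 km scale. These sizes are the package's chosen
desk-scale conditions; `scripts/acceptance.R` uses the generator defaults.
Every stochastic step takes an explicit seed, and stage seeds are derived
from the configuration seed by a fixed affine map, so identical
configurations reproduce results byte for byte. June and December k-means
share a seed, which makes identical seasonal inputs yield identical
partitions — the zero-shift limit then classifies every cluster stable by
construction rather than by luck.

## Known limitations

* The ellipsoid family cannot represent multimodal niches; τ trims
  outliers but not bimodality.
* Trimming + swap search is heuristic beyond the exact-enumeration range;
  the coverage invariant always holds, optimality is only guaranteed for
  small n.
* The gap statistic's uniform reference is coordinate-aligned; strongly
  correlated occupancy columns can bias K downward.
* The grade-of-membership EM uses plain restarts, not accelerated or
  annealed optimization; for large K the best-of-10 likelihood may still
  be a local optimum.
* Hexagon ids and geometry are anchored to the region bounding box;
  analyses are reproducible, but counts of hexagons are not comparable
  across differently anchored regions.
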