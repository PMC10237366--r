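# nichecohesion

Tools for asking how tightly communities of co-occurring species hold
together across seasons. Given presence-only occurrence records and a stack
of environmental raster layers, the package fits ellipsoidal niche models
per species and season, projects them to binary distribution maps (either
free to fill all suitable habitat, or clipped to the biogeographic "slope"
a species actually occupies), aggregates those maps onto a hexagonal
sampling array, clusters species by where they occur, and measures whether
the clusters — and each species' own niche — stay put between the two
solstice months. A fully synthetic landscape generator with known ground
truth makes every stage testable at desk scale.

Intended users are macroecologists and biodiversity informaticians working
with presence-only data (eBird-style occurrence extracts, museum records)
who want a transparent, reproducible implementation of this co-occurrence
"community cohesion" workflow.

## The method

**Niche models.** For species *s* in season *t*, occurrence points are
mapped to environment space (one axis per raster layer) and enclosed in a
minimum-volume ellipsoid covering a fraction τ of the points (default
τ = 0.75, which discards environmental outliers such as vagrants). The
model is the set {x : (x − μ)ᵀ Σ⁻¹ (x − μ) ≤ c}. Cells inside the ellipsoid
form the binary distribution model; exp(−m²/2), max-rescaled, is the
continuous suitability surface. The τ-subset is found exactly (exhaustive
enumeration) when combinatorially affordable and by iterative trimming with
local swap refinement otherwise; the enclosing ellipsoid of a subset uses
Khachiyan's algorithm (implemented in C++).

**Hexagonal presence–absence matrix.** Raster cells are assigned to the
regular flat-top hexagon (default area 164.8 km²) containing their
centroid. A hexagon counts as occupied under a tiered coverage rule on its
n assigned cells: k/n ≥ 70% when n ≤ 10, ≥ 50% when 11 ≤ n ≤ 40, ≥ 30%
when n > 40.

**Clustering and stability.** Species (rows of the PAM) are clustered with
k-means; the number of clusters is chosen by the gap statistic. June
clusters are compared with December clusters through the best-match overlap
fraction f and classified **stable** (f > 2/3), **split** (1/3 < f ≤ 2/3),
or **diffuse** (f ≤ 1/3); clusters with fewer than 5 shared resident
species are **unknown**. A UPGMA dendrogram is exported for visualization.

**Niche similarity.** Schoener's D = 1 − ½ Σᵢ |pᵢ − qᵢ| between each
resident's normalized June and December suitability surfaces, compared
against a randomized null that pairs different species across seasons
(Welch t), across stability categories (Wilcoxon rank-sum), against
seasonal effort differences (Spearman), and between migrant-associated
species and 500 random same-size subsets (Fisher's exact test).

**Geographic motifs.** The site × species matrix is decomposed by a
grade-of-membership (topic) model fitted with EM for K = 2…14: each hexagon
is a mixture over motifs, each motif a probability vector over species.

## Worked example

```r
library(nichecohesion)

cfg <- pipeline_config(
  sim = sim_config(grid_nx = 60, grid_ny = 60, n_layers = 6, n_species = 20,
                   seasonal_shift = 0.5, detection_rate = 0.7, seed = 42),
  gap_B = 20, n_null = 300, n_subsamples = 200, gom_k = 2:6)
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result> 20 species simulated, 12 residents modeled, 30 hexagons
#>   neutral: K = 2 (June) / 6 (December); mean D = 0.604; Welch t = 8.33 (p = 4e-06)
#>     categories: split=1, unknown=1
#>   constrained: K = 2 (June) / 6 (December); mean D = 0.605; Welch t = 8.33 (p = 4.04e-06)
#>     categories: split=1, unknown=1

head(res$per_mode$constrained$records, 3)
#>   species         D category delta_points        mode
#> 1   sp001 0.8443413    split           12 constrained
#> 2   sp002 0.8406228    split           15 constrained
#> 3   sp004 0.7538311    split           18 constrained
```

Reading the output: 12 of the 20 simulated species were observed in both
seasons and modeled as residents. With a moderate seasonal niche shift
(0.5 SD) the June clustering splits rather than dissolves (its one
classifiable cluster keeps half its members together in December), each
resident's seasonal similarity D is well below 1 but far above the
randomized null (mean D ≈ 0.60 vs ≈ 0.01; Welch t ≈ 8.3), and the neutral
and slope-constrained analyses agree closely — the expected picture when
niches move but do not reorganize.

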