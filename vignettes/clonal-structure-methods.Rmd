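---
title: "Methods: spatial clonal structure analysis with clonescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial clonal structure analysis with clonescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

clonescape analyses the spatial clonal structure of partially clonal plant
populations sampled as individual ramets, geocoded in a planar metric
frame, and genotyped at codominant microsatellite loci.  This vignette
explains the statistical machinery, the choices made where the methodology
was genuinely open, and what the simulation-based validation does and does
not establish.

## Data model

A dataset is a plain tibble: one row per sampled ramet with `sample_id`,
planar coordinates `x`, `y` in metres, a `patch_id`, and two integer
allele columns per locus (`<locus>_1`, `<locus>_2`; `NA` = missing call).
Allele labels are opaque integers (fragment sizes scored upstream); no
binning is performed.  Readers are provided for a flat CSV layout and a
GenAlEx-style codominant export.  Units carrying any missing call are
excluded from clone discrimination and flagged (`NA` group id); a
`"pairwise"` mode that compares mutually scored loci is available but not
the default, because imputing clone membership across missing loci risks
lumping distinct genets.

## Clone discrimination

Pairwise genetic distance is the allelic mismatch count: per locus,
`2 - |multiset intersection|` of the two allele pairs, summed over loci
(0 for identical genotypes, up to `2L`).  Multilocus genotypes (MLGs) are
the connected components of the graph joining pairs at distance
`<= t` (single linkage), so `t = 0` is exact genotype identity and larger
`t` merges MLGs separated by putative somatic mutations or scoring errors
into multilocus lineages (MLLs).  Merging is monotone in `t`.  The default
is `t = 0`: in the population that motivated this package no distance gap
separated MLLs from MLGs and one-step pairs were treated as distinct
genotypes; the threshold remains a user argument, and the mismatch
histogram (`mismatch_histogram()`) supports the visual gap inspection.
Group labels are assigned by first appearance after sorting sample ids, so
the partition is invariant to row order and to coordinates.

Confidence that repeated genotypes are clonemates uses the standard
two-probability screen.  `Pgen` is the probability of drawing a genotype
from reference allele frequencies: per locus `p^2` (homozygote) or `2pq`
(heterozygote) under Hardy–Weinberg equilibrium, generalised to
`p^2 + p(1-p)F` and `2pq(1-F)` under an inbreeding departure `F_IS`,
multiplied over loci.  `Psex` is the binomial-tail probability that an MLG
observed `n` times among `N` units arose at least `n` times from
independent sexual events:

$$P_{sex} = 1 - \sum_{l=0}^{n-1} \binom{N}{l} P_{gen}^l (1 - P_{gen})^{N-l}.$$

Both default to **round-robin** allele frequencies: for each locus, MLGs
are identified from all the *other* loci and the focal locus is counted
once per such genotype.  This clone-censors the frequencies without letting
the focal locus censor itself.  `F_IS` for the `(FIS)` variants is
estimated per locus from the clone-censored dataset as `(He - Ho) / He`.
The marker panel's resolving power is checked with a genotype accumulation
curve (locus subsets drawn without replacement; the curve should plateau
below the full locus count).

## Diversity statistics

Population statistics are computed on one representative per MLG (at
`t = 0` clonemates are identical, so the representative choice is
immaterial, and a test asserts this invariance):

* `Na`, `Ho`, `He = 1 - sum(p^2)` (no small-sample correction — this is
  the convention under which the reference population's printed per-locus
  table is internally consistent, with `FIS = (He - Ho)/He` reproducing
  its FIS column within rounding);
* Botstein's polymorphic information content
  `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`;
* genotypic richness `R = (G - 1)/(N - 1)`;
* Shannon–Wiener equitability `E_H = (-sum p_i ln p_i)/ln S` over clone
  sizes, defined as 0 at `S = 1` (the "all ramets one genet" limit, even
  though `ln S = 0` makes the ratio formally indeterminate);
* the Pareto clone-size slope: OLS of `log N(>= X)` on `log X` over the
  distinct observed sizes, reported as `beta = -slope`.  The cumulative
  (survival) regression was chosen over a non-cumulative fit because it is
  the common convention in clonal plant work and is exact when
  `N(>= X)` follows a power law; dropping the largest size class and the
  non-default variants are exposed as arguments;
* the clonal subrange: the largest distance between two clonemates.

## Spatial structure

**Aggregation index.** `Psp` is the fraction of units whose nearest
neighbour (ties broken by smallest sample id, one relation per unit) is a
clonemate; `Psg = sum n_g(n_g-1) / (N(N-1))` is the probability that two
random distinct units are clonemates.  We report the normalised excess
`Ac = (Psp - Psg) / (1 - Psg)`, which is 0 under random labelling and 1
when every nearest neighbour is a clonemate, matching the stated 0–1
meaning of the index and its inverse relation to the patch mixing index
below.  (The historical GenClone formulation is not published in closed
form; the normalisation is this package's documented choice.  Ac can go
negative for over-dispersed clonemates, which is informative and is not
clipped.)  Significance comes from permuting coordinates among units —
equivalently genotype labels over fixed positions — with
`p = (#{Ac* >= Ac} + 1)/(B + 1)`.

**Kinship profiles.** Pairwise kinship follows Loiselle et al. (1995):

$$F_{ij} = \frac{\sum_l \sum_a (x_{ia} - p_a)(x_{ja} - p_a)}
               {\sum_l \sum_a p_a (1 - p_a)} + \frac{1}{n - 1},$$

with `x_ia` the within-individual allele frequency (0, 1/2, 1).  Distance
classes are built with equal pair counts (sizes differ by at most one), 10
classes by default — the reference analysis did not state its class count,
and equal-count classes make the permutation envelopes comparable across
classes.  The analysis runs at two levels: ramet level (all units,
per-ramet reference frequencies) and genet level (one genotype per MLG
placed at the arithmetic centroid of its ramets, clone-censored reference
frequencies).  Per class, significance is two-sided against `B`
permutations of spatial locations among individuals, with the 2.5%/97.5%
quantile envelope reported.  Under clonality the ramet-level first-class
kinship exceeds the genet-level one — decomposing exactly the contribution
of clonal spread to spatial genetic structure.

## Genet geometry

The area occupied by a genet (`A_GEN`) is the convex hull of its ramets
when at least three non-collinear ramets were sampled.  Hulls cannot be
built for one- and two-ramet genets, so their areas are imputed from the
mean hull area `A3` of genets with exactly three ramets: `A3/3` for
singletons, `A3/1.5` for pairs.  For mapping and overlap accounting these
genets get constant-area buffer polygons: a disc for singletons and a
stadium (segment buffer) for pairs, whose half-width solves
`pi w^2 + 2 d w = target` for ramets a distance `d` apart.  Collinear
multi-ramet genets (zero-area hulls) are routed to the pair rule using
their two most distant ramets.  Genets found in several patches get one
pooled footprint.

Polygons are discretized with 64 segments per full circle; radii are
solved against the *discretized* area, so every buffer's polygon area
equals its target to machine precision rather than to discretization
error.  All footprints are convex (hulls, discs, stadiums), so every
k-wise intersection is itself convex; the overlap report clips polygons
exactly (Sutherland–Hodgman), accumulates the k-wise intersection areas,
and obtains the union, the area covered by two or more genets, and the
maximum multiplicity by inclusion–exclusion — no rasterisation or Monte
Carlo is involved.  The reported overlap percentage is the ≥2-cover area
relative to the union of all footprints; the total patch area can be
substituted as denominator where patch outlines are available.

## Patch-level analysis

Per patch with at least two sampled units: `R_p = (G_p - 1)/(n_p - 1)`,
`E_H` over within-patch clone sizes, and the genotypic spatial mixing
index `S_mix = N_Pdif / N_Ptot`, the fraction of nearest-neighbour
relations joining different genets.  `N_Ptot` counts *directed* relations
(one per ramet, so `N_Ptot = n_p`): the defining phrase "pairs of nearest
neighbouring ramets" is ambiguous between directed and unordered pairs,
and the directed reading is deterministic and keeps the index in `[0, 1]`
for every configuration; an unordered mode that collapses mutual pairs is
available.  All three indices are 0 on monoclonal patches and invariant to
genet relabelling, and S_mix moves opposite to Ac by construction.  Each
index is regressed on patch area `A_P` (planar outline area) by OLS, with
Pearson r and its two-sided t-test p-value (printed to 3 decimals and
never as exactly zero).

Local genotypic richness surfaces compute, per ramet, `R` over the units
within a 1 m radius (0 for isolated units, consistent with the monoclonal
limit) and interpolate to a grid.  The interpolant is inverse-distance
weighting with exact reproduction at data points; the multilevel B-spline
used in the original mapping work is a visual-smoothing choice that no
numerical result depends on, so any interpolant meeting the
reproduce-at-points contract is acceptable here.  Cells farther than the
masking radius from any unit are flagged as outside the species.

## The synthetic population generator

Because the motivating study's raw genotypes and coordinates live in a
journal appendix rather than a machine-readable archive, every stage is
validated against simulated populations with known truth.  The generator's
defaults are fixed at the study's conditions: 240 genets, eight loci with
8, 5, 4, 7, 16, 11, 14 and 8 alleles, clone sizes from a truncated Pareto
law (tail exponent 0.69, capped at 55 ramets) dominated by small clones,
and a phalanx architecture in a 40 × 40 m arena sized so the occupied area
is a few hundred square metres and a 1-m grid sample yields several
hundred units.  Per-locus allele frequencies are drawn from a symmetric
Dirichlet; founder genotypes under HWE (a selfing rate adds homozygosity);
genet seed points are uniform with a hard-core exclusion distance (1.5 m
for phalanx); somatic mutations are infinite-alleles steps per allele copy
(default rate 0, since the study concluded somatic variation was
negligible).

Phalanx ramets are placed uniformly in a compact disc of radius
`sigma * sqrt(n_g)` (`sigma` = 0.25 m), so a clone's occupied area grows
linearly with its ramet count at constant within-clone density — the
defining phalanx property, and the reason clone size and footprint area
correlate.  Guerrilla ramets take isotropic Gaussian displacements with a
large scale (3 m), so genets intermingle.  Patches are the single-linkage
components of ramets under a 1 m connectivity radius, outlined by the
buffered convex hull of their ramets (a convexity approximation: real
patch drawings are irregular).  Grid sampling applies the field protocol:
2 samples from a quadrant mostly covered by a patch that extends beyond
it, 1 from a minor intersection, 2 from a patch wholly inside a quadrant —
capped by ramet availability, with per-quadrant ramet counts recorded.

`simulate_aged_population()` composes the scenario behind the patch-area
regressions: an established cohort of large clones (sizes 8–40) spaced
5 m apart and a dense young cohort of single-ramet genets recruited in
the surrounding areas; patches larger than 3 m² are then stripped of
young singletons, emulating developed patches that no longer admit
seedlings.  Under this mechanism all three patch indices decline with
patch area, reproducing the direction of the study's regressions.

What the simulations do *not* emulate: demographic dynamics through time
(growth, die-off, disturbance), mating systems and geitonogamy, allele
frequency drift, irregular (non-convex) patch shapes, and genotyping
error beyond the somatic mutation channel.  Passing tests therefore show
the estimators are correct and calibrated on populations with the study's
structure, not that any particular field population follows that
structure.

## Numerical and validation choices

* Nearest-neighbour ties (exact equal distances) break to the smallest
  sample id; every permutation or subsampling step takes an explicit seed,
  and the pipeline records its seeds in every artifact.
* Permutation p-values use the `(+1)/(B+1)` correction, so they are never
  exactly zero.
* Validation problem sizes: oracle-equivalence tests run on instances of
  8–50 units; parameter recovery uses a ~60-genet grid-sampled population
  and a 2000-singleton frequency-consistency check (3 standard errors);
  the architecture contrast uses 50 replicate pairs of 40-genet
  populations with matched clone sizes; null calibration uses 100
  genotype-randomised replicates at 200 permutations each, requiring
  rejection rates at the 5% level to fall in [0.01, 0.10]; the aging
  scenario uses 50 replicates and requires negative slopes for all three
  indices in at least 90%.  These sizes were chosen to make sampling noise
  small relative to the effects under test while keeping the suite quick.

## Known limitations

* The aggregation index's exact historical formula could not be verified
  against a published closed form; results are comparable within this
  package but may differ by an affine rescaling from legacy software.
* Round-robin genotype identification censors on the non-focal loci only;
  with very few loci (L = 2–3) the censoring can be weak.
* The overlap machinery is exact only because all footprints are convex;
  concave footprint models (alpha shapes) are out of scope.
* Patch outlines produced by the simulator are convex hulls; real
  digitized outlines can be concave, and their areas are taken as given.
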