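---
title: "Ring statistics for congeneric spatial patterns: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring statistics for congeneric spatial patterns: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oring)
```

## The scientific problem

Fully stem-mapped forest plots record every free-standing tree and
shrub down to 1 cm diameter at breast height (DBH), with map
coordinates on a rectangular window — here a 400 × 500 m, 20 ha plot
is the reference design. For a guild of congeneric species, two
questions recur: how strongly is each species aggregated, at which
scales, and do congeners attract, ignore or repel one another?  The
package answers both with ring (O-ring) statistics, and asks them at
two taxonomic levels: each species on its own, and each genus as the
pooled pattern of its congeners ("mixed congeneric species
individuals"), so that the dilution of aggregation and association
under pooling is itself a measurable quantity.

## The statistics

**Relative neighborhood density.** For a species with `n` mapped
stems and plot-wide mean density `lambda = n / A(plot)`, the
statistic for the annulus `[r, r + w)` is

    Omega_r = D_r / lambda,   D_r = N_r / A_r

where `N_r` sums, over all stems taken as focal points, the
conspecific neighbours in the annulus (self excluded), and `A_r` sums
the in-window annulus areas around the same stems. `Omega_r = 1`
under complete spatial randomness (CSR); above 1 aggregated, below 1
regular. The scalar `Omega_0-10` — the first 10 m ring — serves as an
aggregation-intensity index. Because a ring, not a disc, is counted,
`Omega_r` is a density at scale `r`, uncontaminated by pattern at
smaller scales.

**Bivariate ring statistic.** `g12(r)` replaces circles of radius `r`
in a Ripley-type cross statistic by rings: the density of species-2
stems in annuli centred on species-1 stems, divided by species 2's
plot-wide density. `g12 = 1` means non-association (independence),
`> 1` attraction, `< 1` repulsion or segregation. No self-exclusion
applies (the patterns are distinct), and the reference density is
always that of the second pattern.

**Pooling convention.** Both statistics pool as a ratio of sums —
`(sum N) / (sum A)`, then divided by `lambda` — rather than averaging
per-focal ratios. The ratio of sums matches the pooled `D_r = N_r /
A_r` form of the statistic's definition and stays stable when a focal
stem sits so close to a corner that its annulus has tiny in-window
area; a per-focal `mean_of_ratios` mode is kept behind the `pooling`
switch of every estimator for sensitivity analysis. For interior
points the two coincide; near edges they differ at the percent level.

## Edge correction

The plot boundary truncates annuli, so raw neighbour densities around
boundary trees are biased low. Every annulus is therefore clipped to
the window exactly: the area of a disc intersected with the rectangle
has a closed form (inclusion–exclusion of circular-segment integrals
over the four corner quarter-planes), implemented in compiled code
and exposed as `annulus_area_in_window()`. The closed form is exact
to floating-point precision — the test suite checks known geometries
(interior ring `100*pi`, corner quarter-ring `25*pi`), checks that a
full ladder of rings tiles the window area to 1e-9, and
cross-validates edge-clipped cases against a rejection-sampling
(dart-throwing) estimate. Per-focal correction of this kind is the
convention of abundance-based neighborhood-density analyses; no
further (e.g. translation) correction is applied.

## Monte Carlo envelopes and classification

The null model is CSR with the observed abundance: `n_sim`
simulated patterns (999 by default), each run through the same
estimator. Per ring, the envelope takes the `k`-th smallest and
`k`-th largest simulated value with `k = ceiling(0.025 * n_sim)` —
the 25th of 999, the 5th of 199 — giving pointwise 2.5% / 97.5%
bounds. The observed curve is *not* added to the null set: the
observed statistic is compared against simulated quantiles.
Classification is three-way: above the upper bound = aggregated
(univariate) or positive (bivariate); below the lower bound = regular
/ negative; otherwise random / independent. A value exactly on a
bound counts as random/independent — the conservative tie-break, made
deterministic so reruns agree bit-for-bit.

Envelopes are pointwise, matching the way such figures are read in
practice; with 25 rings, roughly one ring per profile will break out
under the null. Summaries that count rings per label inherit this
multiple-testing caveat, which is why the tests of calibration work
at a *fixed* ring.

For the bivariate test, pattern 1 is held fixed and pattern 2
re-simulated as CSR. This nulls both the association *and* pattern
2's own clustering, which is the stricter and historically common
construction; a toroidal-shift alternative (`null = "toroidal"`),
which preserves each pattern's internal structure and tests
independence alone, sits behind a flag for sensitivity checks but is
not the default.

Randomness is governed by one master seed per computation;
replicate-level streams are derived from it (`derive_seeds()`), so a
report rerun with the same seed reproduces every table byte for byte
and results do not depend on evaluation order.

## DBH conventions

Size classes are half-open intervals `[lo, lo + w)` anchored at the
1 cm census floor. Two widths are in play and both are parameters,
not constants: 2 cm for size-structure histograms, 3 cm for
aggregation-by-size profiles. A class enters the
aggregation-by-size analysis only when it holds at least 50 stems;
the source phrasing "more than 50" is ambiguous between strict and
non-strict, and the package fixes `>= 50` as the documented default
(`min_count`), which callers can change. Within a class,
`omega_by_dbh()` treats the class's stems as a pattern of their own:
both neighbour counts and the reference density come from the class
(`lambda = "class"`). The alternative reading — class neighbour
density over the *whole group's* density — is available as
`lambda = "group"`; it differs by exactly the ratio of class to group
abundance, so the choice rescales but does not reorder a series.

## The synthetic community generator

No census of the reference design is publicly deposited, so the
package ships a generator whose defaults *are* the study conditions:
eight species in four genera on the 400 × 500 m window with exact
abundances 4478, 2557, 2118, 1302, 800, 532, 1352 and 223 (13362
stems), every species spatially clustered, strong within-genus
segregation for two genera, and declining size structures.

Species are drawn from a conditional-total Thomas process: `kappa`
parents uniform over a placement region, exactly `abundance`
offspring assigned to parents uniformly and displaced by an isotropic
Gaussian with sd `sigma`, reflected at the window boundary. Fixing
the total departs from the textbook Thomas process (Poisson cluster
sizes) so that generated tables carry exact prescribed abundances;
reflection (rather than discarding) keeps them exact, with toroidal
wrapping behind a flag. Placement regions implement segregation
geometrically: `left_half` / `right_half` put congeners' parents on
opposite plot halves, and the four `corner_*` quarters allow
opposite-corner pairs. (A bare "corner" placement would be ambiguous
— a segregated pair needs two *different* corners — so the region set
names each quarter; `"corner"` aliases `corner_sw`.)
`shared_with` reuses another species' parent set, producing attracted
congeners. The generator makes no mechanistic claim — it reproduces
the statistical signatures (clustering intensity, segregation,
declining size classes), not the habitat or dispersal processes that
created them; in particular, real topography-driven density gradients
and dispersal kernels with heavy tails are not modelled, so passing
tests demonstrate estimator correctness and qualitative
reproducibility, not ecological inference on real data.

Cluster parameters were set once from the expected-value relation for
a Thomas process, `Omega_0-10 ≈ c + P(d < 10) * 636 / kappa` (with
`c` the support inflation: 1 for full-plot species, ~2 for half-plot,
~4 for quarter-plot, and `P(d < 10) = 1 - exp(-25/sigma^2)` the
within-cluster pair capture), choosing `kappa` between 15 and 60 and
`sigma` between 8 and 12 m so species-level `Omega_0-10` spans
roughly 2–18 with the rarest, most-concentrated species the most
aggregated — the qualitative profile of a real congeneric guild,
where rare species are routinely the most intensely aggregated.

Diameters are drawn above the 1 cm floor: "L-shaped" structures as
1 + a truncated exponential, "reverse-J" as 1 + a truncated Weibull
with shape < 1 (heavier large-stem tail), both capped at 60 cm (a
desk-scale cap, recorded in the spec of each species) by inverse-CDF
sampling so the cap costs no rejection loop. For size-dependent
aggregation studies, `sigma_by_dbh` interpolates each stem's
dispersal sd linearly in DBH, which yields tightly clustered small
stems and near-random large stems and hence a declining
`Omega_0-10`-by-DBH series.

## Numerical and degenerate-input choices

* Duplicate coordinates are legal (multi-stemmed recruits share a map
  point); zero-distance neighbour pairs fall in the first ring and
  are counted. One measurable consequence, asserted in the tests:
  pooling a species with an exact copy of itself shifts
  `Omega_0-10` up by exactly `n / (2 * A_1 * lambda_1)` — the
  coincident-pair term — rather than leaving it unchanged.
* A ring with zero summed in-window area cannot arise for in-window
  focal points, so profile values are always defined; empty rings
  simply yield 0.
* Patterns with fewer than 2 points (univariate) or empty patterns
  (bivariate) raise errors rather than returning NaN.
* Ring membership is computed as `floor(d / w)` on exact distances;
  points exactly on a ring boundary belong to the outer ring,
  consistent with half-open intervals.
* All validation errors cite the offending row, column or code, and
  group lookups list the known codes.

## Problem sizes used in the checks

The calibration and reproduction suite runs at sizes chosen to give
tight Monte Carlo error while keeping a laptop-scale runtime: 200
replicates of n = 1000 (univariate CSR calibration) and 200 pairs of
n = 500 (bivariate), envelope coverage at n = 100 with 199 null
simulations over 400 outer replicates, power ordering over 50 Thomas
replicates per cluster scale, and 20 regenerations of the full
13362-stem community for the pooling inequality. Brute-force
equivalence is checked on fixtures up to n = 500 against a plain
double-loop oracle at 1e-10 relative tolerance.

## Known limitations

* The null is CSR only; no heterogeneous-Poisson or
  habitat-conditioned nulls, so "aggregation" conflates true
  clustering with habitat-driven density variation — as it does in
  the analyses this package reimplements.
* Homogeneous statistics only; no intensity-reweighted
  (inhomogeneous) variants, and no kernel-smoothed pair correlation —
  rings are the estimator, not a smoothing choice.
* Pointwise envelopes; no global rank-envelope test.
* Single-census snapshots; no recruitment/mortality dynamics, no GIS
  coordinate systems.
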