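---
title: "Methods: little auk foraging, diet and condition analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: little auk foraging, diet and condition analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aukforage)
```

`aukforage` implements, as a reusable and fully tested pipeline, the
analyses used to study how a central-place-foraging Arctic seabird — the
little auk (*Alle alle*) — uses bathymetry and the marginal ice zone
while rearing chicks: GPS-track classification and trip metrics, kernel
utilization distributions and habitat overlap, dive-record calibration
and metrics, diet and zooplankton-community statistics including a
prey-selection index, chick-growth and body-condition models, and
regional sea-ice summaries. Because raw tracking and net-haul data of
this kind are rarely deposited, the package ships a synthetic-data module
that generates every input with known ground truth, so each stage can be
validated end to end.

## Behavioural classification and trips

GPS fixes arrive at 15-min intervals. The only speed available at that
sampling is the segment speed: great-circle distance between consecutive
fixes (haversine, R = 6371 km) divided by elapsed time. Fixes with
segment speed strictly below 10 km/h are labelled `forage_rest`, all
others `travel`; foraging and resting cannot be separated at this
resolution and are deliberately kept as one class. The threshold
comparison is strict — exactly 10 km/h is `travel` — because the
defining rule is "below 10". The first fix of a track carries no speed
and is excluded from behaviour tallies. Segments spanning a gap longer
than 3 median intervals are left unlabelled (GPS gaps are common in
field data; the multiplier is configurable).

A trip is a maximal run of fixes outside the colony radius (default
1.0 km — tracking studies rarely state this; it is configurable and
results are insensitive well below the commuting step length of ~11 km
per fix). A trip is *complete* only when flanked by inside-radius fixes
on both ends; incomplete trips (tracks ending at sea) are kept but
excluded from duration and path-length summaries, mirroring standard
practice. Two-group comparisons of trip metrics use the two-sided
Wilcoxon rank-sum test, exact when the combined sample is at most 20 and
without ties, otherwise the normal approximation with continuity
correction; the reported W is the first-group statistic of
`stats::wilcox.test`, stated in the output metadata.

Distances from positions to the consolidated-ice (≥80% concentration)
polygon are zero inside the polygon, else minimum boundary distance,
evaluated in a local azimuthal-equidistant projection. Radial distances
are exact under that projection and tangential distortion is below 0.01%
at the ~300-km scale of these data, so the result is effectively
geodesic; a user needing bit-compatibility with a GIS workflow can
project coordinates themselves and work planar throughout.

## Space use

The utilization distribution is a bivariate Gaussian product-kernel
density on a regular grid (default 200 × 200 cells, extent padded by 3
bandwidths), renormalised so that density × cell area sums to 1. The
bandwidth default is the bivariate reference ("ad hoc") rule
*h* = σ·n^(−1/6) with σ² the mean of the coordinate variances — the
convention of the classic home-range tools. Core areas are volume
contours: cells ranked by density, smallest prefix reaching the target
mass (75% by default). The cell mask is authoritative for area and
overlap; polygon rings are derived only for export.

Overlap between two regions reports areas of each, intersection and
union, and the overlap percentage under all three denominators; which
denominator a published "percentage of overlap" used is often ambiguous,
so all are always given. Intersection and union areas are evaluated on a
fine common grid (default 600 cells per axis; cell masks are sampled
natively, polygons by centre-point membership). Against a 10⁵-point
Monte-Carlo oracle this agrees within 1% at the default resolution. The
shelf-break band (500–1500-m isobaths) is built by joining the two
isobath polylines into a closed ring.

An analytic check anchors the contour machinery: for points from an
isotropic bivariate normal, the 75% volume contour of the KDE has area
π·χ²₂(0.75)·σ_eff² with σ_eff² = s² + h²; the grid contour matches
within discretisation error (tested at 7%).

## Dives

The DST micro-TD tag underestimates depth; pressure-chamber
recalibration gives the affine correction depth = 1.0473·raw + 0.4498 m,
applied before any analysis. Other tag models pass through unchanged
(strict mode turns unknown models into errors). A dive is a maximal run
of samples at or beyond the detection depth lasting at least the minimum
duration; defaults of 2 m and 8 s sit far below the reported means
(~17–21 m, ~55–60 s), so summary metrics are insensitive to them. Run
length is counted inclusively in samples × interval, which makes
detection invariant to 1/2/4-s sampling for dives of ≥3 samples. No
zero-offset drift correction is applied by default.

## Diet and communities

Relative abundance (RA) is per-sample count share; group tables report
mean ± SD of RA and occurrence frequency (OF, share of samples where the
taxon occurs). The linear food selection index for taxon *i* is
LFSI = GP_i − E_i, the difference between diet and environment RA,
in [−1, 1]. Uncertainty uses a parametric bootstrap: 10,000 independent
normal draws around the observed means and SDs of both proportions,
without truncation to [0, 1] — plain normal draws reproduce the
closed-form SD of a difference of independent normals,
√(0.176² + 0.027²) = 0.178, matching the published rounding. Percentile
intervals are the default (the interval type is rarely stated; normal
intervals differ negligibly at these SDs).

Between-year comparisons of RA use the pooled-variance Student's t from
group summaries: published df of 38 with n = 20/20 identifies the pooled
(not Welch) form on raw RA. Net-haul densities assume 100% filtration of
the swept cylinder (WP2 net, 0.57-m mouth, 50-m hauls). Calanus species
are classified from stage-specific prosome-length cut-points; boundary
lengths go to the larger species. The shipped cut-points are explicitly
assumed (the study derived its own from unpublished length
distributions) and should be replaced per dataset.

Community structure uses Bray-Curtis dissimilarity on counts (or RA)
with Ward clustering; `ward.D2` is the default minimum-variance form,
`ward.D` is selectable and can group differently. Per-habitat density
comparisons run a tie-corrected Kruskal-Wallis test, pairwise Wilcoxon
tests, and a compact letter display (insert-and-absorb) at a stated α.
An all-constant input is reported as H = 0, p = 1 by convention.

## Growth and condition

Chick growth over the linear window (ages 4–14 d) is modelled by
random-intercept linear mixed models fitted by maximum likelihood — not
REML, because candidate models differ in fixed effects and their AICs
must be comparable. Candidates default to all combinations of age and
year plus their interaction. The parameter count k includes fixed
effects plus the two variance components (whether published K counts
variances is usually unrecoverable; the convention is stated, and
selection is insensitive here because all candidates share the random
structure). Selection keeps models within 2 AIC of the minimum and
returns the one with smallest k, ties broken by lower AIC; the rule is
order-invariant.

Adult body condition is the residual of a pooled OLS of mass on wing
and head-bill length. Years are compared by the F-test of residual mass
on year (df2 = n − 2, the convention implied by published degrees of
freedom for this index); a covariate-adjusted year test from the joint
model is also returned since the two can differ when size distributions
shift between years.

## Sea ice

Regional concentration is the unweighted mean over grid cells inside a
projected 150 × 200 km rectangle centred on the colony (east-west ×
north-south; the orientation is a package choice) and days inside the
15 July – 15 August window, ignoring missing cells but counting them.
Equal weights are appropriate for near-equal-area 12.5-km polar grids;
cos-latitude weighting is available. The interannual trend is OLS of the
yearly mean on year with t = slope/SE, df = n − 2.

## The synthetic scenario

The generator emulates the study conditions: 15-min fixes; out-and-back
trips with a directional commute (~45 km/h), a ~24-h low-speed
foraging/resting phase (speeds drawn below 8 km/h) around a feeding
ground 100 ± 26 km east of the colony (between the two reported yearly
means of 89 and 108 km, with their ~26-km spread); ~270 Poisson dives
per 24 h as square-wave events of 19 ± 4 m and 57 ± 5 s; at-sea
communities drawn Dirichlet-multinomial (concentration 50) around the
published shelf / shelf-break / open-ocean composition; gular-pouch
loads as truncated-normal RA around the published yearly pouch
compositions; and linear chick growth (20 g + 6 g/d, chick intercept SD
5 g, residual SD 5 g) sampled every second day. The within-trip time
budget is a free parameter, not an estimate — no such budget is
published. Each generator runs on its own sub-stream of the master seed,
so outputs are byte-identical per seed and adding a generator does not
perturb the others. Ground truth (trip apexes, dive list, chick
effects) is always emitted alongside, never embedded in the data files.

What the generator does *not* emulate: spatial autocorrelation of real
foraging beyond a soft pull toward the feeding ground, oceanography and
ice drift, device effects on behaviour, overdispersion structure of real
count data beyond Dirichlet-multinomial, and nonlinear (logistic)
growth outside the linear window. Passing recovery tests therefore show
the estimators are correct under the stated generating model, not that
real data meet that model.

The ice-distance scenario holds foraging positions fixed while the ice
edge moves from 23 km to 152 km beyond the feeding grounds — matching
the observation that space use was unchanged between an icy and a
near-ice-free year — so the implied extra round-trip commuting distance
is exactly twice the difference of the median ice distances, 258 km.

## Numerical choices and limitations

Earth radius 6371 km everywhere; strict threshold comparisons where a
rule is stated as an inequality; KDE mass renormalised after grid
clipping; contour mass guaranteed within one cell's mass above the
level; overlap resolution 600–1000 cells per axis (≤1% area error);
LMM convergence per lme4 defaults with singular fits tolerated at the
boundary (zero chick variance is a legitimate estimate); exact Wilcoxon
only without ties and combined n ≤ 20. Problem sizes in the test suite
(50 birds, one 24-h dive record, 10–100 community samples, 1000-rep
type-I simulations) were chosen as the smallest that make the
statistical checks sharp.

Known limitations: no state-space or hidden-Markov behavioural models,
no track interpolation, no Brownian-bridge or autocorrelated kernel
estimators, no wiggle/bottom-phase dive analysis, no energy-content or
isotope mixing models, and no retrieval or parsing of satellite sea-ice
products — concentration grids must be supplied as tables.
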