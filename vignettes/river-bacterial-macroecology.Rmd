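---
title: "Methods: bacterial macroecology along a river transect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bacterial macroecology along a river transect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivermacro)
```

## The problem

Large rivers carry bacterioplankton communities downstream for days to
weeks. Over such a journey the community both works (producing biomass from
dissolved carbon) and changes (phylotypes are replaced, richness erodes).
`rivermacro` implements the quantitative machinery to describe both
processes on a downstream-ordered transect whose central coordinate is
**water travel time** (WTT): the cumulative hours a parcel of water has
spent flowing since the headwater site, computed per segment as distance
over flow velocity and accumulated by prefix sums.

Everything below operates on two inputs: a site-metadata table (river
kilometre, velocity, total cell counts *TCC*, bulk bacterial secondary
production *BSP*, mean cell volumes, optional covariates) and an ASV count
table with a sample-to-site map.

## Production calculus

The production module chains elementary conversions, each exposed as its
own function so intermediate quantities stay inspectable:

- per-cell production `BSP_c = BSP * 1e9 / TCC` (fgC cell⁻¹ h⁻¹);
- per-cell biomass `mBM_c` from mean cell volume — by default a linear
  factor of 310 fgC per µm³, which maps typical riverine cell volumes
  (0.02–0.12 µm³) onto the commonly reported 6–37 fgC per cell. The
  volume-to-carbon literature spans linear and allometric forms; both are
  available (`biomass_from_volume()`), the choice is recorded in the
  profile, and the linear default was chosen because it reproduces
  realistic biomass ranges with a single interpretable constant;
- hourly and daily division rates `CD = BSP_c / mBM_c`;
- doubling time as the **reciprocal** of the daily rate, `1 / CD_d` — the
  rate is already a count of divisions per day, so no `ln 2` enters; an
  `ln2` convention is available for exponential-rate interpretations but is
  off by default and labelled;
- cumulative doubling events over a journey, `CD_d × tt_cum` in days;
- segment cell production `aCP_h` from the mean of the endpoint BSP values
  and the upstream site's biomass, times the segment travel time; summing
  segments gives the whole-river production `CP_tot` for one travelling
  litre, compared with the median standing stock as a dimensionless ratio;
- the carbon-atom conversion `rate × N_A / M_C` that turns a per-cell
  production slope (gC cell⁻¹ h⁻¹ per travel-hour) into atoms per cell per
  hour squared.

Cumulative divisions come in two estimators: the default multiplies the
median daily rate by the total travel time (comparable with published
whole-river numbers); the alternative sums each segment's local rate times
its travel time. They agree exactly when rates are constant, a property the
tests check.

## Diversity engine

Rarefaction resamples each library **with replacement** to a fixed depth
(multinomial draws), 50 repetitions by default, then averages and rounds
half away from zero. Half-away-from-zero matters because base R rounds half
to even and the rounding decides presence/absence at the margin. Each
sample draws from a private random substream derived from the master seed
and the sample id, so adding or removing a sample never perturbs the other
samples' draws.

Beta diversity between two communities is partitioned from incidence
counts (`a` shared, `b`/`c` unique): Simpson turnover
`min(b,c)/(a+min(b,c))`, Sørensen dissimilarity `(b+c)/(2a+b+c)`, and
nestedness as their difference. The partition is exact arithmetic; the test
suite checks it against exhaustive enumeration of all small communities.
Whole-river turnover defaults to the endpoint comparison (first site
versus last site) because a single per-dataset turnover number is most
parsimoniously an endpoint contrast; the Baselga multiple-site Simpson is
provided and labelled, since survey reports rarely state which estimator
produced a single number. Presence/absence is taken from the rarefied
table by default (matching the usual pipeline order), with a
pre-rarefaction option.

Headwater persistence takes every ASV seen in the uppermost `n_head`
(default 3) sites as the pool and asks which members remain present in at
least 90% of all downstream samples.

## Trend models

Simple travel-time trends are ordinary least squares (`stats::lm`),
reported as slope ± SE with adjusted R². Backward selection starts from
the full candidate model and removes predictors by AIC (`stats::step`) or
by largest p-value above α = 0.05. AIC is the package default for
analyses; note that AIC's two-point penalty tolerates spurious predictors
at a ~16% rate each, so screening-style "noise must be dropped" behaviour
is the α-criterion's job, and the tests exercise it there.

Ordination defaults to principal coordinates (deterministic, negative
eigenvalues reported); nonmetric MDS by stress minimization from the PCoA
start (`vegan::monoMDS`, 500-iteration cap) is available behind a flag.
Deterministic PCoA was preferred as the default because vector-fitting
conclusions are robust to the ordination method while determinism keeps
every downstream number reproducible. Environmental vector fitting
regresses the variable on the ordination axes and permutes the variable for
the p-value, with `(b+1)/(B+1)` smoothing; it agrees with `vegan::envfit`
to numerical precision, which the tests verify.

The discharge-richness model regresses observed ASVs on `log2` of the
discharge ratio (each discharge normalized to the site's series minimum).
The base-2 logarithm is the only functional form under which "a doubling
in discharge adds *s* ASVs" is independent of the baseline discharge.

## Phylotype growth

Phylotypes are selected by three filters (max/min relative-abundance ratio
≥ 100, maximum abundance ≥ 1% somewhere, prevalence ≥ 20 samples). A zero
minimum passes the ratio filter by convention — these are exactly the
phylotypes blooming from zero — with a pseudocount alternative by flag.
Absolute abundances are relative abundances times TCC. Trajectories over
travel time are penalized cubic regression splines (`mgcv::gam`, basis
dimension 10, GCV-selected penalty; both the basis size and the selection
rule are package choices, since model-family conventions rarely pin them
down). Derivatives are finite differences of the prediction-matrix rows
(step 1e-5 of the grid range) with the smoother's Bayesian covariance
propagated into a ±2 SE envelope, reported as an approximate credible
band. Replicates at identical travel times are averaged before fitting.
Sitewise per-capita rates are natural-log rates, `24·ln(n_down/n_up)/tt`;
division by `ln 2` converts to doublings and is labelled.

## The synthetic generator

The generator exists so that every stage can be exercised with known
ground truth. `jds3like` (default) emulates a low-flow whole-river survey:
54 equidistant sites over 2582 km, velocities bounded by 0.9–5.4 km h⁻¹
with a downstream-decelerating profile whose shape exponent is solved so
the total travel time is exactly 49.7 days; TCC rising 9.5 × 10⁶ cells l⁻¹
per travel-hour from 6 × 10⁹; BSP falling 0.79 ngC l⁻¹ h⁻¹ per travel-hour
from 1.7 µgC l⁻¹ h⁻¹; cell volumes shrinking 0.11 → 0.03 µm³; richness
declining 0.13 ASVs h⁻¹ from 400; replacement probability 0.3 per segment;
persistent fraction 0.10; five logistic bloomers at 100× the bulk rate;
sequencing depth 10 000. `jds2like` mirrors a mean-flow survey (75 sites,
velocities 0.6–11.2 km h⁻¹, 33.7 days, ~10× lower cell counts). These
values were fixed once, from the magnitudes such surveys report, and are
not tuned per analysis.

Design choices worth knowing before interpreting recovery tests:

- **Noise is centred and of constant absolute scale.** Trend values are the
  line plus lognormal-shaped, mean-corrected noise scaled by the mid-river
  level. Proportional (heteroscedastic) noise would make OLS standard
  errors miscalibrated and turn slope-recovery checks into tests of lm's
  variance model rather than of the pipeline.
- **Richness is realized exactly.** Every member phylotype of a site's
  community receives one guaranteed read before the remaining depth is
  drawn multinomially, so column sums equal the configured depth exactly
  and observed richness equals the planted trajectory. Consequently
  richness-slope recovery measures the planted trend; measuring richness
  after rarefaction instead would add a detection-loss bias (~5–10%
  shallower slopes) that is a property of rarefaction, not of the
  generator.
- **The persistent core is sized against the measured quantity.** The
  persistence analysis reports (persisting ASVs) / (3-site headwater
  pool), and the pool includes ASVs first seen at sites 2–3. The core
  (plus the always-present bloomers) is therefore sized as
  `p·(S₁ + 2r·S̄)/(1 + 2rp)` so that the planted `persistent_fraction` is
  the expectation of the measured ratio, not of a quantity nobody
  computes.
- **Bloomers are members everywhere.** They hold one read ("nearly zero")
  upstream and grow logistically — logistic rather than exponential so
  maxima are finite and the derivative extremum has the closed form
  `rK/4` at the midpoint, which the tests use as an oracle.
- **Replacement is a Bernoulli process with a protected core** — the
  simplest generative mechanism consistent with turnover-dominated,
  nestedness-minor partitions. No claim is made that rivers work this way;
  what passing tests show is that *if* data have this structure, the
  pipeline recovers the planted parameters. Real data add spatially
  autocorrelated noise, tributary mass effects, uneven site spacing and
  detection artefacts that the generator deliberately omits.

## Numerical choices and degenerate inputs

- Travel times are stored in hours; day-denominated outputs divide by 24 at
  presentation only.
- Comparisons against printed figures round half away from zero at the
  printed precision; internal computation is never rounded.
- Zero-variance predictors, empty communities, non-positive denominators
  (TCC, biomass, travel time) and unordered transects raise immediate
  errors rather than propagating NaN.
- A downstream abundance of zero yields a `-Inf` sitewise rate with an
  `extinct` flag; an upstream zero is an error (the rate is undefined).
- Identical first and last communities make whole-river turnover 0 with a
  `degenerate` flag and a 0% contribution rather than 0/0.
- All randomness flows from one master seed through
  `derive_seed(seed, label)` substreams keyed by stable labels, so stage
  order cannot perturb results; derived seeds stay below 2³¹.

## Problem sizes used by the checks

The bundled analyses and tests run the 54-site preset (plus the 75-site
preset in the drivers), 100-seed recovery sweeps for the three planted
parameters, 1000-repetition rarefaction checks at depth 100, and
200-replicate permutation-uniformity checks at 199 permutations each —
sizes chosen so the full suite completes in a couple of minutes while
keeping binomial noise on recovery rates near ±3%.

## Known limitations

- The biomass–volume conversion constant is a convention; analyses
  sensitive to absolute biomass should vary it (the allometric option
  exists for exactly that).
- Whole-river turnover from endpoints ignores the path between them; the
  multisite estimator weights all pairs but has no single-number published
  convention either. Both are reported, labelled.
- The spline envelope is pointwise, not simultaneous; derivative sign
  changes near the boundary knots are less trustworthy than interior ones.
- `ordinate(..., method = "nmds")` reports final stress but the package
  does not attempt multi-start NMDS; for publication-grade NMDS use vegan
  directly on the exported distance matrices.
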