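---
title: "Methods: strontium-isotope origin classification and backward flight trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strontium-isotope origin classification and backward flight trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflight)
```

This vignette explains the models behind `isoflight`, the assumptions they
make, the parameters that matter, and the design choices taken where the
underlying procedure admits more than one reasonable implementation. It is
the package's own account of its science; all numbers shown are computed by
the code below or by the test suite.

## The inference problem

A moth trapped in an immigration area may be a local individual, a domestic
migrant, or an overseas immigrant. Two observables constrain its natal
origin:

1. Its body ⁸⁷Sr/⁸⁶Sr ratio. Strontium moves from bedrock through soil and
   host plants into herbivore tissue with little isotopic fractionation, so
   the ratio reflects the geology of the larval feeding area. Young volcanic
   terrain (much of the Japanese immigration areas) gives low ratios; older
   continental bedrock gives high ones.
2. Where the winds could have carried it from. Nocturnal migrants take off
   around dusk and fly downwind overnight, so backward trajectories from
   the trap site over the plausible immigration dates delimit candidate
   take-off areas.

Neither line is decisive alone — the isotope ratio is not unique to one
region, and a trajectory is only circumstantial — so the package combines a
cut-off classification of the ratio with a terminal-point frequency map and
a small decision table.

## Isotope data reduction

Thermal-ionization measurements carry instrumental mass fractionation. The
exponential-law correction normalizes the simultaneously measured ⁸⁶Sr/⁸⁸Sr
to its canonical value 0.1194:

$$\beta = \frac{\ln(0.1194 / (^{86}\mathrm{Sr}/^{88}\mathrm{Sr})_{meas})}
               {\ln(M_{86}/M_{88})},\qquad
  r_{corr} = r_{meas}\,(M_{87}/M_{86})^{\beta}.$$

When the measured ⁸⁶Sr/⁸⁸Sr equals 0.1194 the correction is exactly the
identity (a property the tests assert). Atomic masses are fixed CODATA-style
constants in `sr_constants()`.

Runs are then normalized so the batch mean of the SRM987 standard sits at
its accepted 0.71025. The normalization is an **additive offset** by
default: drift at these magnitudes (offsets of order 2e-5) makes additive
and multiplicative adjustment indistinguishable in practice (they differ by
under 1e-6 here, asserted in the tests), and the additive form preserves
differences between samples of a batch exactly. A multiplicative option is
available behind `method = "multiplicative"`. Whether fractionation
correction precedes normalization is configurable in
`reduce_measurements()`; the default order is fractionation first, which is
the natural instrument-side order. Reported ratios round to 5 decimal
places, the precision at which such ratios are printed.

The blank-contamination model is two-component mass-weighted mixing of the
sample strontium with the procedural blank. Its contract is bounded between
the two end-member ratios and its error vanishes monotonically as the blank
mass goes to zero:

```{r blank}
blank_mixing(0.71000, 7.278, blank_model(0.175, 0.70905))
```

The paired cleaned/uncleaned evaluation (`paired_cleaning_stats()`) is an
ordinary least-squares fit plus the SD of the paired differences — the
standard way to show that surface contamination does not move the ratio
materially.

## The origin classifier

`fit_origin_model()` pools reference insects and host plants (their ratios
agree closely where both exist) and fits
$P(\text{continental}) = \text{logit}^{-1}(\beta_0 + \beta_1 \cdot r)$ by
maximum likelihood through `stats::glm`. Complete separation is not an
error: the model is flagged and returned, because everything downstream
(ROC, cut-off) depends only on the score ordering, which separation leaves
intact.

The ROC is built on the **ratio scale**. The logistic is strictly monotone
in the ratio, so ratio-scale and probability-scale ROC curves are identical
point sets; the ratio scale is what field practitioners quote. Candidate
thresholds are midpoints between consecutive distinct scores, with
sentinels at ±∞. The AUC is the trapezoid area and equals the tie-corrected
Mann–Whitney probability (asserted against a brute-force pairwise oracle
and against an established ROC package). The working cut-off minimizes
$(1-\text{sens})^2 + (1-\text{spec})^2$; **ties break toward the lower
threshold**, so borderline insects are called non-local — the conservative
direction when the cost of missing an immigration event exceeds the cost of
a false alarm. The convention at the cut-off itself is strict: a ratio
exactly at the cut-off is called local/low-ratio.

Confidence intervals for the AUC use DeLong's placement-value variance by
default; a seeded stratified bootstrap is available. Both truncate to
[0, 1]. Which method produced a published interval is rarely stated, which
is why both are kept.

The Brunner–Munzel test is implemented from the published formulas
(mid-ranks, rank-based variance of the placements, Welch–Satterthwaite
degrees of freedom). Degenerate inputs are handled explicitly: identical
pooled values give an undefined statistic; complete separation gives a
±∞ statistic with relative effect 0 or 1, flagged rather than thrown.

```{r classifier}
refs <- gen_reference_set(seed = 1)
m <- fit_origin_model(refs)
m
```

## The synthetic-data generators

The generators define the study conditions under which the package is
exercised offline:

* **Reference sets** are independent Gaussians per class. The defaults are
  the reported class moments of the target system — immigration-area
  insects 0.70806 ± 0.00088, continental insects 0.71088 ± 0.00333
  (⁸⁷Sr/⁸⁶Sr, dimensionless). Only the class moments are published, so no
  site-level hierarchy is modelled; per-site structure in real data would
  tighten or widen the overlap in ways the generator cannot emulate.
* **Wind fields** are analytic — uniform, solid-body rotational, vertically
  sheared, or uniform with a cold layer — so the trajectory engine can be
  checked against closed-form truth (uniform advection, orbit closure). A
  seeded Gaussian perturbation option exists for robustness tests. Grids
  follow the archive convention the engine emulates: 1° horizontal spacing
  and 3-hourly instants, heights in m AGL. Temperature follows
  `T0 − lapse·height + A·sin(2π·hour/24)`.
* **Land masks** are rectangles (a continent west of a meridian plus an
  island band) on the 0.25° grid convention. Real coastlines are
  deliberately out of scope.
* **Trap series** are Poisson background counts with an exact spike on the
  peak date.

What passing tests on these data do **not** show: performance on real
meteorology (fronts, vertical motion, terrain), on site-structured isotope
references, or on real coastal geometry. The generators emulate the
statistical shape of the inputs, not their full richness.

## The trajectory engine

Parameters, with defaults and units (`flight_params()`):

| parameter | default | meaning |
|---|---|---|
| `self_speed` | 3.0 m/s | self-powered airspeed added along the downwind direction |
| `t_enroute_min` | 9 °C | minimum en-route temperature; colder air invalidates |
| `t_takeoff_min` | 11 °C | minimum temperature at the terminal (take-off) point |
| `start_heights` | 100–1500 m by 100 | 15 fixed starting heights, m AGL |
| `dusk_hour_utc` | 11 | fixed dusk hour (take-off), UTC |
| `duration_mode` | "short" | terminal at dusk 1 day back (13–36 h) or 2 days back (37–60 h) |
| `time_step` | 600 s | integration step |
| `calm_epsilon` | 0.1 m/s | wind speed below which the downwind direction is undefined |

The defaults are the study conditions of the analysis the package
implements: flight-mill work on armyworm-sized noctuids puts sustained
airspeed near 3 m/s, flight activity halves below ~9 °C and take-off
requires roughly 11 °C, radar observations put migration layers mostly
between 200 and 1000 m (sometimes 1500 m), and 24 hourly starts cover the
unknown arrival hour. These are the generator-side and engine-side
conditions; they are not tuning knobs.

Numerical choices:

* **Integrator**: a two-stage (Petterssen-style) predictor–corrector. The
  predictor displaces with the velocity at the current point; the corrector
  re-displaces with the mean of the current and predicted velocities. On
  smooth fields this is second-order accurate; the tests assert a 13-h
  uniform-advection displacement within 0.1% of the closed form, orbit
  closure under solid-body rotation within 2% of the radius, sub-kilometre
  sensitivity to step halving, and forward-backward reversibility.
* **Geometry**: spherical earth, radius 6371 km, local tangent update
  `Δlat = −v·Δt/R`, `Δlon = −u·Δt/(R·cos lat)`. No geodesic library is
  needed at these precisions.
* **Vertical motion**: off by default — heights are held fixed in m AGL,
  mirroring the fixed-starting-height sweep of the analysis; advection by a
  `w` field can be switched on.
* **Calm air**: below `calm_epsilon` the downwind direction is undefined and
  the self-speed contribution is suppressed rather than pointed arbitrarily.
* **Domain exit**: a trajectory leaving the field's space-time hull is
  truncated and marked `left_domain`, and excluded from terminal-point
  mapping — the conservative reading when the archive does not cover the
  candidate source.
* **Gate precedence**: a trajectory that is both en-route cold and terminal
  cold records the en-route reason; the en-route gate is evaluated over all
  steps including the terminal one, with strict `<` at both thresholds.

The published figure captions and methods text disagree slightly on the
starting-height range (0–1500 m vs 100–1500 m); the methods value
(100–1500 m, 15 heights) is used here.

How the cited trajectory tool added the self-powered vector (preprocessing
of the winds vs inside the integrator) is not documented; here it enters the
integrator's velocity directly, which is the only formulation consistent
with "wind speed + 3 m/s at the flight altitude" at every step.

## Source mapping and the decision table

Terminal points are counted on a 0.25° grid with **half-open cells**
`[west, east) × [south, north)` — the standard raster convention, stated
explicitly because edge points must land deterministically in exactly one
cell. Smoothing spreads each cell's count equally over its in-bounds 3×3
neighborhood: mass-conserving by construction, and the least-structured
kernel that reproduces the sub-unit "fractional points per cell" appearance
of published frequency maps (the exact smoothing used by the original
plotting program is unspecified; the kernel is configurable in principle
and documented as an approximation). Sea masking zeroes the smoothed values
over sea cells — a take-off over water is not a source — while raw counts
are retained for audit.

A region counts as "reached" when its smoothed mass exceeds a threshold
(default: any positive mass; configurable because published practice applies
visual judgment to maps). The decision table over the isotope call and the
reached region kinds is total and deterministic; its two deliberately
asymmetric rows are (a) a high-ratio insect whose ensemble reaches both the
continental belt and a high-ratio domestic district is **undeterminable**,
because both scenarios explain the data, and (b) a low-ratio insect whose
ensemble reaches a distant low-ratio district is called domestic non-local
even if the local area was also reached, since the distant-source signal is
the informative one.

The analytical period is the 3 days ending at the collection date plus the
`interval − 1` preceding non-survey days (3 dates for daily monitoring, 9
for 7-day intervals).

## Problem sizes and stochastic checks

The test suite and the acceptance script use sizes chosen to make
Monte-Carlo error small relative to the quantities checked while keeping
runs desk-scale: 2000 references per class for the binormal-AUC and cut-off
convergence checks (the empirical AUC is compared within 3 DeLong standard
errors of Φ(Δμ/√(σ₀²+σ₁²)), and the recovered cut-off within 5e-4 of the
analytic two-Gaussian minimizer, about the size of its sampling
variability at this n); 2000 null simulations for the Brunner–Munzel
type-I rate (binomial 3-SE band around 5%); and reduced trajectory
ensembles (2 heights × 24 hours) where a test needs many integrations.
Full 360-trajectory ensembles are exercised where the ensemble design
itself is the claim.

## Known limitations

* The classifier's cut-off is a *tentative* discriminator: real reference
  data have site structure and regional overlap the two-Gaussian synthetic
  world does not, and high-ratio areas exist inside Japan, which is exactly
  why the decision table has an undeterminable row.
* The trajectory engine is a kinematic re-implementation: no terrain, no
  data-assimilation vertical coordinates, no dispersion. It is meant to be
  validated on analytic fields and to make the ensemble design reproducible,
  not to replace an operational trajectory model on real archives.
* Dusk is a fixed hour (11:00 UTC), not a solar-elevation computation; over
  the few-degree longitude spans of interest the difference is minutes.
* Likelihood-based assignment over a bioavailable-strontium isoscape is
  deliberately not performed; agricultural inputs make field-level ratios
  unpredictable, so classification stays at the two-class cut-off level and
  geography comes from the trajectories.
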