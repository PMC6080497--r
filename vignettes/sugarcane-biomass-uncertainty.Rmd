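---
title: "From field biometrics to TCH: the models and their uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From field biometrics to TCH: the models and their uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canemass)
options(canemass.verbosity = 0)
```

# The problem

Sugarcane ground campaigns face a structural imbalance: destructive biomass
measurements (cutting, weighing, oven-drying whole plants) are expensive and
disturb the very canopy that satellite products are being validated against,
so campaigns collect mostly non-destructive biometrics — stalk height `H`,
stalk diameter `D`, cane counts per row-metre `C`, leaf area index — at many
elementary sampling units (ESUs), and destructive measurements at only a few
of them (ESUBs). `canemass` implements the chain that converts those
biometrics into cane biomass and tons cane per hectare (TCH), interpolates
them over the season, and quantifies the uncertainty of every step.

# The allometric model

Per-cane stalk biomass treats the stalk as a tapered cylinder:

$$BM_S = \frac{\pi D^2}{4}\, H\, \rho_S(t)\, F, \qquad BM_C = BM_S + BM_L(t)$$

with `rho_S(t)` the stalk mass density (kg/m^3, rising through the season as
sucrose accumulates), `BM_L(t)` the leaf biomass per cane, and `F` a
dimensionless taper factor calibrated by dividing ESUB-measured stalk biomass
by the uncorrected cylinder estimate (shipped default 0.977,
`calibrate_taper_factor()`). Yield converts per-cane biomass and row counts
to areal terms:

$$\mathrm{TCH} = BM_C \cdot C(t) \cdot 10 / S$$

where `S` is the mean row spacing (default 1.2 m, the midpoint of the 0.9 m
and 1.5 m spacings of a dual-row planting pattern) so that `C/S` is the
areal cane density in canes/m^2 and the factor 10 converts kg/m^2 to t/ha.

Two readings of the printed material deserve a note because we pin them
deliberately:

* The stalk cross-section is `pi * D^2 / 4`. Any reading that squares
  `pi * D` is dimensionally inconsistent with the destructive stalk-density
  computation (`stalk_density_from_sample()`: mass over cylindrical volume),
  which must be the algebraic inverse of the biomass equation.
* `C` is a count per row-metre and `S` a row spacing in metres; only the
  quotient `C/S` is an areal density. Internal units are strictly SI
  everywhere else (m, kg, kg/m^3, fractions), fixed once at file reading
  (`read_campaign()` converts declared units such as cm or g), because the
  equation mixes metres with kg/m^3 and a single silent cm/m slip scales
  biomass by 10^4.

# Growth interpolators

All temporal interpolation uses the three-parameter logistic
`f(t) = delta_y / (1 + exp(-k (t - t0)))` — asymptote, growth rate (1/day),
midpoint (day). Cane spatial density declines over the season, which is the
same family with `k < 0`. Fitting (`fit_logistic()`) is Levenberg–Marquardt
least squares with an analytic Jacobian; 95% confidence intervals come from
the linearised covariance with t-quantiles at `n - 3` degrees of freedom.
Optimiser tolerances default to 1e-10 (relative) and 10,000 function
evaluations; all are configurable.

**Origin forcing.** A logistic is strictly positive at `t = 0`, so an exact
zero-origin constraint is impossible. We implement the intent — the curve
should be near zero at the start of growth — as an appended pseudo-observation
`(0, 0)` whose weight (default: one observation) is configurable. This is a
modelling prior, and it trades a small bias at early ages for realism; in
exact-recovery validation against synthetic truth (whose logistic is positive
at the origin) the pseudo-observation is turned off, because with it on the
fit is deliberately not an unbiased estimator of that truth.

**The hierarchy.** A single *general* fit pools all fields' biomass values
(measured and estimated); each field is then *re-fitted* with the general
coefficients as starting values and the general 95% confidence intervals —
each side widened by 10% of the interval half-width — as box bounds
(`refit_constrained()`). The alternative widening convention (10% of the
bound's own magnitude) is available as an option; the half-width reading is
the default because it is symmetric in the coefficient scale and invariant
to the sign of the bound. The same mechanism produces per-ESU cane-density
curves from the general density fit. Re-fitted coefficients always lie
inside the widened box — that is a hard contract of the optimiser, and it is
property-tested. The constraint is also a genuine shrinkage: when a field's
true asymptote lies outside the pooled confidence box, the re-fit lands on
the boundary. That is by design — the hierarchy trades per-field bias for
stability on sparse early-season data.

Auxiliary trends (`fit_trend()`) are ordinary least squares: linear for
stalk density, through-origin second-order polynomials for leaf biomass per
cane and LAI. Whether the leaf polynomial should be origin-forced is not
fully determined by the source material; we force it (a cane with no age has
no leaves) and expose the choice as an argument. The overall RMSE of each
trend is that quantity's *function fitting precision*.

# The three precision tiers

* **Instrument operation**: dispersion when re-measuring the same plant with
  the same instrument (replicate sets of 5).
* **Idealization**: dispersion when re-measuring at the same GPS-located
  point, where a neighbouring plant is selected by chance — local plant
  variability, which *contains* the instrument component. The synthetic
  generator nests the tiers accordingly (idealization variance =
  local-variability variance + instrument variance), so recovered tables
  satisfy instrument ≤ idealization on average; violations in a recovered
  table raise a warning, never an error, since with finite replicate sets
  sampling noise can invert the order where the true sigmas are close.
* **Function fitting**: the trend-fit RMSE of the modelled quantities
  (stalk density, leaf biomass).

`replicate_sd()` uses the sample standard deviation (n−1). At five
replicates this estimator is biased low by the factor c4(5) ≈ 0.94; we do
not correct for it, and the tests document the bias instead, because the
shipped reference sigmas were produced by the same uncorrected estimator.

The *total precision at location* mixes tiers: idealization for the directly
measured `D` and `H`, fitting RMSE for the modelled `rho_S` and `BM_L` —
whose idealization precisions are excluded since the trends are fitted
through data already carrying them. The *total precision within ESU*
replaces the D/H/C dispersion with the corner-point (20 m scale) dispersion.

# Error propagation, first and second order

With independent Gaussian errors, the relative first-order term for the
stalk component is

$$\vartheta = \sqrt{(2\sigma_D/D)^2 + (\sigma_H/H)^2 + (\sigma_\rho/\rho)^2}$$

(the diameter enters squared, hence its doubled weight), and the
second-order correction collects the pairwise products,

$$\chi = \sqrt{((\sigma_D/D)^2)^2 + (2\tfrac{\sigma_D}{D}\tfrac{\sigma_H}{H})^2 + (2\tfrac{\sigma_D}{D}\tfrac{\sigma_\rho}{\rho})^2 + (\tfrac{\sigma_H}{H}\tfrac{\sigma_\rho}{\rho})^2}.$$

For TCH the same structure extends with the cane-count term and a separate
leaf component (TSH and TLH, combined in root-sum-square).

**How theta and chi combine is a pinned design choice.** The printed form of
these equations is typographically ambiguous between adding `chi` to `theta`
linearly and combining the two scaled terms in quadrature. We default to
quadrature,
`sigma^2 = (theta |X|)^2 + (chi |X|)^2 + ...`, for two reasons we verified
numerically: (1) against a 10^6-draw Monte-Carlo of independent Gaussian
inputs, quadrature agrees within about 2% across the whole CV ≤ 10% grid,
while the linear sum overshoots by 6–13%; (2) at campaign-scale CVs the
quadrature reading keeps the second-order contribution below 2 percentage
points of relative TCH precision, while the linear reading can add 7 points
or more. Both observations match the documented behaviour of the framework.
The additive reading remains available via `second_order = "additive"` and
must be selected explicitly; silent switching is not possible.

# Perturbation bands

Analytic propagation answers "what if TCH were computed directly from one
day's measurements". The band machinery answers the operative question:
how uncertain is the *fitted* TCH profile. Each of 100 replicates perturbs
every unit-visit mean with `N(0, sigma)` at its total-at-location precision
and re-runs the constrained re-fit; the field biomass ensemble and the unit
density ensemble (100 × 100, i.e. 10,000 product combinations) give a
pointwise one-standard-deviation band (`perturb_and_refit()`,
`tch_profile()`). Replicates that fail to converge are dropped and logged;
the ensemble aborts if more than 20% fail (heavily perturbed early-season
data can pin a re-fit against its bounds). Perturbation is applied to
unit-visit *means*; perturbing raw corner replicates instead is a
configuration choice the API leaves open.

Two behaviours are the framework's key findings, and both are asserted in
the test suite on the default synthetic campaign: the band's relative sd
*shrinks* from early to late season, and at late season it sits well below
the direct delta-method propagation of the same sigmas — fitting a
constrained growth model through the season's data buys real precision over
single-day propagation.

# The synthetic campaign generator

Because the original field data live in an external repository, every
downstream stage is validated against a generator with known truth
(`truth_config()`, `simulate_campaign()`). The shipped defaults emulate the
reference campaign's shape and conditions:

* 4 fields, 3–5 ESUs each, 1–2 of them destructive; 8 visits over the
  season; 4 corner replicates per visit.
* Per-field logistic biomass truth (asymptotes 1.9–2.9 kg, midpoints
  145–170 d), per-ESU logistic density decline (k = −0.004/day around 18
  canes/row-m, declining to the 8–10 canes/row-m of mature stands), linear
  stalk-density trend (450 + 1.5 t kg/m^3),
  through-origin quadratic leaf and LAI trends.
* Additive Gaussian noise at the three-tier sigmas of the shipped precision
  table (`default_precisions()`), drawn at the idealization tier for routine
  visits — the dispersion a revisit of a GPS-located point actually sees.
  Cane-mass sigmas derive from the leaf-biomass idealization sigmas divided
  by stage leaf fractions (0.5/0.15/0.07), the same construction used in
  the field to get the leaf values from cane-mass dispersion.
* Negative draws of physically non-negative quantities are redrawn
  (truncation is counted and logged: it slightly biases small-mean
  quantities upward, which matters only for near-zero early-season values).
* One master seed; each unit draws from a substream keyed on its id, so the
  same seed reproduces the identical table byte for byte and adding a unit
  never perturbs another's draws.
* `H` and `D` are derived from the truth biomass by inverting the biomass
  equation under a fixed diameter-to-height ratio (0.01): heights and
  diameters are then automatically consistent with the biomass curve,
  which is what makes zero-noise end-to-end recovery exact.

What the generator does *not* emulate: spatial autocorrelation between
units, non-Gaussian or correlated measurement errors, weather, and the
literature-reported early rise of cane density before its decline (the
shipped truth is monotone, matching the campaign's own fitted shape). Tests
passing on this generator therefore validate the estimation machinery, not
the field protocol: they say nothing about representativeness of plant
selection or about errors the Gaussian tiers cannot express.

# Numerical choices and degenerate inputs

* Logistic exponent clamped at ±700 to avoid overflow at extreme `t`.
* Confidence intervals fall back to `NA` when the Jacobian cross-product is
  numerically rank-deficient (reciprocal condition below 1e-14); re-fit
  boxes built from absent or degenerate intervals fall back to a ±50%
  window around the estimate, and every box is kept non-degenerate by an
  epsilon so the optimiser accepts it.
* Trend fits with a constant abscissa raise a fit error (rank deficiency)
  rather than returning NA coefficients.
* Growth stages: early is `t < 150`, mid is `150 ≤ t ≤ 300`, late is
  `t > 300`; stage-representative days are 75/225/350.
* Variogram bins are half-open `[lo, hi)`; a pair on the last edge is
  outside. `2*gamma` is the mean squared difference per bin (twice the
  classical semivariance), the definition matching how the transect results
  are reported.
* Precipitation agreement defaults to the mean pairwise agreement over
  station-pair-days (missing values excluded pairwise); an all-station
  unanimity rate is available by flag. The pairwise definition is the one
  we pin, since the source material does not spell its definition out.
* Taper calibration defaults to the mean of per-sample ratios; the pooled
  ratio (sum over sum) is an option. The two differ only at second order
  in the sample scatter.

# Problem sizes used in validation

The shipped validation runs use: 10^6-draw Monte-Carlo oracles on a 27-point
CV grid for the propagation identities; 100 synthetic campaigns for
parameter recovery; 100 × 100 perturbation ensembles on a 5-day grid for the
band/propagation comparison; 200 random transects against a brute-force
variogram oracle. These sizes give sampling error comfortably below the
tolerances they are checked against (e.g. the Monte-Carlo sd of a 10^6-draw
sigma estimate is ~0.1% relative, against a 5% band).

# Known limitations

* The constrained re-fit's shrinkage means per-field asymptotes are
  recovered with a median error that grows with true inter-field spread;
  under the default conditions the median relative asymptote error is
  below 10%, but an outlier field pinned at the pooled bounds can carry a
  20% error. That is inherent to the hierarchy, not a defect of the
  optimiser.
* Propagation assumes uncorrelated errors; wind-lodged plots or a single
  miscalibrated instrument violate that and would widen true uncertainty.
* Leaf biomass receives no wet/dry correction in the biomass equation; the
  wet-content module reports contents but does not feed them back.
* The variogram module estimates; it does not fit spherical/exponential
  models or krige.
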