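---
title: "Probabilistic screening of radionuclide concentrations in bottom sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic screening of radionuclide concentrations in bottom sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaprog)
```

## The problem

Nuclear power plants routinely discharge small, authorised quantities of
radionuclides with their liquid effluents. The resulting activity
concentrations in the receiving water are far below detection limits, but
bottom sediments integrate the discharge over years through continuous
sorption and deposition, so sediment monitoring data are one of the few
places where the environmental footprint of routine discharges can actually
be measured — and where the *conservatism* of generic screening models
(their intended tendency to over-predict) can be tested against reality.

`aquaprog` implements that test as a reproducible pipeline:

1. infer a probability distribution for the **source term** (release rate,
   Bq/s) from a few years of annual discharge data;
2. propagate it by **Monte Carlo** through a steady-state **dispersion
   model** for the receiving water body (reservoir, river, or coast) and a
   **sediment partitioning model** with stochastic distribution
   coefficients;
3. summarise the resulting distribution of bottom-sediment concentration
   (Bq/kg dry) and **compare** it with measured environmental ranges;
4. estimate the **global-fallout baseline** that explains measured
   Cs-137/Sr-90 levels which cannot be attributed to the plant.

Only Co-60, Cs-137 and Sr-90 ship in the nuclide table: across the studied
monitoring programmes these are the only nuclides with values above
detection limits, and Co-60 — short-lived, with no fallout background — is
the only clean indicator of plant discharges.

## Source-term inference

Annual discharge data come as five consecutive annual mean release rates.
With so few values, a triangular distribution is the standard subjective
choice: `fit_triangular_source()` takes the observed minimum and maximum as
the bounds and the series arithmetic mean as the central tendency estimator.
By default the mean is used directly as the triangular *mode*
(`mode_convention = "mode_is_mean"`); the alternative `"match_mean"`
convention solves `mode = 3*mean - min - max` so that the distribution's
expectation equals the series mean. The default is the simpler literal
reading; both are provided because either reading is defensible, and for the
shipped data the difference in the fitted mode is a few per cent. A series
with zero spread degenerates to a point distribution with a warning.

## Dispersion models

All three models are steady-state analytical screening solutions, linear in
the release rate `Q`, returning the *total* (dissolved + sorbed to
suspended matter) concentration in water, in Bq/m^3 internally (SI
consistency with Bq/s and m^3/s; conversion to litre-based units happens
only at the I/O surface).

**Reservoir / lake** (`lake_concentration`). A single instantaneously and
homogeneously mixed box at equilibrium:
`C = Q / (outflow + lambda * V)`. The decay term `lambda * V` is the same
physics as decay during residence; no further transit decay is applied.
There is no receptor dependence.

**River** (`river_concentration`). Plug flow at velocity `U` with
first-order decay over the travel time `d/U`. Beyond the complete lateral
mixing distance `L = 7 * width^2 / depth` a bank discharge is uniformly
mixed over the cross-section and
`C = (Q / flow) * exp(-lambda * d / U)` on either shore. Closer than `L`,
a receptor on the *discharge* shore sits in the still-unmixed bank plume:
the fully mixed value is multiplied by the partial-mixing factor
`sqrt(L/d)`. This is the lateral-Gaussian `1/sqrt(d)` plume growth pinned
to exactly 1 at `d = L`, which makes the factor continuous at the mixing
distance (no jump as a receptor crosses `L`) and always `>= 1`.
Opposite-shore receptors conservatively use the fully mixed form at any
distance.

**Coast** (`coastal_concentration`). A lateral-Gaussian plume in an
alongshore current with reflection at the shoreline:

```
C(x, y) = Q * exp(-lambda*x/U) / (sqrt(2*pi) * sigma_y(x) * depth * U) *
          [exp(-(y-y0)^2 / (2*sigma_y^2)) + exp(-(y+y0)^2 / (2*sigma_y^2))]
```

with plume growth `sigma_y(x) = alpha * x^(7/6)` — the power law implied by
scale-dependent (4/3-law) horizontal diffusivity in coastal waters, under
which the plume spreads faster than linearly and a receptor moving away
*along* a fixed bearing can see its concentration first rise and then fall.
The plume-growth coefficient `alpha` defaults to 0.0124 m^(-1/6), a value
representative of empirical coastal diffusion data; it is a model constant
of the package, fixed once, and is exposed as `dispersion_coeff` for users
with site-specific information. With a shoreline release (`y0 = 0`) the
reflection doubles the plume.

## Sediment model

The water-to-sediment transfer has three factors
(`dissolved_fraction()`, `buildup_factor()`,
`bottom_sediment_concentration()`):

* equilibrium partitioning between solution and suspended matter,
  `C_dis = C_tot / (1 + Kd * 1e-3 * S_s)` with `Kd` in L/kg and the
  suspended load `S_s` in kg/m^3 (the `1e-3` converts L/kg to m^3/kg —
  Kd is kept in L/kg throughout configs precisely to avoid silent
  factor-1000 slips);
* sorption onto the bed, `Kd * 1e-3 * C_dis`, with a top-layer fraction
  (default 0.1) for the share of deposited activity residing in the sampled
  surface layer;
* the time-averaged build-up factor
  `B(lambda, T) = (1 - exp(-lambda*T)) / (lambda*T)` for a discharge period
  of `T = 30` years, i.e. the mean of `exp(-lambda*t)` over the
  accumulation period. `B -> 1` for long-lived nuclides; for Co-60 at 30
  years it is ~0.25, which is why the short-lived indicator nuclide ends up
  relatively depleted in sediment. Below `lambda*T = 1e-8` a second-order
  series expansion avoids cancellation.

Default suspended loads are 0.05 kg/m^3 for freshwater and 0.01 kg/m^3
for coastal water (coastal waters carry less suspended matter); both are
per-scenario settings.

## Stochastic inputs and seeding

Kd is sampled per Monte-Carlo draw as a lognormal around the tabulated
geometric mean in *freshwater* scenarios and held at the geometric mean in
*marine* scenarios (the stochastic treatment is documented for the
freshwater cases only; `kd_stochastic` switches either behaviour). The
geometric standard deviation shipped in the nuclide table (2.5 for all
three nuclides) is a calibration input of the package: it was fixed once
from the spread of the reference reservoir Co-60 interval, whose 95% ratio
of ~36 between upper and lower bound corresponds to a GSD of about 2.5, and
has not been adjusted since. Q and Kd are sampled independently; no
correlation between them is asserted by the data.

One root seed drives a run. Per-(stage, nuclide) sub-streams are derived
from it by hashing, so adding a nuclide or a receptor never perturbs the
draws of the others, and identical seeds give bit-identical results. The
"95% confidence interval" of each output cell is the empirical
2.5th–97.5th percentile interval of the draws — the natural summary for a
Monte-Carlo output distribution. (The reference reservoir Cs-137 row,
mean 127 / SD 62 / interval 87–130, is not self-consistent with any
percentile interval; the package reports honest percentiles and makes no
attempt to reverse-engineer that cell.)

Default draw count is 10,000, which resolves the reported 2-significant-
figure means to well under a per cent of Monte-Carlo error while keeping a
full three-site run under a second.

## Site fixtures and calibration

The shipped scenario files encode the three studied sites: a dammed cooling
reservoir (Almaraz), a Mediterranean coastal release (Vandellós II, outfall
on the shoreline, receptors at (500,50) … (5000,500) m), and a river reach
(Ascó, receptors 500–2000 m downstream on either shore). The published
record gives the source terms and the measured sediment ranges but *not*
the site hydrology, so the hydrological fixture values are reconstructed by
calibration: `calibrate_scenario()` adjusts named free scenario parameters
(reservoir volume and outflow; river velocity; coastal depth) to match
deterministic model runs — all stochastic inputs at their central values —
to the reference table means, minimising the sum of squared log ratios.
The river calibration keeps width and depth fixed at values satisfying the
documented complete-mixing distance `7 * width^2 / depth = 14000` m as a
hard constraint. Calibration was performed exactly once; the results are
committed in the fixture files with provenance comments, and ordinary runs
never self-calibrate. Because the calibration is deterministic while the
reported statistics are Monte-Carlo means over skewed input distributions,
the probabilistic means sit 10–20% above the deterministic anchors — well
inside the factor-of-2 fidelity that an unpublished-hydrology
reconstruction can claim.

## Comparison and verdicts

`compare_prognosis()` computes, per nuclide and receptor,
`ratio_mean_mid` (model mean over measured-range midpoint — the headline
conservatism ratio) and `ratio_max_max` (model upper 95% bound over
measured maximum). Both variants are reported because summary statements
like "at maximum 1.1 times higher" in the source material do not pin down
which quantities were divided. Verdicts use a configurable threshold `r`
(default 1.5): `conservative` above `r`, `comparable` within `[1/r, r)`,
`non_conservative` below, and `not_comparable` when the measurements were
below the detection limit (as reservoir Sr-90 always was). The thresholds
are reporting conventions, not science; they live in config.

## Synthetic data

`synthetic_spec()` + `generate_discharge_series()` /
`generate_measured_range()` emulate the *structure* of the real inputs: a
handful of annual means drawn from a known release-rate distribution, and
measurement ranges built as a symmetric multiplicative band
`truth * bias * (1 ± 2*cv)` (the k = 2 coverage convention), flagged when
below a detection limit. They make every stage testable against known
ground truth — e.g. biasing measurements by `1/r` must return conservatism
ratios of `r` end to end. What they deliberately do **not** emulate:
temporal trends or autocorrelation in discharges, the actual distributional
shape of monitoring uncertainties, spatial heterogeneity of sediments, or
count-statistics of gamma spectrometry. Passing the synthetic recovery
tests therefore validates the propagation machinery, not the realism of
any site fixture.

## Numerical choices and edge cases

* Year length fixed at 3.1536e7 s (365 d) in every half-life conversion.
* Triangular sampling by closed-form inverse CDF; all supported
  distributions have non-negative support for valid parameters, so negative
  concentrations are impossible by construction.
* The river model refuses `d = 0` (not applicable at the outfall); the
  coastal model refuses receptors up-current of the release.
* `buildup_factor()` matches its defining integral to 1e-10 (tested).
* Sample SD uses the n-1 denominator; percentile intervals use the default
  empirical quantile definition.
* Degenerate inputs (zero-spread discharge series, missing Kd spread)
  degrade to point distributions with warnings rather than failing.

## Known limitations

* The dispersion kernels are screening-level: steady state, uniform flow,
  no estuary model, no sediment-transport dynamics, no resuspension or
  pore-water diffusion, no depth-resolved profiles.
* Kd geometric means are generic handbook sediment values; site-specific
  geochemistry can shift Kd by an order of magnitude, and the freshwater
  Cs-137 value consistent with the reservoir response over-predicts the
  river response (the two published responses are mutually inconsistent
  under any single Kd).
* Fixture hydrology is a calibrated reconstruction, not measured data;
  results transfer to other sites only after re-parameterisation.
* Atmospheric discharges, food-chain transfer and dose assessment are out
  of scope.
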