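---
title: "Water quality indices and probabilistic nitrate risk: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water quality indices and probabilistic nitrate risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqrisk)
```

## What this package computes

`wqrisk` implements the computational chain of a seasonal reservoir
water-quality assessment: (1) rating raw physicochemical and microbial
measurements into parameter sub-indices and aggregating them into two
composite indices with quality classification; (2) deterministic
non-carcinogenic risk of nitrate in drinking water (chronic daily intake and
hazard quotient per age group); (3) Monte Carlo propagation of the hazard
quotient through configurable input distributions; and (4) variance-based
Sobol sensitivity analysis of the hazard quotient with first-, second- and
total-order indices.

## The two indices

Both indices start from the same primitive: a **rating curve** mapping a raw
parameter value to a dimensionless sub-index. Curves are piecewise linear
over ordered breakpoints, and values outside the breakpoint domain are
clamped to the terminal sub-index — a curve is flat beyond its ends, which
is the conventional reading of the published curve plots and keeps extreme
values from extrapolating to nonsense.

**NSFWQI** is a weighted arithmetic mean of sub-indices \(Q_i \in [0,100]\):
\[
\mathrm{NSFWQI} = \frac{\sum_i Q_i W_i}{\sum_i W_i},
\]
with conventional weights over nine parameters (dissolved oxygen saturation
0.17, fecal coliform 0.16, pH and BOD\(_5\) 0.11, nitrate, phosphate and
temperature 0.10, turbidity 0.08, total solids 0.07).

**IRWQISC** is a weighted geometric mean of sub-indices \(I_i \in [1,100]\):
\[
\mathrm{IRWQISC} = \Big(\prod_i I_i^{W_i}\Big)^{1/\gamma},
\qquad \gamma = \sum_i W_i,
\]
over eleven parameters (weights 0.140 down to 0.051; see
`default_registry()`). It is computed in the log domain,
\(\exp(\sum W_i \ln I_i / \gamma)\), which is exact for the same expression
and avoids underflow when many small sub-indices multiply. The geometric
form penalizes a single very bad parameter more than the arithmetic form;
by the AM–GM inequality the geometric index never exceeds the arithmetic
one for the same sub-indices and weights, which the test suite asserts as a
property.

**Missing parameters.** Both formulas divide by the sum of the weights that
are actually present, so a partially measured cell renormalizes rather than
failing. This is standard NSF practice and the only reading under which the
explicit \(\sum W_i\) denominator does anything (the full weight vectors
already sum to 1). The reported `used_weight_sum` lets users audit how much
of the weight vector backed any given score.

**Classification.** The published band tables have small gaps between bands
(e.g. 25 → 26, 44.9 → 45). Scores are continuous, so the bands are made
contiguous and upper-inclusive at the printed upper bounds. The IRWQISC
table leaves scores below 15 unlabelled; "Very bad" is extrapolated there,
mirroring the band naming one step further down. Labels are always derived
from unrounded scores.

**Rating curves are stand-ins.** No study publishes the exact digitized
curves it used. The packaged CSV curve tables encode the public NSF Q-value
curve shapes and plausible IRWQISC rating shapes; they are explicitly
replaceable (`read_curves_csv()`), and every unit test of the engine uses
synthetic curves so that engine correctness never rests on the packaged
tables. Two caveats worth knowing: the NSF temperature curve is defined in
the literature on the *deviation* from equilibrium temperature; the
packaged stand-in maps measured temperature with a peak near 15 °C, which
mimics a zero deviation at a temperate-reservoir equilibrium. And dissolved
oxygen is consumed directly as percent saturation — converting mg/L using
temperature and pressure is out of scope.

**Rounding.** Printed-table comparisons use decimal-string rounding, half
away from zero, at the printed precision (`round_half_up()`). Rounding the
binary double directly misrounds values such as 42.35 (stored fractionally
below the decimal midpoint); recovering the short decimal expansion first
avoids that artifact. Seasonal tables report one decimal; risk tables two.

## Deterministic exposure risk

Chronic daily intake of nitrate through drinking water:
\[
\mathrm{CDI} = \frac{C \cdot IR \cdot ED \cdot EF}{BW \cdot AT}
\quad \text{(mg/kg/day)}, \qquad
\mathrm{HQ} = \frac{\mathrm{CDI}}{\mathrm{RfD}},
\]
with \(AT = ED \times 365\) days, so CDI reduces to
\(C \cdot IR \cdot EF/(BW \cdot 365)\) and is independent of the exposure
duration. Defaults (per `default_exposure()`): ingestion rates 1.25 / 1.58
/ 1.95 L/day for children / teenagers / adults, exposure frequency 345
days/year, body weights 16.41 / 39.83 / 77.45 kg, nitrate RfD 1.6
mg/kg/day. \(\mathrm{HQ} \ge 1\) flags unacceptable non-carcinogenic risk.
Because IR/BW decreases from children to adults, children always carry the
highest hazard quotient at a fixed concentration — a monotone ordering the
tests assert.

A note on the reference risk table this package's fixtures encode: its
printed CDI column equals HQ/RfD (i.e. CDI/RfD\(^2\)), not the CDI of the
intake equation — at the maximum observed concentration the equation gives
≈ 2.56 mg/kg/day for children, while the table prints 1. The package
reports the intake equation at face value and anchors its checks on the HQ
values, which are internally consistent with the equations. The standard
deviation convention is the sample one (n − 1); the reference does not
state its convention, and only min/max are anchored (the underlying 60
monthly concentrations are unpublished — the packaged range 7.8–35.6 mg/L
is what is known).

## Monte Carlo propagation

`mc_hq()` samples the stochastic inputs (any of C, IR, EF, BW; unspecified
inputs sit at the group's point values), pushes each joint draw through the
intake equations, and reports the 5th/50th/95th percentiles, mean, sd and
\(P(\mathrm{HQ} \ge 1)\). Implementation choices:

* **Quantile convention**: linear interpolation of order statistics (R's
  type 7). Stated because software conventions differ enough to move a
  95th percentile visibly at moderate n.
* **Truncation** is exact inverse-CDF on the restricted probability range,
  not accept–reject, so run length is deterministic and seeds map to the
  same draw count.
* **Seeding**: each input's stream is derived from the master seed and the
  input's *name*, so adding or reordering inputs does not silently change
  another input's draws, and permutation invariance is exact.
* Default n = 50,000 draws; a seed is mandatory (there is no hidden default
  in the CLI).

The reference study reports Monte Carlo percentiles but not its input
distributions, so those percentiles are not reproducible and are not
asserted anywhere. The shipped example configuration
(`default_distributions()`) is for illustration and rank-level checks only:
concentration lognormal fitted so that its central 95% spans the observed
7.8–35.6 mg/L range and truncated to it; ingestion rate lognormal around
the group default with sdlog 0.5 (drinking-water ingestion is strongly
right-skewed across individuals); exposure frequency uniform over 180–365
days/year; body weight normal with a 15% coefficient of variation,
truncated to physiological bounds. The "certainty level" language sometimes
attached to such analyses is surfaced only as \(1 - P(\mathrm{HQ} \ge 1)\);
no further semantics are asserted.

## Sobol sensitivity analysis

`saltelli_design()` draws two independent N × k base matrices A and B from
the input marginals and builds the column-swapped matrices
\(A_B^{(i)}\) and \(B_A^{(i)}\); the full design costs \(N(2k+2)\) model
evaluations. `sobol_indices()` then estimates, with
\(V = \widehat{\mathrm{Var}}(f(A) \cup f(B))\):

* first order (Jansen):
  \(S_i = 1 - \frac{1}{2NV}\sum_j \big(f(B)_j - f(A_B^{(i)})_j\big)^2\)
* total order (Jansen):
  \(T_i = \frac{1}{2NV}\sum_j \big(f(A)_j - f(A_B^{(i)})_j\big)^2\)
* closed second order (Saltelli 2002):
  \(V^c_{ij} = \frac{1}{N}\sum_j f(B_A^{(i)})_j\, f(A_B^{(j)})_j - f_0^2\),
  with \(f_0^2 = \overline{f(A)}\,\overline{f(B)}\) and
  \(S_{ij} = V^c_{ij}/V - S_i - S_j\) — the *pure* pairwise interaction.

The Jansen estimators were chosen for their low variance and because the
extended (B\(_A\)) design supports all three index tiers the analysis
needs. Sampling is plain pseudo-random; the design abstraction would admit
low-discrepancy sequences but none is required. Small-sample estimates can
be slightly negative and are reported as-is — clipping at zero would bias
averages and hide estimator noise — with percentile-bootstrap intervals
(resampling design rows jointly, preserving the A/B pairing) conveying the
uncertainty. A numerically constant output (variance below
\(10^{-12}\times\) mean²) returns all-zero indices with a warning rather
than 0/0.

Correctness is anchored on closed forms, not on another library: the
Ishigami function (a = 7, b = 0.1), whose \(S\), \(T\) and single non-zero
closed second-order index are analytic, and additive models, where
\(S_i = a_i^2 \mathrm{Var}(x_i)/V\), \(\sum S_i = 1\) and all
\(S_{ij} = 0\). Under the shipped example configuration the ingestion rate
carries the largest first- and total-order index in every age group — the
same qualitative ranking (IR > C > EF > BW) the reference study prints for
children — and the tests assert exactly that rank statement, never the
numeric index values, since those depend on the unstated distributions.

## The synthetic generator: a stated world

`generate_measurements()` emulates the campaign's structure — 5 stations ×
4 seasons × 13 parameters, one observation per cell — with independent
draws per parameter from the reported spans: nitrate 7.8–35.6 mg/L, pH
6.48–7.9, temperature 12–26 °C, turbidity 8–24 NTU, total solids 10–40
mg/L, total hardness 154–530 mg CaCO₃/L, fecal coliform 0–125 CFU/100 mL,
phosphate 0.4–2.3 mg/L, BOD₅ 2–8.3 mg/L. Where only partial statistics are
reported the defaults bracket them: DO 35–38% saturation and COD 10–54
mg/L (station means), ammonium lognormal around the reported 0.012 mg/L
mean with sdlog 0.5 (only the mean is reported; a small positive spread is
the least committal choice), and EC 700–1600 µS/cm — a plausible span for
a semi-arid irrigation reservoir, chosen once since no EC values are
printed. Everything is overridable per parameter.

The generator deliberately does **not** model spatial or temporal
correlation, monthly-within-season structure, detection limits, or
inter-parameter dependence (e.g. BOD–DO coupling). A green end-to-end test
therefore establishes that the pipeline is correct on tables with the right
schema, ranges and size — not that the packaged curves reproduce any
particular published score, which would require the study's unpublished raw
data. The published seasonal score tables are instead shipped verbatim as
fixtures (`load_fixture()`), and the aggregation/classification stages are
validated against those printed cells directly. Three of the twenty
printed mean cells are internally inconsistent with their own member cells
(off by 0.1, consistent with averaging unrounded monthly scores); the
fixture test freezes those three as known divergences and asserts exact
recomputation for the other seventeen.

## Degenerate inputs and numerical edges

* Curves require ≥ 2 strictly increasing breakpoints; ratings clamp, never
  extrapolate.
* The geometric index errors on any sub-index ≤ 0 (undefined mean);
  `compute_wqi()` floors curve output at 1 for the 1–100 scheme first.
* Empty sub-index sets, empty groups, concentration lists shorter than 2,
  negative concentrations, non-positive RfD, and out-of-range scores are
  all hard errors, not warnings.
* Pipeline outputs are CSV + JSON twins stamped with the master seed and a
  config fingerprint; two runs under one seed are byte-identical, which the
  test suite checks literally.

## Known limitations

Packaged rating curves are best-effort stand-ins; DO unit conversion,
carcinogenic (slope-factor) risk, dermal/inhalation routes, correlated
inputs (copulas), variance reduction, and GIS outputs are out of scope. The
reference study's Monte Carlo percentiles and numeric Sobol indices are
unrecoverable without its input distributions and are intentionally not
asserted.
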