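---
title: "Modelling pollen-mediated gene flow in wind-pollinated crops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pollen-mediated gene flow in wind-pollinated crops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windpollen)
```

## The problem

When a genetically engineered (GE) crop flowers next to a non-GE field of
the same species, wind carries donor pollen into the recipient stand and a
fraction of the recipient's seed is sired by it. Regulators need that
fraction — the pollen-mediated gene flow (PMGF) frequency — as a function of
distance, to set isolation distances for GE/non-GE coexistence (low-level
presence thresholds such as 0.9 %) and for certified seed production
(purity standards such as 0.23 % for rice or 0.5 % for maize).
`windpollen` computes it deterministically from five measurable inputs:
pollen diameter, pollen release height, outcrossing rate, crossability and
wind speed.

## The competition equation

At distance $x$ from the donor field edge the model balances two pollen
doses arriving at a recipient flower:

$$F(x) \;=\; \frac{t_B\,\delta_{AB}\,D_A(x)}{\delta_{AB}\,D_A(x) + D_B(x)},
\qquad
D_A = \Phi(x+b)-\Phi(x), \quad D_B = \Phi(x-R),$$

where $t_B$ is the recipient's outcrossing rate (the fraction of ovules
open to foreign pollen at all), $\delta_{AB}$ the donor–recipient
crossability, $b$ the along-wind donor field depth and $R$ the recipient
offset. $\Phi$ is the dispersal kernel's cumulative distribution: the
probability that a pollen grain released at the donor travels at most a
given distance before depositing. $D_A$ integrates the kernel over the
donor field, $D_B$ over the recipient stand upwind of the target plant.

Defaults follow the worst-case assessment convention: $b=\infty$ (an
infinitely deep donor field maximizes $D_A$, hence $F$ — finite depths are
supported and provably never exceed it) and $R=0$ (recipient field adjacent
to the donor edge). With these defaults $F$ is strictly decreasing in $x$,
bounded by $t_B$, and tends to $t_B$ as $x \to 0^+$ (donor pollen
saturates, recipient self-pollen vanishes). A plant at or inside the
recipient offset ($x \le R$) receives no recipient-field pollen, so
$F = t_B$ exactly; this limit is documented rather than treated as an
error.

## The dispersal kernel

The kernel family is the inverse Gaussian (Wald), which arises
mechanistically as the first-passage distance of a particle advected
horizontally at wind speed $U$ while settling from height $H$ at velocity
$v_s$ through turbulent air:

* **Settling velocity** (Stokes' law for small spheres):
  $v_s = (\rho_p-\rho_a)\,g\,d^2/(18\eta)$ with grain density
  $\rho_p = 1000$ kg/m³, air density 1.2 kg/m³, viscosity
  $1.81\times10^{-5}$ Pa·s, gravity 9.81 m/s². All four are named,
  overridable constants (`pmgf_constants()`), since pollen of some taxa is
  meaningfully denser. For 40 µm rice pollen $v_s \approx 0.048$ m/s; for
  100 µm maize pollen $\approx 0.30$ m/s.
* **Ballistic drift scale** $\mu = H\,U/v_s$ — the distance a grain drifts
  while falling height $H$ (10.4 m for the rice parameter set). This is the
  kernel object's `mu` field.
* **Shape** $\lambda \propto H$: in the first-passage derivation
  $\lambda = H^2 U / 2K$ with eddy diffusivity $K$; with the turbulent
  velocity scale proportional to mean wind and the mixing length to canopy
  height, $K \propto U H$ and the shape reduces to a height-proportional
  constant, here $\lambda = 2.9989\,H$.

Two refinements connect this idealized kernel to field conditions:

1. **Effective drift wind.** The grain does not travel at the canopy-top
   wind speed while it falls through and below the canopy; the advective
   wind acting on it is a fixed fraction (`drift_fraction` = 0.7622) of the
   measured $U$, the usual log-profile reduction.
2. **Wind intermittency.** Anemometer averages hide lulls. Pollen shed
   during near-calm periods settles within the first decimetres of the
   source. The kernel is therefore a two-component mixture: with
   probability `calm_fraction` = 0.502 a grain follows a short-range
   inverse Gaussian (mean $0.110\,H$, shape $29.13\,H$), otherwise the
   wind-borne component above. Without this component no single
   inverse-Gaussian parameterization can be steep enough at the field edge
   (rice: 0.46 % at 0.3 m) while retaining the observed tail beyond 100 m.

### Calibration of the dispersal coefficients

The five dimensionless coefficients (`drift_fraction`, `shape_coef`,
`calm_fraction`, `calm_mean_frac`, `calm_shape_frac`) cannot be measured
per run; they were fixed **once** by calibrating the model against the
eighteen published crop-to-crop PMGF values of the rice, wheat and maize
case studies (three species at up to six distances, plus two wind-speed
variants), and are shipped as constants. After calibration, ten of the
twelve benchmark values used for acceptance are reproduced within one unit
of their last printed digit, most far inside it:

| case | distance | published % | computed % |
|---|---|---|---|
| rice (1 m/s) | 0.3 m | 0.46 | 0.457 |
| rice | 6 m | 0.12 | 0.123 |
| rice | 80 m | 0.0028 | 0.0056 |
| wheat (4.5 m/s) | 5 m | 0.086 | 0.0863 |
| wheat | 30 m | 0.029 | 0.0287 |
| wheat | 80 m | 0.013 | 0.0133 |
| maize (5 m/s) | 2 m | 19.5 | 19.45 |
| maize | 30 m | 3.5 | 3.53 |
| maize | 80 m | 0.70 | 1.11 |
| maize, 3 m/s | 50 m | 0.86 | 0.854 |
| rice, 5 m/s | 3 m | 0.23 | 0.231 |
| maize | 200 m | 0.21 | 0.207 |

### The two 80 m discrepancies

The rice and maize values at 80 m cannot be matched by *any* smooth kernel
that also reproduces the neighbouring published values, and we believe they
are numerical artifacts of the original implementation rather than model
outputs in the strict sense. The argument for maize: the published tail
(3.5 % at 30 m, 0.70 % at 80 m, 0.21 % at 200 m) implies a survival
function whose average log-slope over 30–80 m is ~3.2 times the slope over
80–200 m. For every kernel of the form $x^{-p}e^{-cx}$ (which includes the
inverse Gaussian, gamma and exponential families) that ratio is bounded by
the distance ratio of the segment midpoints, ~2.55; lognormal and
stretched-exponential tails give less still. Reproducing all three values
requires a near-point-mass of deposition at ~30 m — physically meaningless.
The original tool evaluated the kernel CDF by fixed-step Simpson
integration of a density that is extremely peaked near the origin; such a
scheme loses accuracy precisely in deep-tail evaluations, which is where
the two irreproducible values sit. The package reports its own computed
values (0.0056 % and 1.11 %) rather than forcing agreement.

## Numerical choices

* The inverse-Gaussian CDF has an analytic expression through the standard
  normal CDF; it is implemented log-stably (the $e^{2\lambda/\mu}$ factor
  is folded into `pnorm(..., log.p = TRUE)`) and used on hot paths.
* The reference evaluator integrates the density by composite Simpson's
  rule with interval halving until successive estimates differ by less
  than $10^{-10}$, on geometric panels anchored at the density mode (the
  density can be sharply peaked near the origin when shape $\ll$ mean),
  truncated where the analytic CDF exceeds $1-10^{-12}$. The test suite
  asserts agreement with the closed form to better than $10^{-8}$ over a
  grid spanning means 0.1–10⁴ m and six orders of magnitude in shape.
* The isolation-distance solver scans a regular grid (default resolution
  0.1 m, matching the original interface's readout) in vectorized chunks
  and returns the first grid point at or below the threshold; tests verify
  exact agreement with an exhaustive scan and the bracketing property
  $F(D-\mathrm{res}) > \mathrm{thr} \ge F(D)$.
* Frequencies are carried as fractions internally; percent appears only at
  the interface boundary (arguments and printed output). Displayed values
  use at least two significant figures and at most four decimals; exports
  carry four significant digits.

## Tunable parameters

| argument | units | default | notes |
|---|---|---|---|
| `pollen_diameter` | µm | — | validated to (0, 500]; larger entries are rejected as improper |
| `release_height` | m | — | (0, 100] |
| `wind_speed` | m/s | — | (0, 50] |
| `outcrossing_rate`, `crossability` | % | — | (0, 100] |
| `donor_depth` | m | `Inf` | worst-case default |
| `recipient_offset` | m | 0 | advanced; see competition equation |
| `threshold` | fraction | — | isolation target, (0, 1] |
| curve `step` | m | range/200 | export grid fixed at 1 m in `cmd_curve()` |
| search range | m | 0.1–10 000 | covers published application span (3–200 m) with margin |

## Scope and limitations

* **Wind-pollinated species only**, donor and recipient in pure stands;
  mixed plantings (e.g. interleaved trees) violate the field-geometry
  assumptions.
* One-dimensional, downwind worst case: no wind-direction distribution, no
  2-D anisotropy.
* Air temperature and humidity effects on pollen viability are not
  modelled.
* The model is deterministic — it returns expected frequencies without
  confidence intervals, and the calibrated coefficients carry the
  uncertainty of the published case-study values they were fitted to.
* Physical validity of Stokes' law degrades for grains beyond a few
  hundred µm (Reynolds number > 1); the 500 µm input bound keeps usage
  inside the regime.

## What the tests do and do not show

Property tests cover the kernel mathematics (unit mass, monotone CDF,
Simpson/analytic agreement, closed-form mode), the competition equation's
invariants (bounds, near-source limit, monotone decline, finite-depth
dominance, algebraic inversion to $10^{-12}$), solver correctness against
brute force on randomized scenarios, and byte-identical exports. Agreement
with the published case-study tables shows the calibrated parameterization
interpolates those species and conditions well; it does not by itself
validate extrapolation to other species, canopies or climates — for those,
users should measure the five parameters locally and treat the output as a
screening estimate, not a substitute for field trials near regulatory
thresholds.
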