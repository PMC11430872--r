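---
title: "Models and methods behind rwdry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rwdry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwdry)
```

rwdry implements the complete analysis chain for thin-layer refractance
window (RW) drying experiments on leafy material such as mint: drying
kinetics, moisture diffusivity and its temperature dependence,
transition-state thermodynamics, energy and emission accounting, color
and quality metrics, and a Levenberg–Marquardt-trained feedforward
network that predicts moisture ratio from water temperature and drying
time. This vignette describes the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## Moisture ratio and thin-layer models

Mass readings are converted to dry-basis moisture
$X_t = (m_t - m_\mathrm{dry})/m_\mathrm{dry}$ and normalized to the
moisture ratio

$$\mathrm{MR}(t) = \frac{X_t - M_e}{X_0 - M_e},$$

so $\mathrm{MR}(0) = 1$ and, for a drying series, $\mathrm{MR}$ falls
toward the equilibrium value. `moisture_ratio()` defaults the
equilibrium moisture $M_e$ to zero: thin leaves dried on a hot film
approach bone-dry, no sorption isotherm is modeled, and the value is
configurable per run for materials where that assumption fails.

Six standard thin-layer models are fitted to $\mathrm{MR}(t)$ by
nonlinear least squares:

| model | formula |
|---|---|
| Newton | $\exp(-kt)$ |
| Page | $\exp(-kt^n)$ |
| Henderson–Pabis | $a\exp(-kt)$ |
| Logarithmic | $a\exp(-kt) + c$ |
| Wang–Singh | $1 + at + bt^2$ |
| Two-term | $a\exp(-kt) + c\exp(-k_0 t)$ |

`fit_thin_layer_model()` minimizes the residual sum of squares with the
Levenberg–Marquardt implementation in minpack.lm under box bounds
($k, k_0 \in (0, 10]$ min$^{-n}$, $n \in (0, 5]$, $a, b, c \in [-5, 5]$),
from a multi-start protocol: the first start comes from a
log-linearization of the Newton model (slope of $\ln \mathrm{MR}$
against $t$ over the positive values; non-positive values are excluded
from the initialization but retained in the SSE), and four further
seeded log-normal jitters of that start guard against local minima.
The SSE-change tolerance is $10^{-10}$. A fit that does not converge is
returned with `converged = FALSE`, never silently replaced. Model
quality is reported as $\mathrm{MSE} = \frac1N\sum(\widehat{\mathrm{MR}}
- \mathrm{MR})^2$ and the standard coefficient of determination
$r^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$; `rank_models()` orders
fits by descending $r^2$, breaking ties by ascending MSE and then by
parsimony, with non-converged fits last.

## Diffusivity and the Arrhenius/transition-state chain

For long drying times the first term of the Fick slab solution gives

$$\ln \mathrm{MR} = \ln\frac{8}{\pi^2} - \frac{\pi^2 D_\mathrm{eff}}{4L^2}\,t,$$

so `deff_from_series()` regresses $\ln \mathrm{MR}$ on time **in
seconds** with a free intercept (the theory predicts $\ln(8/\pi^2)$,
not 0) and converts the slope magnitude $K_1$ to
$D_\mathrm{eff} = 4L^2K_1/\pi^2$. Two settings matter:

* `half_thickness_m` — the slab half-thickness $L$; default
  $1.5\times10^{-4}$ m (a 0.3 mm leaf). Absolute diffusivities scale
  with $L^2$, so this must be set from caliper measurements when
  absolute values matter; the activation energy is independent of $L$,
  which only shifts the Arrhenius intercept.
* `mr_floor` — smallest MR admitted to the regression, default 0.05:
  near zero the logarithm amplifies measurement noise.

`arrhenius_fit()` regresses $\ln D_\mathrm{eff}$ on $1/(T + 273.15)$;
the activation energy is $E_a = -\mathrm{slope}\cdot R$ with
$R = 8.314$ J mol$^{-1}$K$^{-1}$ and the pre-exponential factor
$D_0 = e^{\mathrm{intercept}}$, i.e. the negative-exponent convention
$D_\mathrm{eff} = D_0\exp(-E_a/RT)$.

Transition-state quantities follow at each observed temperature (no
interpolation):

$$\Delta H = E_a - RT,\qquad
\Delta S = R\left[\ln D_0 - \ln\frac{k_B}{h} - \ln T\right],\qquad
\Delta G = \Delta H - T\Delta S,$$

with $k_B/h$ the Boltzmann-over-Planck frequency factor. The
$\Delta G$ column of `thermo_table()` satisfies the third identity to
machine precision by construction. A caveat worth stating plainly: the
entropy expression is the standard transition-state form, but published
per-temperature entropy values for this kind of experiment are
generally **not** recoverable from a printed Arrhenius fit alone (they
depend on the unpublished per-replicate regressions), so the package's
checks of $\Delta S$ rest on the $\Delta G$ identity rather than on
absolute recomputation.

## Energy and emissions

Specific energy consumption is metered energy over water removed,
$\mathrm{SEC} = E/m_w$ (kWh per kg water), with the water mass from the
wet-basis balance $m_w = m_0(M_0 - M_f)/(100 - M_f)$. Primary-energy
("real") consumption divides by a plant/transmission efficiency,
default 0.871, and emission intensities follow

$$\mathrm{intensity} = \frac{\mathrm{SEC}}{\eta}\times EF \times
\left(1 - \frac{ER}{100}\right),$$

with default emission factors 622 g/kWh (CO₂) and 3.78 g/kWh (NOₓ) for
a fossil-fuel combined-cycle plant, and an emission-reduction
percentage $ER$ defaulting to 0. Percent changes are reported as
$100(\mathrm{ref} - \mathrm{new})/\mathrm{ref}$ so that decreases are
positive numbers.

## Color and quality metrics

Color change is the Euclidean CIELAB distance
$\Delta E = \sqrt{\Delta L^2 + \Delta a^2 + \Delta b^2}$ against the
fresh reference, and chroma is $\sqrt{a^2 + b^2}$ (no CIEDE2000, no hue
angle). The pipeline computes both per replicate and then averages;
summary-level recomputation from group means is also available and is
what the fixture checks use for chroma. Rehydration ratio is
rehydrated over dried mass per soak time; DPPH antioxidant activity is
$100(1 - A_\mathrm{sample}/A_\mathrm{control})$, with values outside
$[0, 100]$ reported as-is with a warning rather than clipped.

## The Levenberg–Marquardt network

The moisture-ratio predictor is a feedforward perceptron written from
scratch in the package: two inputs (water temperature, drying time),
one or two hidden layers of 2–15 neurons, one output, with `tansig`
(hyperbolic tangent), `logsig` (logistic) and `purelin` (identity)
activations. Inputs are standardized to $[-1, 1]$ per feature and the
scaling is stored with the model.

Training is damped Gauss–Newton on the residual vector: each epoch
builds the analytic backpropagated Jacobian $J$ and solves
$(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta = -J^\top r$,
escalating $\lambda$ (×10) until the training MSE decreases and
relaxing it (÷10) after an accepted step — so the accepted-step
training MSE is non-increasing by construction. $\lambda$ starts at
$10^{-3}$. Stopping criteria: the epoch cap (default 1200), a gradient
infinity-norm below $10^{-10}$, a relative SSE improvement below
$10^{-12}$, no acceptable step after 30 escalations, or a validation
MSE that has not improved for `patience` epochs (default 6 — observed
epoch counts are far below the cap, which is the signature of
validation-based early stopping). The weights at the best validation
MSE are returned and test metrics are reported on those weights.

The data split is 70/15/15 (train/validation/test), drawn at random
under the configured seed and stratified by temperature so every
partition covers all water temperatures; the split is redrawn per
training seed, and `topology_search()` derives one seed per candidate
so the grid is reproducible end to end. Candidates are ranked by test
MSE. Because the network's exact test error depends on the private
measurement noise of any particular dryer, the package's own checks of
the trainer are structural: the Jacobian agrees with finite
differences, a purelin-only network reaches the ordinary-least-squares
optimum of the same design matrix, and the flagship 2-15-14-1
(tansig–logsig–purelin) topology explains a noiseless Page surface
with test $R^2 \ge 0.999$.

## The synthetic-data generator

`generate_experiment()` emulates the study conditions the analysis
assumes: five water temperatures (50–90 °C), three replicates per
temperature, 5-minute sampling, 80% wet-basis initial moisture, and
Page-type curves $\mathrm{MR} = \exp(-k(T)\,t^n)$ whose rate constant
follows an Arrhenius law. Defaults: $n = 1.1$ and
$k_\mathrm{ref} = 0.01513$ min$^{-n}$ at 50 °C, chosen so the noiseless
drying time (first sample at $\mathrm{MR} \le 0.02$) is about 156 min
at 50 °C; $E_{a,\mathrm{sim}} = 25750$ J/mol, which brings the 90 °C
run down to about 60 min — the observed range for RW drying of mint
leaves. Replicate noise is additive Gaussian on MR (SD 0.01, clipped
to $[0, 1]$), the simplest mechanism consistent with reported ±SD
summaries; the energy meter is a constant mean draw (0.87 kW for a
500 g load, which yields SEC falling from ≈5.7 to ≈2.9 kWh/kg across
the temperature range) with seeded per-interval jitter; quality and
color panels are Gaussian draws from per-temperature means ± SD taken
from the shipped reference summaries; rehydration curves are monotone
three-phase saturating curves reaching the per-temperature plateau by
180 min. Sub-seeds derive deterministically from (master seed,
temperature index, replicate index), so adding replicates never
perturbs existing runs, and a hard cap of 10,000 samples per run turns
an unreachable `mr_stop` into an explicit error.

What the generator does **not** emulate: heat- and mass-transfer
physics of the film and water bath (curves are phenomenological),
shrinkage and case-hardening (which bend $\ln \mathrm{MR}$ away from
linearity at long times), correlated or heteroscedastic measurement
error, and assay chemistry. Passing tests on synthetic data therefore
demonstrate that the estimators recover the parameters of the assumed
data-generating process — exact Page-parameter and $E_a$ recovery in
the noiseless limit, nested-model SSE dominance, monotone SEC — not
that real leaves obey a Page curve.

## Problem sizes and reproducibility

The shipped test-suite and examples run the chain at the scale of the
emulated experiment itself (5 temperatures × up to 3 replicates,
~20–35 samples per run, networks up to 2-15-14-1 with ≈284
parameters), which keeps a full run in seconds while exercising every
code path; nothing in the methods depends on that scale. All
randomness flows from explicit integer seeds through deterministic
sub-seed derivation, so `run_pipeline()` with a fixed seed is
byte-identical across runs, including its CSV outputs (written with
6 significant digits; the JSON report keeps full precision).

## Known limitations

* Only the first-term slab solution is used; at short times or high
  Biot numbers the multi-term series would differ.
* $D_\mathrm{eff}$ is moisture-independent within a run.
* Entropy absolute values inherit any inconsistency in the upstream
  Arrhenius intercept; rely on the $\Delta G$ identity for checking.
* The emission model is a single emission-factor multiplication — no
  life-cycle assessment.
* The network is a regression surface over the observed temperature and
  time ranges; extrapolation beyond them is unconstrained.
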