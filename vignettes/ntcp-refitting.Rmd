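---
title: "Refitting NTCP model parameters across dose-calculation algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refitting NTCP model parameters across dose-calculation algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcprefit)
```

## The problem

Normal tissue complication probability (NTCP) models map a lung dose-volume
histogram (DVH) to a probability of radiation pneumonitis. Their parameters
are fitted to clinical outcome data using the dose distributions a particular
treatment planning system computed — historically, correction-based pencil
beam (PB) algorithms. Pencil beam algorithms systematically overestimate dose
inside thoracic fields and underestimate it outside (they miss the widened
penumbra in low-density lung), so a clinic using a modern model-based engine
(collapsed cone, AAA) that evaluates published PB-era parameters on its own
DVHs inherits a systematic NTCP error — a change of up to several percentage
points for the same plan, comparable to the confidence interval of the NTCP
estimate itself.

The remedy implemented here is parameter *refitting*: find new model
parameters such that NTCP evaluated on the new algorithm's DVHs reproduces
the NTCP evaluated on the reference algorithm's DVHs with the original
parameters, plan by plan, over a representative cohort. No new outcome data
are needed; the refit transfers an existing dose-response model between dose
engines.

## Models

Two standard NTCP models are provided.

**Lyman-Kutcher-Burman (LKB).** The DVH is reduced to a generalized
equivalent uniform dose,

$$\mathrm{EUD} = \Big(\sum_i v_i D_i^{1/n}\Big)^{n},$$

over differential bins $(D_i, v_i)$, and the response is probit:
$\mathrm{NTCP} = \Phi(t)$ with $t = (\mathrm{EUD} - D_{50})/(m\,D_{50})$.
$\Phi$ is evaluated through the complementary error function
(`stats::pnorm`), never by numerical integration. Parameters:
$D_{50}$ (Gy), slope $m$, volume exponent $n$ ($n = 1$: mean-dose organ).

**Relative seriality (RS).** The uniform-dose response is Poisson-type,

$$P(D) = 2^{-\exp\left(e\gamma\,(1 - D/D_{50})\right)},$$

and subvolume responses combine through the seriality parameter $s$:

$$\mathrm{NTCP} = \Big[1 - \prod_i \big(1 - P(D_i)^s\big)^{v_i}\Big]^{1/s}.$$

The slope multiplier is read as the product $e\cdot\gamma$ (the Källman
convention). Because the printed form of this response is ambiguous in parts
of the literature, the multiplier is controlled by a `convention` flag
(`"kallman"`, default, vs `"expgamma"` for $e^{\gamma}$) which is carried
into all pipeline provenance output. The RS EUD — the uniform dose
reproducing a given NTCP — is the exact analytic inverse
$D = D_{50}\,(1 - \ln(-\ln p/\ln 2)/(e\gamma))$, verified in the test suite
by the roundtrip property rather than trusted from any printed formula.

**Numerical choices.** `ntcp_rs()` accumulates the product in log space with
a stable $\log(1-e^{x})$, because parallel-organ seriality values
($s \approx 0.01$–$0.1$) drive $P^s$ to 1 and the naive product underflows;
agreement with a naive scalar loop is still 1e-10 relative over random DVHs
of moderate dose, which the suite checks. DVH conversion attributes the
volume of each cumulative step to its lower-edge dose (a convention; the
alternative upper-edge/midpoint choices shift discrete mean doses by up to
half a bin). Cumulative monotonicity violations up to 1e-6 — typical export
rounding — are clipped with a warning; larger ones are errors.

All DVHs are corrected to EQD2 before modelling using the linear-quadratic
model with per-bin dose per fraction $d_i = D_i/n_\text{fractions}$,
$\alpha/\beta = 3$ Gy for lung and a 2 Gy reference fraction:
$\mathrm{EQD2} = D\,(d + \alpha/\beta)/(2 + \alpha/\beta)$. Reading the
published "dose per fraction = 2 Gy" as the *reference* fraction size (not a
claim that every bin received 2 Gy fractions) is a design choice; the number
of fractions is therefore a required input of `fractionation_scheme()`.

## The refit

`refit_parameters()` minimizes

$$\sum_{\text{plans}} \big[\mathrm{NTCP}_\text{new}(\text{target DVH};
D_{50}, \text{slope}, n/s\ \text{fixed}) -
\mathrm{NTCP}_\text{orig}(\text{reference DVH})\big]^2 .$$

Design choices, each genuinely open:

* **Objective in NTCP space** (not EUD space, not probit-transformed):
  curves are compared in NTCP-vs-EUD coordinates downstream, and NTCP-space
  residuals weight the clinically relevant part of the response. The
  objective is exposed as `refit_residual()` so alternatives can be probed.
* **Two free parameters.** Only $(D_{50}, m)$ / $(D_{50}, \gamma)$ move; the
  tissue-architecture parameter $n$/$s$ is copied structurally and is never
  free, mirroring how published algorithm-transfer tables hold it fixed.
* **Optimizer.** Derivative-free Nelder-Mead on the log of the parameters
  (enforcing positivity, scale-free), started at the original values plus
  five fixed multiplicative jitters, then polished by restarting the simplex
  at the incumbent. Restart factors are deterministic, making refits exactly
  reproducible and invariant to plan order. Objective tolerance 1e-12.
  Because the originals are one of the candidate starts, the fitted residual
  can never exceed the original-parameter residual.

The strongest correctness oracle is exact scaling: if every target DVH is
the reference DVH with doses multiplied by $k$, both models' NTCP depend on
dose only through $D/D_{50}$-type ratios, so the refit must return
$(k\,D_{50}, \text{unchanged slope})$ exactly. The suite checks recovery to
1e-3 relative (observed: ~1e-12).

**Standard errors.** The published transfer tables quote purely mathematical
refitting uncertainties without stating the estimator, so both reasonable
readings are provided: a plan-level bootstrap (resample plans with
replacement, refit, SD across `n_boot = 200` resamples — a 68%-level, one-SE
measure) and asymptotic curvature errors
$\sigma^2 (J^{\mathsf T}J)^{-1}$ from the numerical Jacobian of per-plan
residuals with $\sigma^2 = \mathrm{RSS}/(N-2)$. On well-behaved synthetic
cohorts the two agree within a factor of two, which the suite asserts.
Bootstrap seeds are explicit arguments and recorded in the output.

## Confidence bands

`ntcp_confidence_band()` propagates published 1D confidence intervals for
$D_{50}$ and the slope into an NTCP-vs-EUD envelope by exhaustive search
over a rectangular grid (default 101 points per axis) — for each EUD, the
minimum and maximum uniform-dose NTCP over the rectangle. The band always
contains the center curve, and widening either interval can only widen it.
For LKB the extremes provably sit on the rectangle boundary (the response is
monotone in $D_{50}$, and in $m$ at fixed sign of $\mathrm{EUD}-D_{50}$);
the tests confirm corner-search agreement, and the full grid is kept as the
defensive default since the RS case is less transparent. The rectangle
ignores parameter correlation, so relative to a joint likelihood region the
band can be slightly too narrow or too wide; that caveat travels in the
band object's `note` field. Confidence levels differ between source studies
and are required inputs on `parameter_interval()`, never defaults. For
heterogeneous irradiation under RS the uncertainty at a given EUD is not
unique — two DVHs with equal EUD can have different band widths — so
`band_for_dvh_series()` evaluates the rectangle on actual DVHs instead.

## The synthetic cohort generator

No plan-level DVHs are published for this kind of study, so the generator
emulates their *statistical structure*; synthetic cohorts are structurally,
not numerically, faithful, and nothing here reproduces any specific
patient's DVH.

Each plan is a latent three-component mixture, matching the in-field /
penumbra / low-dose-bath physics of 3D-conformal thoracic plans:

* in-field lung: Normal(in-field dose, penumbra width), truncated at 0;
* penumbra: Uniform(0, in-field dose);
* bath: Exponential(bath decay), truncated at the prescription dose;

discretized to 0.5 Gy bins and normalized exactly. Default templates:
tangential breast (Tang) with a small in-field fraction (0.10), locoregional
breast (LGL) intermediate (0.18) with a larger bath, lung (Lung) with the
largest and most variable in-field fraction (0.25, 25% relative jitter vs
10% for Tang) — lung plans are individually optimized and vary in both dose
level and shape, which the dispersion test verifies. Prescriptions are
50 Gy/25 fx (breast) and 60 Gy/30 fx (lung), conventional fractionation for
these techniques.

An algorithm change transforms the *same* latent plan (monitor units are
shared between recalculations, so paired DVHs must be coupled, not drawn
independently): the in-field dose is scaled down, a fraction of in-field
volume moves into the penumbra, and the bath's dose scale is multiplied up —
the better engine computes more dose outside the field, so low-dose volume
grows while high-dose volume and mean lung dose (MLD) shrink. Scaling the
bath *dose* rather than its volume fraction is what makes the low-dose
volume (V5) increase together with a falling MLD, the directional signature
of a pencil-beam-to-model-based change. Shipped presets were calibrated once
with `calibrate_effect()` (200-plan Monte Carlo) so cohort mean relative MLD
reductions land at the magnitudes reported for real algorithm changes —
near 10/9/8% (Tang/LGL/Lung) for the `"PB-CC"` presets and 4/4/5% for
`"PBC-AAA"` — and were then frozen. The per-plan spread of the reduction is
somewhat smaller than clinical experience suggests, because the effect
transform is deterministic given the latent plan; cohort-level means, which
drive the refits, are the calibrated quantity.

What passing tests on these cohorts show: the refitting machinery is
correct (identity, scaling, dominance, order-invariance oracles hold on any
paired cohort). What they do not show: that refitted parameter *values*
match any clinical table — those depend on the clinic's actual plans, which
is precisely why the method exists.

## Problem sizes and runtime

Cohorts of 10 plans per treatment type mirror the emulated study design;
calibration checks use 200 plans; bootstrap SEs default to 200 resamples
(tests use 30–60). The full default study — six cohorts, 28 refits with
curvature SEs — runs in a few seconds on one core.

## Limitations

* The refit transfers a model between dose engines; it cannot make the
  original parameters more clinically accurate, and refitted parameters are
  treatment-type specific (pooling types requires an explicit flag because
  the transfer genuinely differs between beam geometries).
* Rectangular confidence bands ignore $D_{50}$-slope correlation.
* Absolute-volume DVHs, DICOM I/O and structure arithmetic (e.g. GTV
  subtraction) are upstream concerns and out of scope.
* The RS slope convention is a documented flag, not a resolved question.
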