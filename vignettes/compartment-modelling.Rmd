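---
title: "Compartment modelling of brain DCE-MRI concentration curves"
author: "dcekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment modelling of brain DCE-MRI concentration curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekin)
```

## The models

`dcekin` models dynamic contrast-enhanced MRI (DCE-MRI) concentration-time
curves acquired under a *slow continuous infusion* of an extracellular
gadolinium agent, in three brain pools. All times are in minutes, all
concentrations in mM, all rates in mM/min (inputs) or 1/min (transfers).

**Blood pool.** Spins affected by the agent enter the circulating pool at a
constant concentration rate $C_{IN}$ and are eliminated at rate $k_{OUT}$,
giving the arterial input function

$$\mathrm{AIF}(t) = C_{IN}\, t\, e^{-k_{OUT} t},$$

valid before and during the infusion. The whole-blood concentration is the
plasma-borne signal scaled by the hematocrit,
$C_{BLOOD}(t) = (1 - \mathrm{Hct})\,\mathrm{AIF}(t)$. After an optional
infusion end `t_end` only elimination acts; the curve is continued as a
mono-exponential decay at $k_{OUT}$, continuous at `t_end`. The closed-form
tissue solutions below are derived for the infusion-phase expression;
`solve_numeric()` integrates the extended forcing if a finite `t_end` is
supplied.

**Tissue voxel.** A white/gray-matter voxel holds four compartments — blood,
extracellular extravascular space (EES), intracellular extravascular space
(IES), and a space not accessible to water protons (NOW) — with fractional
volumes closing to one:
$v_{BLOOD} + v_{EES} + v_{IES} + v_{NOW} = 1$. Exchange across the
blood–EES barrier follows the Kety–Schmidt rate law

$$\frac{dC_{EES}}{dt} + k_{EP} C_{EES} = k_{TRANS} C_{BLOOD}(t),
  \qquad C_{EES}(0) = 0,$$

and across the EES–IES barrier

$$\frac{dC_{IES}}{dt} + k_{IP} C_{IES} = k_{PI} C_{EES}(t),
  \qquad C_{IES}(0) = 0.$$

The voxel signal-producing concentration is the volume-weighted mixture
$C_{TISSUE} = v_{BLOOD} C_{BLOOD} + v_{EES} C_{EES} + v_{IES} C_{IES}$;
the NOW compartment contributes nothing. An intact blood–brain barrier
means $k_{TRANS} = 0$: the voxel then enhances through its blood
compartment only.

**CSF voxel.** A CSF voxel holds two compartments, blood and CSF
($v_{BLOOD} + v_{CSF} = 1$). Considering blood filtration as the formation
mechanism, spins enter the CSF space at an overall rate $k_{IN}'$ and leave
at $k_{OUT}'$, giving a CSF input function of the same form as the AIF,
$\mathrm{CSFIF}(t) = k_{IN}'\, t\, e^{-k_{OUT}' t}$. No hematocrit factor is
applied to the CSF term. The voxel mixture
$v_{BLOOD} C_{BLOOD} + v_{CSF}\,\mathrm{CSFIF}$ mirrors the tissue mixing
rule; the two-compartment mixture itself is a modelling assumption of this
package (the compartmentalization fixes the compartments; the mixture
weights follow the tissue rule).

**IOF.** For a cohort spanning disease stages (e.g. control/mild/severe
communicating hydrocephalus), per-stage mean CSF rates are normalized by
the same-region control means and compared as the output-to-input flow
statistic

$$\mathrm{IOF} =
  \frac{\bar k_{IN}'\big|_{\mathrm{norm}}}{\bar k_{OUT}'\big|_{\mathrm{norm}}}.$$

IOF of the control stage is 1 by construction. IOF > 1 flags a predominant
input-mechanism disturbance, IOF < 1 a predominant output disturbance;
whenever IOF < 1 the reciprocal is also reported. A configurable tolerance
band (default half-width 1e-9) around 1 is labelled "balanced"; `tol = 0`
recovers the strict binary rule. Means are unweighted arithmetic means over
subjects; per-subject fits, not pooled curves, are the default pipeline.

## Closed forms and numerical evaluation

With $A = (1-\mathrm{Hct})C_{IN}$ and $c = k_{EP} - k_{OUT}$, the EES
solution is

$$C_{EES}(t) = k_{TRANS} A\, e^{-k_{EP} t}
  \left[\frac{t e^{ct}}{c} - \frac{e^{ct}-1}{c^2}\right]
  \;\xrightarrow{c \to 0}\;
  k_{TRANS} A\, e^{-k_{OUT} t}\, \frac{t^2}{2}.$$

Evaluated literally, the bracket loses $\sim \varepsilon/(ct)^2$ relative
digits near the degeneracy, which would break the package's own 1e-8
oracle-agreement guarantee around $|k_{EP}-k_{OUT}| \approx 10^{-6}$.
`ees_concentration()` therefore factors the solution as
$k_{TRANS} A\, e^{-k_{EP}t}\, t^2\, h(ct)$ with
$h(z) = (z e^z - (e^z - 1))/z^2$, computed by its power series for
$|z| < 0.5$ (18 terms reach machine precision there) and by `expm1`
arithmetic otherwise, in a rearrangement that never multiplies
$e^{-k_{EP}t}$ by $e^{+ct}$ (overflow-safe for fast $k_{EP}$). The value is
smooth through $c = 0$; $h(0) = 1/2$ reproduces the degenerate limit
exactly.

The IES solution is a sum of four exponential modes with rates
$k_{OUT}$ (double), $k_{EP}$, $k_{IP}$. Its partial-fraction coefficients
become ill-conditioned when any two of the three rates coincide;
`ies_concentration(method = "auto")` therefore uses the closed form only
when every pairwise gap $g$ satisfies $g \cdot \max(t, 1) > 0.02$ and falls
back to adaptive ODE integration otherwise. `solve_numeric()` (deSolve's
lsoda, relative tolerance 1e-10, absolute 1e-16, explicit failure on
solver error) is the independent oracle used throughout the test suite to
validate both closed forms; the suite checks agreement to better than 1e-8
in relative sup-norm, including forced near-degenerate draws.

## Fitting

Estimation is two-stage, mirroring the pool-by-pool structure of the
models: blood-pool parameters are fitted first from a blood-ROI curve with
the hematocrit supplied, then tissue or CSF parameters conditional on them
(`fit_tissue()` and `fit_csf()` never modify the supplied blood
parameters). All fits use bounded Levenberg–Marquardt least squares
(minpack.lm) from five deterministic starting points spread over the
physiologically reported ranges (plus a data-driven start from the curve
peak where the model's peak has a closed form), keeping the lowest-RSS
solution. Convergence: relative RSS change below 1e-12 or parameter step
below 1e-10, at most 500 iterations. Volume closure is structural, not
penalized: the optimizer works on stick-breaking coordinates
($v_{BLOOD} = (1 - v_{EES})u_1$,
$v_{IES} = (1 - v_{EES} - v_{BLOOD})u_2$, $u_i \in [0,1]$), so returned
volumes always sum to one exactly with $v_{NOW} \ge 0$. Rate estimates
below 1e-6 1/min are reported as exactly 0; a zero $k_{TRANS}$ sets the
"blood-only enhancement" flag (intact blood–brain barrier). `v_ees` is
fixed at 20% by default — it can be freed, but it then multiplies
$C_{EES}$ jointly with $k_{TRANS}$ and is only weakly identifiable.

Two structural identifiability facts shape the interface:

* **Tissue ridge.** The IES rate law is linear in $k_{PI}$ and the mixture
  is linear in $v_{IES}$, so the data determine only the product
  $v_{IES} k_{PI}$; the likelihood has an exactly flat ridge along
  $(v_{IES}, k_{PI}) \mapsto (cv_{IES}, k_{PI}/c)$. `fit_tissue()` reports
  both coordinates (some point on the ridge), attaches the identifiable
  product as `v_ies_k_pi`, and notes the ridge in the result. Recovery
  guarantees apply to $k_{TRANS}$, $k_{EP}$, $k_{IP}$, $v_{BLOOD}$ and
  the product.
* **CSF valley.** When a subject's $k_{OUT}'$ approaches their blood
  $k_{OUT}$, CSFIF and $C_{BLOOD}$ become proportional and
  $(v_{BLOOD}, k_{IN}')$ collapse toward one identifiable combination; the
  least-squares optimum then wanders along a flat valley, producing
  heavy-tailed $k_{IN}'$ estimates (verified by refitting from the truth:
  the walk is a property of the objective, not of the optimizer).
  `fit_csf()` therefore caps $v_{BLOOD}$ at 0.3 by default: reported CSF
  voxel blood fractions (partial-volume contamination of small CSF
  spaces) stay well below that, so the cap removes only non-physiological
  valley excursions. Set `v_blood_max = 1` for the unconstrained fit.

## The synthetic generator

`generate_cohort()` draws per-subject parameters from per-(stage, region)
normal distributions truncated at 0 (fractions capped at 1) and emits a
blood-ROI curve and one CSF-voxel curve per region with additive i.i.d.
Gaussian noise on concentration. Defaults encode the reported slow-infusion
ranges: blood $C_{IN} \sim N(0.06, 0.008)$ mM/min (reported range
0.0427–0.0956), blood $k_{OUT} \sim N(0.031, 0.0025)$ 1/min (range
0.0281–0.0344), CSF $v_{BLOOD} \sim N(0.12, 0.02)$ (range 9.4–16.5%),
$k_{IN}' \sim N(0.06, 0.008)$ mM/min, noise sd 0.005 mM, sampling 0–60 min
every minute, hematocrit 0.45. The CSF evacuation rate is centred at
$k_{OUT}' \sim N(0.045, 0.004)$ 1/min, deliberately away from the blood
elimination rate: the two describe different physical processes (bulk CSF
outflow versus renal elimination of the tracer), and coincident means
would make the simulation design rank-deficient — the blood and CSF input
shapes become proportional and the generated cohorts could not identify
$(v_{BLOOD}, k_{IN}')$ even in principle. Disease effects are encoded by
scaling one stage's distribution (`scale_stage()`), e.g. doubling the mild
stage's $k_{IN}'$.

What the generator does *not* emulate: Rician noise on raw MR signal (the
package operates post signal-to-concentration conversion, which is out of
scope, so noise is Gaussian on concentration), AIF dispersion/delay
between artery and voxel, motion or scanner drift, and anatomically
realistic geometry (phantoms are class-labelled boxes). Passing recovery
tests therefore demonstrate correctness of the estimation machinery under
the model's own assumptions, not robustness to real-data artefacts.

`generate_phantom()` assembles small 4D images from voxel-class layouts
(background/blood/tissue/CSF) with per-class parameters and truth maps,
exportable as NIfTI-1 via `write_phantom()` with the time step in the
temporal pixdim.

## Numerical and design choices

* Time is fixed to minutes and concentration to mM throughout; fits
  evaluate the model at the data's own time points, with no interpolation.
* The hematocrit scales the blood compartment everywhere $C_{BLOOD}$
  appears — in tissue and CSF voxel mixtures alike — because a single
  blood concentration feeds all pools. No (1−Hct)-like factor is applied
  to CSFIF, which is taken literally.
* The ODE oracle is also the production path for the IES model near rate
  coincidences, avoiding four-way branch proliferation in the closed form.
* Truncated-normal draws use inverse-CDF sampling, so cohorts are
  bit-reproducible under a seed, and the caller's RNG stream is restored
  afterwards.
* Degenerate inputs fail loudly: identically-zero curves, missing control
  stages, zero control means, unknown YAML keys (a typo in a rate name
  must not silently corrupt an analysis), and non-converging ODE
  integrations all raise errors.

## Problem sizes in the test suite

The suite validates each guarantee at sizes a desk machine handles in a
few minutes: 200 random parameter draws for the closed-form/ODE
equivalence (50 forced near-degenerate), 100-replicate Monte-Carlo
recovery experiments at noise 0.002–0.005 mM on 61-point curves, a
100-curve table for the volume-closure property, and an end-to-end cohort
of 200 subjects per stage (600 blood + 600 CSF fits) for the IOF pipeline
check against a doubled mild-stage input rate.

## Known limitations

* The $(v_{IES}, k_{PI})$ ridge means individual values of those two
  parameters should not be interpreted — only their product is data-driven.
* With noise of 0.002 mM on 61-point curves, the $k_{TRANS}$-driven signal
  ($v_{EES} C_{EES}$, peaking near 6e-4 mM for
  $k_{TRANS} = 5\times10^{-4}$ 1/min) lies below the noise floor; the
  Fisher information then bounds any unbiased estimator's standard
  deviation at roughly 2e-3 1/min on that grid (about 7e-4 even at 15-s
  sampling over two hours), so single-curve $k_{TRANS}$ estimates at that
  noise level carry errors of the same order as the rate itself.
  Detecting transfer rates at the 1e-4 1/min scale requires lower noise,
  averaging over many voxels, or both.
* Only the filtration mechanism of CSF formation is modelled; the CSF
  voxel has exactly two compartments.
* No statistical inference on IOF differences is provided — the statistic
  is descriptive; uncertainty quantification is limited to RSS and bound
  diagnostics.
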