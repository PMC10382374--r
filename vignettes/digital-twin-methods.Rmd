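---
title: "Methods: an individualized digital twin for transdermal fentanyl therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an individualized digital twin for transdermal fentanyl therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fentatwin simulates transdermal fentanyl therapy for a virtual population of
cancer patients. Each patient gets an individualized *digital twin*: a
physics-based model chain from the drug reservoir in the patch, through the
skin, into a physiologically based pharmacokinetic (PBPK) model, and onward
to two clinical endpoints — pain intensity on the visual analog scale (VAS,
0–10) and minute ventilation (L/min), fentanyl's main adverse effect. On top
of the twin sits a closed-loop patch-replacement controller that is compared
against the conventional fixed 72-h replacement schedule.

This vignette documents the model equations, the assumptions behind them,
the tunable parameters, the numerical scheme, and the design decisions taken
where the source material left the design open.

## Drug uptake through the skin

Transport in the patch and the three skin layers (stratum corneum, viable
epidermis, and an *equivalent* dermis whose reduced thickness stands in for
capillary uptake) follows Fick's second law,
$$\partial c_i/\partial t = \nabla\cdot(D_i \nabla c_i),$$
with partition equilibrium $c_i = K_{i/j}\, c_j$ at each layer interface. To
avoid the concentration discontinuities this induces, the solver works in
the *drug potential* $\psi_i = c_i / K_i$, which is continuous everywhere;
the layer capacities $K_i$ are fixed by the printed partition coefficients
($K_{\mathrm{pt}/\mathrm{ep}} = 1/3.4$, $K_{\mathrm{ep}/\mathrm{dm}} = 1$)
with the patch normalized to $K = 1$ — only capacity *ratios* affect the
solution, because the initial load fixes the patch concentration.

Boundary conditions: no flux at the top of the patch and at the lateral
boundaries; at the bottom of the dermis the concentration equals the plasma
concentration (potential continuity $\psi_b = c_p / K_{\mathrm{dm}}$), which
couples the skin to the PBPK model in both directions. Since the lateral
boundaries are no-flux and all data are laterally uniform, the 2-D problem
is exactly 1-D, and the package solves it in 1-D.

A single epidermal diffusivity is applied to both the stratum corneum and
the viable epidermis (they remain separate layers for thickness
bookkeeping); the patch and dermis have their own diffusivities. With the
default constants the release is patch-diffusion-limited: the dermal flux
rises over several hours, peaks, and then declines as the patch face
depletes — which is what produces the peak-then-decline plasma profile and,
eventually, returning pain.

## Pharmacokinetics

Five compartments: central (blood + lungs), rapidly equilibrating (brain,
heart, skin, kidneys), slowly equilibrating (muscle, fat, carcass),
gastrointestinal (gut, spleen, pancreas) and hepatic. The dermal flux enters
the central compartment as $\mathrm{Flux}_d \times A / V_c$. Every
first-order rate constant is derived as $k = Q/V$, where $Q$ is the shared
inter-compartment flow and $V$ is the volume of the compartment whose
balance equation the term appears in; the same flow therefore yields
*different* rate constants in the donor and receiver equations, and the
implementation stores $(Q, V)$ and derives each coefficient per equation.
The unbound fraction $f_u = 0.20$ multiplies only the central-compartment
outflow and elimination terms, exactly as the model prints it. Elimination
is hepatic (clearance $Cl_h$, applied in the liver as
$k_{met} = Cl_h/V_l$) plus a first-order renal term on unbound central drug.

Two consequences of the printed structure deserve emphasis:

* **Renal sign.** The printed central balance carries the renal constant
  with a sign that makes renal clearance a *source*. Physically renal
  clearance removes drug, so the package implements it as elimination by
  default and provides `pk_reference$literal_renal_sign = TRUE` to reproduce
  the printed sign.
* **Mass asymmetry and stability.** Because $f_u$ scales only the central
  outflows while the peripheral uptake terms receive the full flow, every
  forward transfer leg creates drug mass at rate $(1-f_u)\,Q\,c_p$. With
  textbook perfusion-scale flows (L/min for the rapid/slow tissues) this
  positive feedback outruns any realistic elimination and the linear system
  has a positive eigenvalue — it is unstable. The published model's own
  flow constants are unpublished fitted values, so this package ships
  *effective* inter-compartment clearances: small rapid/slow distribution
  clearances, a large gut→liver chain carrying most of the elimination, and
  a hepatic clearance large enough to suppress the liver-return
  amplification. They were fixed once by two documented rules: (i) the
  composed system must be stable at $f_u = 0.2$ (all eigenvalues negative;
  asserted in the test suite), and (ii) the conventional-therapy plasma
  peak of the reference 70-kg male patient must sit at the midpoint of the
  reported 1.3–3.2 ng/ml population range. Everything physiological
  (compartment volumes, their weight scaling, $f_u$) keeps its standard
  value. The acceptance quantities (population statistics, EC50 mean, PD
  identities) are independent of this block by construction.

## Pharmacodynamics

Each endpoint has an effect compartment with first-order lag
$\partial c_e/\partial t = k_e (c_p - c_e)$ ($k_e = 2\times10^{-3}$/s for
pain, $7\times10^{-4}$/s for ventilation) and a sigmoid Emax response on the
decreasing branch,
$$E = E^0 - E^{max}\frac{c_e^{\gamma}}{EC_{50}^{\gamma} + c_e^{\gamma}}.$$
Pain: $E^0 = E^{max} = 8$, $\gamma = 2.71$, and a patient-specific
$EC_{50} = (-1.148\times10^{-2}\,\mathrm{Age} + 1.96)\,e^{\theta}$ ng/ml.
Ventilation: $E^0 = 20$ L/min, $E^{max} = 20\times0.91$,
$EC_{50} = 1.14$ ng/ml, $\gamma = 2.69$. At zero effect-site concentration
the endpoints are exactly at baseline; at $c_e = EC_{50}$ exactly halfway to
the maximum effect — both are acceptance identities.

## From covariates to a twin

Skin-layer thicknesses, compartment volumes, flows, clearance and the pain
EC50 are computed from age, gender (male = 1, female = 0), weight and
height by the published covariate equations, each multiplied by an
independent lognormal factor $e^{\theta}$, $\theta \sim N(0, 0.1)$, so that
95% of every parameter lies within roughly ±20% of its central value. One
$\theta$ is drawn per parameter (the equations attach the variability per
equation, not per patient), and all draws are recorded in the twin for
reproducibility.

Three constants in the thickness equations required decisions:

* The stratum-corneum expression is evaluated literally as printed,
  `(0.125·Age + 11.80·(Gender + (1−Gender)·1.40))·exp(θ)` µm. Its
  population mean (≈21 µm) exceeds the printed 18.0 µm population mean;
  rather than silently altering a printed formula, the package exposes the
  discrepancy and offers an optional global `sc_calibration_factor`
  (default off).
* The viable-epidermis base value and the dermis age-scaling ratio are
  cited but not printed. Both are config constants fixed by a one-time
  calibration (`calibrate_skin_constants()`) so the *expected* population
  means over the reference 3000-patient population equal the printed
  29.7 µm and 242.6 µm. The calibration uses the analytic lognormal mean
  $e^{\sigma^2/2}$, so it is exactly idempotent. The dermis base expression
  evaluates to ≈1.8 for typical BMI, which reads naturally as millimetres
  of anatomical dermis; the calibrated ratio (≈0.134) then plays the
  printed role of the age scaling that shrinks it to the equivalent
  thickness. The BMI-linear equation is only trusted on BMI 15–45, and
  both the cohort generator and the population sampler keep patients inside
  that range.

## The virtual population

The real 20-patient cohort behind the study is unpublished; only its
marginals (ages 40–68, age 56.75 ± 9.82 y, weight 72.8 ± 14.8 kg, height
1.70 ± 0.12 m, 10 men/10 women) and three correlations (gender–height 0.87,
gender–weight 0.43, weight–height 0.38, gender coded 0/1) are printed.
`generate_sample_cohort()` therefore builds a synthetic stand-in whose
*empirical* moments match those targets essentially exactly: gender is fixed
at 10/10, weight and height are Gaussian-copula draws re-standardized
affinely against the standardized gender column (which makes the three
target correlations and all means/SDs exact), and age is drawn from a beta
shape on [40, 68] and re-standardized, with rejection until the range holds.
What this stand-in does *not* reproduce is the unobservable fine structure
of the real cohort — individual patients, age–weight dependence, tumour
sites, dosing history. Downstream results depend on the printed summaries
only, which is exactly what the stand-in preserves.

`gibbs_sample_population()` then draws the virtual population: gender ~
Bernoulli($p$) with a uniform prior on $p$; conditional on gender,
(age, weight, height) is multivariate normal with a
normal–inverse-Wishart prior centred on the per-gender sample moments with
prior strength 1 pseudo-observation (a config knob; the source does not
state it). The Gibbs chain alternates $\mu \mid \Sigma$ and
$\Sigma \mid \mu$ per gender; after 20 000 burn-in iterations, each of the
3 000 kept iterations emits one posterior-predictive patient, so the kept
count *is* the population size. Draws outside the covariate bounds (or the
BMI range) are rejected and redrawn. The two-component gender-conditional
model reproduces the gender–height gap that a single dichotomized Gaussian
would blur.

The published population table shows population SDs roughly half the sample
SDs (e.g. 4.9 vs 9.82 years), which posterior-predictive draws cannot
produce (they are always at least as wide as the likelihood). The mechanism
is not described; the sampler therefore exposes
`draw = "parameter_mean"`, which emits the current posterior mean instead
and produces that kind of shrinkage. Population *means*, which is what the
acceptance targets check, are unaffected by this choice.

## Therapy policies and the controller

Conventional therapy applies one patch at $t=0$ and replaces it every 72 h
(never, within the default 72-h horizon). Digital-twin-assisted therapy
checks the *simulated* VAS every 8 h (config: 2–72 h) and, when it is
strictly above the target of 3 at the checkpoint instant, removes the
current patch and applies a fresh, fully loaded patch of the same size at a
new location on virgin skin. "Strictly above 3" for the trigger and
"strictly below 3" for the pain-free time mean a value of exactly 3 neither
counts as pain-free nor triggers replacement. The first check one full
interval after application is the lockout against over-frequent
replacement. The source does not say whether a removed patch's skin depot
keeps releasing; `numerics$residual_depot` keeps the depot active by
default (the drug is physically in the skin), and both modes are tested.

## Numerics

The coupled state — all active sites' potential fields, five PK and two
effect compartments — is one sparse *linear, autonomous* system between
patch events. The package exploits that directly instead of running a
generic stiff integrator:

* **Space:** cell-centred finite volumes, 25 cells per layer (≈100 per
  site), geometrically graded (factor 1.15) towards both ends of every
  layer; interfaces always coincide with cell faces. Face conductances
  compose $D_iK_i$ harmonically over the adjoining half-cells, which
  enforces flux continuity and the partition jump simultaneously. A
  Richardson study on nested grids shows second-order convergence on
  smooth problems and a bottom-flux error below 0.1% at the default
  resolution; the 12.6 mg load is conserved (stack mass + cumulative
  outflux) to round-off.
* **Time:** Crank–Nicolson with a fixed 120 s step and a pre-factorized
  sparse operator, preceded by four backward-Euler half-steps after every
  event (Rannacher smoothing) to damp the non-smooth modes a freshly
  loaded patch introduces. The scheme is unconditionally stable, keeps the
  potential field non-negative in all tested configurations, and halving
  the step changes hourly plasma concentrations by well under 0.1%. Patch
  events are exact integration breakpoints; output is sampled hourly.
  An independent method-of-lines integration of the same semi-discrete
  system with a stiff adaptive solver (deSolve's lsoda, maximum step 6 h)
  agrees with the production stepper and serves as the oracle in the test
  suite.
* **Outcomes:** time without pain is measured on the hourly grid with
  linear interpolation at the VAS = 3 crossings (both total and longest
  contiguous run are reported); refining the output grid changes it by
  less than half an hour. Undefined statistics (correlations of constant
  outcomes, tests on an empty heavy-user subgroup) are reported as missing
  rather than invented. The toxicity threshold defaults to 2 ng/ml with
  the printed alternative 3 ng/ml available in config.

## Problem sizes

The package's own studies use the full population pipeline (20-patient
sample, burn-in 20 000, 3 000 kept members). The two-arm comparative study
in the test suite runs the first 200 members of that population through
both arms — a size chosen to make the directional population contrasts
(median and IQR of time without pain, pain mean/SD, pain-free fraction,
patch-count/weight correlation, heavy-user subgroup composition) stable
while keeping a full run in minutes on one CPU. The headline percentage
changes of the published 3000-patient comparison are *not* asserted
numerically: they depend on the unpublished PBPK flow constants, so the
package checks their directions, not their magnitudes.

## Known limitations

* Lateral diffusion, dermal advection and capillary microarchitecture are
  outside the model; the equivalent-dermis thickness absorbs them.
* No metabolite kinetics, no CO2 feedback on ventilation, no liver/kidney
  function covariates, and no dose-strength titration (replacement always
  uses the same patch size).
* The PBPK flow block is effective, not anatomical; absolute plasma
  magnitudes inherit its calibration and should be read comparatively.
* The synthetic sample cohort matches printed summaries exactly but is not
  the real cohort; conclusions about covariate effects are conditional on
  the printed correlation structure.
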