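---
title: "Methods: the corrected whole-body glucose-insulin-glucagon model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the corrected whole-body glucose-insulin-glucagon model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorensen)
```

## The model

The package simulates the classical whole-body compartmental model of
glucose homeostasis in its corrected form, extended with a linear
gastrointestinal transit chain for oral dosing. The state comprises

* eight glucose compartments (mg/dl): brain vascular and interstitial,
  heart/lungs, gut, liver, kidney, peripheral vascular and interstitial;
* seven insulin compartments (mU/l) over the same organ topology (a single
  well-mixed brain pool);
* normalized plasma glucagon (basal = 1);
* three slow hepatic regulatory states: the insulin multipliers of hepatic
  glucose production and uptake, each relaxing toward a tanh law of
  normalized liver insulin with time constant `tau_I = 25` min, and the
  glucagon-effect offset `f2` with `tau_Gamma = 65` min;
* the pancreatic secretion submodel: potentiator `P`, inhibitor `I` and
  labile insulin `Q` (U), with glucose-driven signals
  `X = g^b1 / (b2^b1 + b3 g^b4)` and `Y = X^b5` and secretion
  `S = [M1 Y + M2 (X - I)^+] Q`;
* four gut compartments (mg): stomach, jejunum, a delay pool and ileum,
  with linear transfers and bioavailable fraction `f`, producing the
  plasma-appearance input `r_oga = f (k_gj J + k_gl L)`.

Organ mass balances are flow-limited (`Q` terms) with capillary-tissue
exchange in brain and periphery (`V/T` terms). Metabolic sinks and sources
are products of basal rates with dimensionless tanh multipliers of
*normalized* concentrations (concentration divided by its basal value),
e.g. peripheral uptake `r_PGU = M_I(I_PI^N) G_PI^N * 35` mg/min and the
renal excretion law `r_KGE = 71 + 71 tanh[0.011 (G_K - 460)]` below the
460 mg/dl threshold, `-330 + 0.872 G_K` above it.

### The corrections are canonical

Only the corrected forms of the model are implemented: the renal slope
0.011 (not 0.11), kidney insulin clearance driven by the arterial
(heart/lungs) concentration, the labile-pool balance
`dQ/dt = K (Q0 - Q) + gamma P - S` with the restoring sign, and the
peripheral interstitial glucose gradient driven by *peripheral* uptake.
The erroneous summary forms exist only as regression fixtures in the test
suite, where each is shown to break the basal cascade or destabilize the
pancreas.

### Parameter presets and the K/gamma resolution

Two presets ship: `appendix_a1` (the corrected literature values, with the
pancreatic dose-response in mg/dl) and `table3_after` (the oral-test
refit, dose-response in mM, conversion 18 mg/dl per mM and 7000 pmol per
U). The literature summary prints `K = 0.575 U/min`, which is
dimensionally a flux and numerically identical to the provision rate
gamma (4025 pmol/min / 7000 pmol/U); with the tabulated
`K = 0.00794/min` instead, the basal pancreas closes to
`S_B = 18.36 mU/min`, within 0.3% of the basal release `r_PIRB =
18.41 mU/min` implied independently by the insulin clearance cascade.
The package therefore defaults to `K = 0.00794/min`, `gamma = 0.575
U/min`, and keeps the printed flux value available as `K_alt_U_min`.

### Glucagon normalization

No absolute basal glucagon concentration is part of the parameterization,
so glucagon is simulated normalized (basal = 1): the mass balance is
divided by the distribution volume, clearance is first-order with rate
`r_MGammaC / V_Gamma`, and basal release is closed so release equals
clearance at basal. With the printed clearance of 9.10 ml/min against an
11.3 l volume the glucagon turnover time is roughly 1240 min — glucagon
is effectively frozen over test horizons. This follows the source values
as printed; absolute glucagon output is intentionally not reportable.

## Basal initialization: printed cascade vs exact equilibrium

`basal_state()` first evaluates the closed-form basal cascade from the
input basal glycemia and insulinemia (89 mg/dl and 12.8 mU/l by default):
heart glucose from the peripheral gradient, organ concentrations from
their flow balances, heart insulin `I_PVB / (1 - F_PIC)`, liver insulin
and the basal pancreatic release from the heart and liver balances, and
the basal pancreas from its equilibrium relations. These cascade values
are also the *normalizers* of every multiplier argument.

The printed initial conditions are not an exact equilibrium: the rounded
multiplier coefficients leave the liver and periphery slightly
unbalanced, and the renal law excretes 0.042 mg/min at basal glucose
while the printed kidney concentration equals the heart concentration.
The resulting drift is below 0.3% over 180 min — negligible
physiologically, but incompatible with a strict steady-state check. By
default the package therefore Newton-refines the full 22-state algebraic
steady state (normalizers held at the cascade values), reaching
`max |dX/dt| ~ 1e-12`; the state shifts stay below 0.05 of a native unit
in every compartment. `basal_state(exact = FALSE)` reproduces the printed
initial conditions verbatim (unit regulatory multipliers, `f2 = 0`,
kidney glucose equal to heart glucose) for comparison studies.

## Protocols and observables

`run_protocol()` integrates from the basal state. Intravenous doses enter
the heart/lungs balances as constant-rate inputs over the administration
window (3 min by default — the only window the source scenarios state,
applied uniformly and configurable); infusions use the window as the
infusion length; oral doses load the stomach at time zero. Body weight
defaults to the 70 kg standard man. Observable channels apply the venous
conversion factors: peripheral venous *blood* glucose is `0.84 G_PV`,
venous *plasma* glucose `0.925 G_PV`; insulin is reported as simulated.
The insulin infusion dose unit is mU/kg/min — the only dimensionally
sensible reading of a 150-minute continuous infusion.

## Numerical integration

The integrator is an adaptive embedded Dormand-Prince 5(4) pair with PI
step-size control, written in the package because no ODE solver library
is available in the supported dependency set. The model is non-stiff at
physiological parameters — the fastest local time constant (brain insulin
exchange, heart/lungs turnover) is about 0.3-0.5 min against simulation
horizons of minutes to hours — so an explicit pair at the default
tolerances (`rtol = 1e-8`, `atol = 1e-10`, exposed everywhere) resolves
the dynamics: halving the tolerances moves reported channels by less than
0.01% (asserted in the test suite). Output times are hit exactly by step
clamping, so there is no interpolation error on the reported grid; dosing
discontinuities are never stepped across because the integration is split
at window boundaries. The gut chain is linear, and the package also
carries its exact matrix-exponential solution, used both as the fast path
for absorption-curve fitting and as an independent cross-check of the
Runge-Kutta route.

## Estimation

The loss is weighted least squares with weights the inverse squared model
expectations — the constant-CV error model. A structurally zero
expectation (the absorption rate at dose time) has zero variance: matched
by a zero observation it contributes nothing; any other value is
penalized. Simulation failures inside an optimization return a large
finite penalty (1e9) rather than aborting the start. Multistart draws
each free parameter from a Normal centered on its center value with SD
15% of that value, truncated at a positivity floor of `1e-8 * center`
(a documented deviation: the Normal has support below zero). The local
minimizer defaults to a quasi-Newton search in log-parameter space with a
simplex polish and a second quasi-Newton pass — empirically the most
reliable scheme on this loss surface; a pure Nelder-Mead is available.
Per-start seeds derive deterministically from the master seed.

The asymptotic covariance at an optimum is `[J' S^-1 J]^-1` with `J` the
central finite-difference Jacobian of the predictions and
`S = sigma^2 diag(f^2)`; percent CVs are `100 sqrt(cov_ii) / theta_i`.
A rank-deficient information matrix (a parameter without effect) falls
back to the pseudo-inverse with a warning.

The four-step pipeline mirrors the staged identification protocol: the
transit rates first (bioavailable fraction fixed at 1), then 100 starts
over the 11 free secretion parameters (`Q0` fixed), then a joint
16-parameter fit from the combined optima, then 200 perturbed restarts
summarizing estimate spread, correlations and the loss distribution.
Stage sizes scale down through arguments for test runs.

### A structural identifiability finding

The transit chain with `f = 1` is only *locally* identifiable from the
absorption curve: exchanging the pole pairs
`{k_js <-> k_gj + k_rj}` and `{k_lr <-> k_gl}` reproduces `r_oga(t)`
to machine precision. "Recovery of the generating values" is therefore
meaningful only within the generating basin, which is how the recovery
tests are posed (multistart about the generating values with the standard
15% perturbation). Starting instead from the population-average preset —
as the staged pipeline does — may legitimately converge to the
pole-swapped equivalent with an identical curve. Relatedly, at 5% noise
on the declared 27-point grid the asymptotic CVs of the five rates range
from 24% to 99% with estimate correlations up to -0.998, so no single
noisy realization can pin all five rates to 15%; the corresponding
acceptance check is left failing, with the analysis recorded rather than
the bound loosened.

## Bayesian a-posteriori identifiability

The inference target is `(log theta, sigma^2)`. `sigma^2` carries an
inverse-gamma prior (weakly informative `nu = tau = 0.01` by default —
the source states no values; both are exposed) and is drawn exactly from
its inverse-gamma full conditional. `log theta` carries a uniform prior
on a box `D` spanning plus/minus 100% of the log-optimum per axis, and is
updated by a random-walk Metropolis step: multinormal proposal centered
on the current point, covariance built once from the asymptotic CVs via
`Var(log theta) = CV^2` and held fixed across iterations. Nine chains of
10,000 draws start on the 3x3 lattice of `D` (vertices, edge midpoints,
center); the first 1000 draws per chain are burn-in, leaving 81,000
pooled realizations. Each chain runs on a seed derived deterministically
from the master seed (R's base RNG offers no counter-based streams; the
derived-seed scheme is the reproducible equivalent).

The 95% credibility region is built from a 20x20 relative-frequency
histogram on the pooled-draw bounding box as the smallest superlevel set
with mass at least 0.95. Exact mass 0.95 is unreachable on a discrete
histogram; ties at the threshold frequency are broken in deterministic
cell order, which bounds the selected mass by 0.95 plus one maximal cell
frequency (asserted in the tests).

## Synthetic data: what a green test establishes

All observation sets are generated by the package itself under the
mean-proportional error model `y = f (1 + sigma z)` and are labelled
STANDIN: the absorption-rate curve (27 points: every 5 min to 70, every
20 min to 300 — a declared grid, dense early and sparse late as in oral
tests), the secretion-rate curve (25 points) and the oral-test glucose
and insulin channels, generated from the refitted preset. They emulate
the sampling layout and noise structure of the original recordings, not
their values: the originals were digitized from figures and never
printed. Green estimation and MCMC tests therefore establish that the
machinery is correct and self-consistent (oracle agreement, parameter
recovery in the generating basin, posterior moments on conjugate toys) —
they do not reproduce the published table entries, loss range or
posterior means, which depend on the unpublished data and are
deliberately not asserted anywhere.

## Known limitations

* No incretin mechanism: oral glucose does not potentiate secretion
  beyond what refitted secretion parameters absorb (by design).
* No subcutaneous insulin route; intravenous boluses and infusions only.
* The glucagon submodel is effectively static under the printed clearance
  (see above).
* The explicit integrator is not suitable for parameterizations that
  make the system stiff (none of the shipped presets do).
* Tanh multiplier laws are used as printed; Hill-function variants are
  out of scope.
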