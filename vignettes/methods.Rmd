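---
title: "Model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnpkpd)
```

This vignette documents the model implemented by `ifnpkpd`, its assumptions,
the estimation and model-selection machinery, the numerical choices behind
the solvers and the optimizer, what the synthetic-data generator does and
does not emulate, and the known limits of the study design it reproduces.

## The biological system and the model

After hydrodynamic tail-vein injection of a naked expression plasmid, the
liver is transiently transfected and expresses the encoded protein in situ.
The package models this for two constructs — interferon-α fused to GFP
(`IFNGFP`) and the same protein additionally fused to apolipoprotein A-I
(`IFNGFPApo`) — through four coupled blocks:

1. **Transcription.** The injected DNA pool degrades (`k_NUNC`) and converts
   into a second, longer-lived transcriptionally active pool (`DNAprime`);
   one rate constant `k_INT` governs both the formation and the elimination
   of that pool. Both pools synthesize mRNA (`k_S1`, `k_S2`), which decays at
   `k_DEG`. Because the effective amount of plasmid reaching hepatocytes is
   unknown, the dose is one arbitrary unit, and `k_S1`/`k_S2` absorb the
   scale of the gene-expression units. The same parameter set describes both
   constructs — the plasmids differ only in their coding sequence.
2. **Delayed hepatic synthesis and disposition.** Between mRNA and measurable
   hepatic protein sits a chain of three identical transit compartments
   (`dT1/dt = k_TRAN(mRNA − T1)` etc.), a standard signal-transduction delay;
   the protein then exchanges reversibly between liver and serum
   (`k_ls`, `k_sl`), degrades in the liver (`k_D`), and enters the brain at a
   very slow first-order rate (`k_sb`). For the ApoAI fusion a peripheral
   distribution compartment exchanging with serum (`k_sp`, `k_ps`) is part of
   the variant; there is no direct first-order elimination from serum in
   either variant.
3. **Brain.** One compartment with first-order input from serum (`k_sb`) and
   first-order exit (`k_E`).
4. **ISG dynamics.** Interferon-stimulated genes (ISG15, 2′-5′ OAS) follow an
   indirect-response model: synthesis driven by the model-predicted protein
   level in the same organ — saturably in liver
   (`k_S_ISG·IFN/(IFN + IFN_50)`, parameters shared between constructs) and
   linearly in brain (construct-specific synthesis rate, shared degradation
   rate) — with first-order degradation `k_D_ISG`.

Two unit conventions make all transfers unit-free first-order exchanges
between scalar amounts: tissue protein density is taken as 1 mg/mL and the
volume of distribution as 1 mL, so pg/mg (liver, brain) and pg/mL (serum)
are numerically interchangeable. This is a deliberate simplification, not a
physiological claim; the model is compartmental, not physiologically based.

Where a single symbol had two spellings in the source material the package
uses one: the brain input rate is `k_sb` (elsewhere `k_sbr`) and the brain
exit rate `k_E` (elsewhere `k_b0`).

On the structure of the `DNAprime` balance: with a single rate constant
described as controlling both formation and elimination of the second pool,
the implemented form is `dDNA/dt = −(k_NUNC + k_INT)·DNA`,
`dDNAprime/dt = k_INT·(DNA − DNAprime)` — conversion depletes the parent
pool, conserving mass. The alternative (formation without depletion) changes
only the effective amplitude absorbed by `k_S1`/`k_S2` under the arbitrary
dose unit; we did not expose it as an option.

## Parameters that matter

| Parameter | Units | IFNGFP | IFNGFPApo | Role |
|---|---|---|---|---|
| `k_NUNC`, `k_INT`, `k_DEG` | 1/h | 1.60, 0.112, 2.12 | shared | DNA/mRNA turnover |
| `k_S1`, `k_S2` | units/h per DNA unit | 1080, 2.96 | shared | transcription |
| `k_TRAN` (`n_transit` = 3) | 1/h | 1.45 | 0.266 | synthesis delay; MTT = (n+1)/k_TRAN |
| `k_S` | pg/h per unit | 769 | 53600 | hepatic synthesis |
| `k_D` | 1/h | 22.4 | 0.0773 | hepatic degradation |
| `k_ls`, `k_sl` | 1/h | 120, 0.406 | 1720, 0.420 | liver–serum exchange |
| `k_sp`, `k_ps` | 1/h | — | 1.54, 0.00994 | serum–peripheral exchange |
| `k_sb` | 1/h | 1.08e-6 | 3.75e-5 | brain input |
| `k_E` | 1/h | 0.118 | 0.509 | brain exit |
| `IFN_50` (liver ISG15 / OAS) | pg/mL | 151 / 255 | shared | half-maximal driver level |

These built-in sets (`reference_kinetic_params()`, `reference_isg_params()`)
are the defaults for simulation and the ground truth of the synthetic-data
generator. The transit chain length defaults to 3 but is configurable
(including 0, which removes the delay and `k_TRAN` with it) for model
discrimination. One printed inconsistency is taken at face value: the liver
ISG15 degradation rate equals its synthesis rate (491/h), which makes that
response track its saturable driver quasi-instantaneously; see
*Identifiability* below.

## Error model and estimation

Observations are strictly positive concentrations spanning several decades,
with residual scatter roughly proportional to the level; fitting therefore
uses `Y_obs = Y_pred·(1 + ε)` on the log scale. The objective is the
extended-least-squares form

```
MVOF = sum_j [ log ω²_r(j) + (log Y_obs,j − log Y_pred,j)² / ω²_r(j) ]
```

with one residual variance `ω²` per response type by default (a shared-`ω²`
switch exists; nothing in the workflow requires one choice, and per-response
is the safer default when responses have different assays). The constant
`N·log 2π` and the log-normal Jacobian are omitted — only differences in the
objective are ever interpreted. At the optimum `ω²` equals the mean squared
log-residual of its response, so it is profiled out analytically rather than
searched numerically; the profiled variance is floored at 1e-18 purely so the
objective stays finite on noise-free data while remaining strictly decreasing
in the residuals.

Fitting is **naive-pooled**: all animals' observations enter one likelihood
without random effects. Under destructive sampling each animal contributes a
single timepoint, so inter-animal variability and residual error are not
separable anyway; mixed-effects modelling is out of scope.

The **four-stage sequential procedure** mirrors how the data inform the
model: (i) transcription parameters from both constructs' liver mRNA jointly
(one shared set); (ii) with those fixed, hepatic/disposition parameters per
construct from liver and serum protein (the early 1/3/7 h serum series is
fitted jointly with the main study — it is what identifies the synthesis
delay); (iii) with all previous fixed, `(k_sb, k_E)` per construct from brain
protein, driving the brain compartment with the fixed stage-(ii) serum
profile (the coupling is one-way at these magnitudes); (iv) ISG parameters
per gene and organ. During stage (ii), `k_sb` is held at its scaffold value
rather than zero: for the ApoAI fusion, serum levels are ~10³ times liver
levels, so even `k_sb ≈ 4e-5`/h removes protein at a rate comparable to
hepatic degradation, and omitting it would bias `k_D`.

**Optimizer.** Free parameters are log-transformed (positivity by
construction) and minimized by a Nelder–Mead simplex/BFGS relay, optionally
multi-started from log-normally jittered copies of the start
(`fit_control()`); ties resolve by lowest objective. Standard errors come
from the inverse of the numerically differentiated Hessian of MVOF/2 at the
optimum in natural parameter space; a non-positive-definite Hessian is
reported as such and the SEs marked unavailable — no pseudo-inverse.
CV% = 100·SE/estimate is the precision measure used by the selection gate.
`recovery_experiment()` defaults to a single local fit started at the
generating values: a recovery study asks whether the data pull the estimate
away from a correct start, and with destructive-sampling designs this far
from saturating the model (see *Identifiability*), aggressive global search
merely hops between noise-equivalent interpolants.

Observations ≤ 0 cannot enter a log-scale likelihood; they are dropped at
validation with a count report rather than imputed — the model has no
below-quantification mechanism.

## Model selection

Nested pairs are compared by the drop in MVOF against χ² quantiles
(`lrt_threshold()` generalizes the classical 1-df 3.84/6.63/10.83 to any
df). Non-nested candidates use `AIC = N·log(RSS/N) + 2·Np` with RSS on the
log scale and natural logarithms. A winner whose estimates include a CV%
above 100 (or whose Hessian failed) is demoted in favour of the next
candidate with proper standard errors. `fit_with_selection()` wires the
three discriminations that matter in this system: transit delay vs none (1
extra parameter), peripheral compartment vs none (2 extra), and saturable vs
linear liver ISG synthesis (AIC).

## Derived quantities

`mean_transit_time()` uses `(n_transit + 1)/k_TRAN`: the expected traversal
time counts the synthesis-driving step in addition to the n transit hops —
the convention consistent with both built-in transit rates and their
characteristic delays (4/1.45 ≈ 2.76 h; 4/0.266 ≈ 15 h). `half_life()` is
`ln 2/k`; `auc()` is a trapezoidal integral over the simulated grid with
interpolated endpoints (grid-refinement convergence is tested).

## Synthetic-data generator

`study_design()`/`generate_study()` emulate the mouse study: terminal
sampling of liver, serum and brain at 6, 9, 13, 24 and 48 h with 6–8 animals
per construct and timepoint (drawn uniformly per point, from two pooled
experiments), plus a serum-only series at 1, 3 and 7 h with 3 animals (a
third experiment). Destructive sampling is respected: one animal contributes
all its organ responses at exactly one timepoint. Noise is realized
log-normally, `Y = Y_pred·exp(η)` with `Var(η) = log(1 + ω²)`, so the
coefficient of variation equals the nominal proportional ω while values stay
positive for the log-scale likelihood; the difference from a symmetric
proportional error is second-order for ω ≤ 0.3. ω defaults to 0.2, a typical
magnitude for ELISA/qPCR readouts at this scale. Optional multiplicative
experiment-level factors (emulating inter-experiment normalization left
undone) and animal-level random effects exist for robustness studies and
default to off; fitting assumes normalization has removed them.

The generator draws mean trajectories through the exact matrix-exponential
path, so at ω = 0 the emitted values are the model's predictions to machine
precision. What it does **not** emulate: assay limits of quantification and
censoring, qPCR cycle-threshold mechanics (gene-expression units are the
already-normalized 2^ΔCt scale), true inter-animal kinetic variability, and
any misspecification between the generating and fitted model family.
Passing recovery tests therefore demonstrate internal consistency of
estimator and generator under the study design — not that real data of this
kind would identify every parameter.

## Numerical choices

- **Solvers.** Rate constants span ~9 orders of magnitude (`k_sb ≈ 1e-6`/h vs
  `k_ls ≈ 1.7e3`/h), so the reference integrator is stiff-capable adaptive
  `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`. The kinetic block is
  linear with constant coefficients, so an exact path (`method = "matexp"`)
  computes states by matrix-exponential stepping (Padé via `Matrix::expm`;
  the transit chain makes the system matrix defective, ruling out eigen
  decomposition), with step propagators cached per unique step length and
  near-integer step ratios resolved by repeated squaring. Fitting uses this
  exact path; ~10⁵ objective evaluations per study make it the difference
  between seconds and hours.
- **ISG/brain driven solves.** Given a (piecewise-linear) driver profile,
  the turnover equation is integrated by an exact exponential-integrator
  update per step — stiffly accurate even at `k_D_ISG = 491`/h — with series
  fallbacks for small `k·h` to avoid cancellation. Staged and fully coupled
  solutions agree to solver tolerance because brain and ISG do not feed
  back.
- **Degenerate inputs.** Non-positive doses, rates, designs and empty
  candidate lists are rejected with explicit messages; a prediction ≤ 0
  inside the likelihood yields `+Inf` with row diagnostics rather than a
  silent `NaN`; solver non-convergence reports the failing time span.
- **Problem sizes.** The shipped tests and the acceptance script use 20
  Monte-Carlo replicates per recovery/selection experiment and the study's
  own sampling design; these sizes give stable medians and selection rates
  for the quantities asserted while keeping a full run in the minutes range.

## Identifiability and known limitations

The printed design (five terminal timepoints from 6 h onward) does not
saturate this model, and the package documents rather than hides that:

- **Transcription.** The log-sensitivity matrix of mRNA at 6–48 h with
  respect to the five transcription parameters has singular values spanning
  {6.6 … 2.7e-6}: effectively three identifiable directions. `k_INT` (the
  terminal mRNA slope) is well determined; `k_NUNC`, `k_S1`, `k_S2`, `k_DEG`
  lie on a sloppy ridge of noise-equivalent interpolants — without pre-6 h
  mRNA samples no estimator can pin them individually. Noise-free recovery
  works (the exact optimum is the truth); at realistic noise their
  Monte-Carlo medians are optimizer-dependent.
- **Fusion hepatic degradation.** For the ApoAI fusion, `k_D = 0.0773`/h is
  negligible against `k_ls = 1720`/h: hepatic degradation removes protein at
  ~1e-5 of the export flux scale, and a 20% change in `k_D` moves every
  liver/serum log-prediction by ~1e-5. The 0–48 h profiles are shaped by
  synthesis decay and serum–peripheral redistribution; `k_D` is effectively
  not estimable from them.
- **Liver ISG15.** With `k_D_ISG = k_S_ISG = 491`/h the response equilibrates
  within seconds, so only the ratio `k_S_ISG/k_D_ISG` and `IFN_50` are
  identified; the pair itself is a flat ridge. `IFN_50` — the
  pharmacologically meaningful quantity — recovers well.
- **Washout horizon.** The fusion's slowest kinetic eigenvalue is ~5e-5/h
  (mass parked in the peripheral store), so complete washout takes ~1e6 h;
  asymptotic-decay tests use each system's own slowest timescale.
- Mixed-effects estimation, physiological organ volumes/flows, intracellular
  trafficking and Bayesian uncertainty are out of scope.
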