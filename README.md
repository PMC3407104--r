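# ifnpkpd

Kinetic–dynamic modelling of liver-expressed interferon-α fusion proteins.

Fusing interferon-α (IFNα) to apolipoprotein A-I changes where the cytokine
goes and how long it stays: the fusion rides on HDL particles, persists in
serum, and induces interferon-stimulated genes (ISGs) differently in liver and
brain. `ifnpkpd` implements a semi-mechanistic ODE model of what happens after
hydrodynamic injection of a naked expression plasmid into mouse liver — from
plasmid DNA through mRNA, delayed hepatic protein synthesis, liver/serum/brain
disposition, down to ISG induction — together with the maximum-likelihood
machinery to fit it to destructive-sampling time-course data, the model
discrimination rules used in that workflow, and a synthetic-data generator
that emulates the mouse study design so the entire pipeline runs and is tested
without any external data. It is aimed at pharmacometricians and systems
pharmacologists who want a reusable, tested implementation of this model
family (in-situ expression kinetics + transit-delay synthesis +
indirect-response dynamics).

## The model

For each molecule (plain IFNα–GFP, or the IFNα–GFP–ApoAI fusion), with all
rates first-order:

**Hepatic transcription** (shared between molecules; dose is one arbitrary
DNA unit placed in the liver at t = 0):

    dDNA/dt   = −(k_NUNC + k_INT)·DNA
    dDNA′/dt  = k_INT·(DNA − DNA′)
    dmRNA/dt  = k_S1·DNA + k_S2·DNA′ − k_DEG·mRNA

**Delayed hepatic synthesis and disposition** (a chain of n = 3 transit
compartments delays synthesis; the fusion additionally needs a peripheral
serum compartment; there is no direct first-order elimination from serum):

    dT1/dt    = k_TRAN·(mRNA − T1),   dTi/dt = k_TRAN·(T(i−1) − Ti)
    dlIFN/dt  = k_S·Tn − k_D·lIFN − k_ls·lIFN + k_sl·sIFN
    dsIFN/dt  = k_ls·lIFN − k_sl·sIFN − k_sb·sIFN [− k_sp·sIFN + k_ps·P]
    dP/dt     = k_sp·sIFN − k_ps·P
    dbrIFN/dt = k_sb·sIFN − k_E·brIFN

The mean transit time of the synthesis delay is `MTT = (n + 1)/k_TRAN`.

**ISG turnover** (indirect response; driver is the model-predicted protein
level in the matching organ):

    dISG/dt = k_S_ISG·f(IFN) − k_D_ISG·ISG,
    f(IFN) = IFN/(IFN + IFN_50)   (liver, saturable)
    f(IFN) = IFN                  (brain, linear)

**Estimation**: observations follow the proportional error model
`Y_obs = Y_pred·(1 + ε)`, fitted on the log scale by extended least squares;
the objective (MVOF, −2 log-likelihood up to a constant) is minimized in four
sequential stages (transcription → protein → brain → ISG), each fixing the
parameters of the previous ones. Nested candidates are compared by the drop
in MVOF against χ² quantiles (3.84 / 6.63 / 10.83 at 5% / 1% / 0.1% for one
extra parameter), non-nested ones by `AIC = N·log(RSS/N) + 2·Np`, with a
precision gate demoting winners whose estimates carry CV% > 100.

## Worked example

```r
library(ifnpkpd)

params <- reference_kinetic_params("IFNGFPApo")   # built-in estimates
traj <- simulate_system(params, times = seq(0, 48, by = 0.5))
trajectory_values(traj, "serum_protein", c(6, 9, 13, 24, 48))
#> [1] 566000 758000 669000 226000 104000          # pg/mL

derived_report(params)[, 1:3]
#>                  quantity        value   units
#> 1       mean_transit_time 1.503759e+01       h
#> 2 liver_protein_half_life 8.966975e+00       h
#> 3    brain_exit_half_life 1.361782e+00       h
#> 4               serum_auc 1.390198e+07 pg*h/mL
```

Serum levels of the ApoAI fusion peak near 9 h at ~7.6×10⁵ pg/mL and remain
above 10⁵ pg/mL at 48 h; its synthesis delay (mean transit time ≈ 15 h) is
about five times longer than the plain construct's (≈ 2.76 h), and its 0–48 h
serum exposure is about five-fold higher — the kinetic signature of the HDL
anchor.

A full in-silico study — generate noisy observations under the mouse design,
refit all four stages, and compare model variants:

```r
cfg <- reference_model_config()                    # generating truth
ds  <- generate_study(study_design(omega = 0.2), cfg, seed = 1)
res <- fit_with_selection(ds, start_config = cfg, seed = 1)
res$comparisons$delay.IFNGFP                       # transit delay vs none (LRT)
res$comparisons$isg_form.ISG15.liver               # saturable vs linear (AIC)
```

Config-driven equivalents (`pipeline_generate()`, `pipeline_simulate()`,
`pipeline_fit()`) and a thin CLI wrapper
(`inst/scripts/ifnpkpd-cli.R`) are provided for scripted runs.

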