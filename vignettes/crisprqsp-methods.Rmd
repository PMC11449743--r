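---
title: "Methods: a translational QSP model of LNP-delivered CRISPR-Cas9 therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a translational QSP model of LNP-delivered CRISPR-Cas9 therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprqsp)
```

## The model

`crisprqsp` implements a minimal physiologically based (mPBPK) disposition
model for an in-vivo CRISPR-Cas9 therapy delivered by lipid nanoparticles
(LNP) carrying a single guide RNA (sgRNA) and a Cas9-encoding mRNA, coupled
to indirect-response pharmacodynamics for three serum biomarkers. Three
species are bundled: mouse (28 g), cynomolgus monkey (5 kg), and human
(71 kg).

The disposition system tracks amounts (ug) of four moieties — LNP lipid,
sgRNA, mRNA, and (intracellularly) Cas9 protein and the sgRNA-Cas9
ribonucleoprotein (RNP) complex — across:

* **plasma**, with organ plasma flows `Q` and lymph flows fixed at 0.2% of
  `Q`;
* a **three-layer liver** (vascular, interstitial, cellular), the target
  organ;
* the **mononuclear phagocyte system (MPS)**, an irreversible sink fed by
  first-order phagocytosis (`k_int`) of vascular free LNP, with
  degradation at `k_deg_LNP`;
* a **kidney** compartment for LNP and sgRNA only — mRNA is too large for
  glomerular filtration and has no kidney states — with first-order renal
  elimination at a flow-limited clearance `fu * Q_kidney`;
* a lumped **remainder**.

Processes in the liver:

* **Opsonization (bio-corona formation).** Free LNP binds plasma opsonins
  reversibly (`k_ass`, `k_dis`) in plasma and in the liver vascular space.
* **Trans-layer transport.** Vascular-to-interstitial exchange combines
  lumped endocytosis (`CL_in = k_in_endo * V`), exocytosis
  (`CL_out = k_out_exo * V`), and convection through paracellular pores at
  the lymph flow `L` attenuated by a vascular reflection coefficient
  `sigma_V`; interstitial material returns to plasma with the lymph,
  attenuated by the interstitial coefficient `sigma_I`.
* **Receptor-mediated uptake.** Interstitial LNP binds the LDL receptor
  (`k_on_LNP`, `k_off_LNP`); the complex is internalized at `k_deg_DR`,
  delivering its carried cargo to the cellular layer. The receptor pool
  turns over with `k_syn = LDL_tot * k_el`, so its undisturbed baseline is
  exactly `LDL_tot`; internalization consumes receptor, giving
  target-mediated disposition.
* **Cargo release.** Free interstitial LNP releases cargo at `k_release`.
  Carried cargo is not a separate state: conversions use the LNP-to-RNA
  mass ratio of the regimen (`cargo = k_release * LNP / lnp_ratio`, split
  by the 33.3/66.7 sgRNA/mRNA mass fractions).
* **Intracellular kinetics.** Cellular mRNA is translated into Cas9
  (`k_trans`); sgRNA and Cas9 associate into the RNP complex
  (`k_on_RNP = k_off_RNP / KD`, with the 0.49 nM dissociation constant
  converted to ug/mL via the Cas9 molecular weight, 160 kDa), which
  dissociates at `k_off_RNP` and — by assumption — does not degrade. Free
  sgRNA, mRNA, and Cas9 degrade at first order.

All rate constants are per species (the bundled values are the published
estimates); `k_in_endo` in the mouse is fixed by allometric scaling from
the monkey with exponent -0.25.

## Pharmacodynamics

The PD driver is the liver-cell RNP concentration
`C_RNP = RNP / V_liver_cell` (ug/mL); editing in the liver is assumed to
act directly on hepatically produced serum biomarkers, reported as percent
of a baseline fixed at 100%.

* **TTR (transthyretin):** a type-I indirect response model with
  inhibition of production,
  `dTTR/dt = k_out*TTR0*(1 - Imax*C^g/(IC50^g + C^g)) - k_out*TTR`.
  The steady state under a constant clamp is
  `TTR_ss/TTR0 = 1 - I(C)`, which saturates at `1 - Imax`.
* **PCSK9:** a transit chain of `n_transit = 3` compartments with rate
  `k_tr = n_transit/MTT`; synthesis into the first compartment carries the
  Hill inhibition and a feedback term `(PCSK9_0/PCSK9)^gamma_fb`
  (switchable), producing the delayed nadir characteristic of the
  feedback-loop model family. The chain's impulse response has mean
  exactly `MTT`.
* **LDL-C:** a precursor-dependent model whose production scales as
  `(PCSK9/PCSK9_0)^Gamma`, so PCSK9 lowering propagates into LDL-C with
  exponent `Gamma`.

Note one modeled idealization inherited from the source models: gene
editing is permanent, yet the indirect-response structure lets biomarkers
rebound as the RNP pool decays. This "relapse" behavior is intentional.

## Key reconstruction decisions

The source model's full equation listing and physiological tables are not
publicly available; the system was reconstructed from narrative process
descriptions. Where those under-determine the structure, the package
makes one default choice, exposes a switch, and documents it here:

* **Physiological volumes and flows** are standard reference values
  (plasma volume about 4.9% of body weight; liver split 15/20/65% into
  vascular/interstitial/cellular; organ plasma flows as fractions of
  cardiac plasma output). Every value is overridable through a JSON
  physiology config.
* **Free-fraction application** (`fu_receptor_gate`, default off). The
  published LNP free fraction (0.002) is footnoted as derived from renal
  clearance, so by default it gates renal filtration only. Gating receptor
  binding with it (the switch's "on" position) reduces hepatic delivery
  about 500-fold and leaves the biomarker models numerically inert — the
  measured liver-cell RNP peaks about 21 orders of magnitude below the
  published IC50s — which is inconsistent with the magnitudes the source
  model was able to fit. The RNA free fraction (0.15) gates endocytic and
  convective RNA uptake from plasma-side compartments.
* **Cellular uptake is one-way** (`cell_exo_frac`, default 0). Cell entry
  is pinocytosis; the lumped exocytosis constant (fitted at 2,690 1/h in
  the monkey) describes the vascular-interstitial interface, where it was
  identified from plasma PK. Applying it also to the cellular layer
  empties the cell on a ~1-second timescale and kills the PD for the same
  reason as above. Setting `cell_exo_frac = 1` restores the fully
  symmetric two-interface reading.
* **Opsonized LNP extravasates** (`ops_extravasation`, default 1),
  shedding its corona on internalization; it never enters the MPS nor
  binds the receptor while opsonized. The ApoE-containing corona is the
  liver-targeting mechanism; moreover, at the human opsonin constants
  99.7% of circulating LNP is corona-bound, so forbidding its
  extravasation cuts human hepatic delivery ~300-fold.
* **Cargo bookkeeping.** Following the "immediate release" assumption,
  the sgRNA and mRNA doses enter plasma as free species at administration
  while the LNP lipid dose is tracked separately; the `k_release` and
  `k_deg_DR` pathways convert LNP mass to cargo via `lnp_ratio`. A
  consequence: with `k_release > 0` total RNA mass is not a conserved
  quantity (the release bookkeeping is a source term), so conservation
  tests switch `k_release` off and a separate test pins the source term
  to its stated rate.
* **Unreported constants.** The human TTR Hill coefficient is not
  reported and defaults to 1; the Cas9 degradation rate is unnamed and
  defaults to the mRNA degradation rate; RNP stoichiometry uses a 32 kDa
  sgRNA against the 160 kDa Cas9 (mass ratio 0.2); monkey biomarker
  sampling days are not printed and default to a conventional
  {1, 2, 4, 7, 14, 21, 28}-day schedule.

## Numerics

The system is stiff (rate constants span 0.00188 to ~2,700 1/h), so the
integrator is a compiled L-stable Rosenbrock 2(3) method
(Shampine-Reichelt scheme) with a forward-difference Jacobian refreshed
every step, adaptive step size, exact landing on output times, and a
restart at the end-of-infusion discontinuity so the right-hand side is
smooth within every integration segment. Round-off negatives within the
absolute tolerance band are flushed to zero. Defaults are
`rtol = 1e-8, atol = 1e-10` for plain simulation; calibration, GSA and
population runs default to `rtol = 1e-6` (or `1e-5` for the large Monte
Carlo sweeps) to keep runtimes at desk scale — the test suite verifies
that every isolated subsystem matches its closed form to 1e-6 relative
error, and that the compiled right-hand side agrees with an independently
assembled pure-R reference to machine precision.

Calibration maximizes a fixed-effect likelihood with the proportional
error model `Var_i = sigma_slope * Y_i^2`; `sigma_slope` is profiled
analytically per output (its conditional MLE is the mean squared relative
residual), parameters are optimized on the log scale with L-BFGS-B under
box bounds (default `init/100` to `init*100`, Imax capped at 1), with
optional Latin-hypercube multi-start. Relative standard errors are
`100 * SE(log theta)` from the inverse central-difference Hessian; the
Hessian step (0.01 on the log scale) is deliberately coarse so solver
noise does not dominate the curvature estimate. Population (SAEM-style)
random-effects estimation is out of scope; between-subject variability
appears only in the forward Monte Carlo module.

Sobol sensitivity uses the Saltelli design (`N*(2d+2)` rows) with Jansen
estimators for first- and total-order indices, averaged over the two
half-designs, plus bootstrap confidence intervals; because variance-based
indices are sign-free, a signed Spearman correlation between each sampled
parameter and the output is reported alongside. Virtual populations draw
lognormal multiplicative perturbations with median equal to the base value
and coefficient of variation equal to the requested `cv`
(`sdlog = sqrt(log(1 + cv^2))`).

## The synthetic-data generator

No raw data are deposited with the source study (its datasets were
digitized from literature figures), so the package generates synthetic
observations with the statistical structure the calibration assumes:
model-predicted means at the six published study designs (doses, routes,
sampling schedules) under the proportional error model, truncated at zero.
The default `sigma_slope = 0.04` (20% proportional SD) is a stated choice
of plausible assay noise — the digitized data's actual noise level is
unknown. A green recovery test therefore establishes self-consistency
(generate, fit, recover under the package's own model), not agreement with
the original digitized datasets; published parameter values fitted to
those datasets are not reproducible at desk scale and are not claimed.

Within that stated world, one honest failure is documented rather than
patched: in the monkey plasma-LNP design (3 doses x 3 times), the
exocytosis rate `k_out_exo` lies on a flat likelihood ridge with
`k_in_endo` — a 35% shift in one is compensated by a 0.3% shift in the
other to within 1e-6 relative — so the 10% recovery criterion for that
single parameter is left red as non-identifiable. The same pair is well
identified in the human design, where the slower opsonin kinetics separate
the two processes.

## Limitations

* The reconstructed ODE system is faithful to the narrative but cannot be
  verified against the unavailable supplementary listing; structural
  switches preserve the alternative readings.
* Absolute RNP exposure in the liver cell is orders of magnitude below the
  published IC50s under every reading of the printed constants, so
  biomarker responses at clinical doses are qualitatively (dose-ordered)
  but not quantitatively comparable to the clinical data.
* No nucleus/DNA-cleavage or indel kinetics; no editing-fraction state;
  single-pore convection only; no multi-dose regimens; no covariate or
  Bayesian inference.
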