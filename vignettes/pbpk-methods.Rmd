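---
title: "Whole-body PBPK simulation of AT-RvD1 with a saliva compartment: models and methods"
author: "salivapk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK simulation of AT-RvD1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and motivation

Aspirin-triggered resolvin D1 (AT-RvD1) is a specialized pro-resolving
lipid mediator under study for Sjögren's-syndrome hyposalivation: it
restores salivary function in the NOD/ShiLtJ mouse model, and the question
of what plasma and, critically, *saliva* exposure a given intravenous dose
produces in mouse and human is a prerequisite for dose selection in future
in vivo and clinical work. No in vivo pharmacokinetic data for AT-RvD1
exist yet, so the package implements a predictive, physiologically based
pharmacokinetic (PBPK) pipeline: species physiology registries, a
mechanistic multi-organ ODE model with an explicit saliva compartment, IV
bolus dosing, virtual-population simulation, non-compartmental analysis
(NCA), and variation-factor local sensitivity analysis.

Everything here is prediction, not description of measured data. The
package is explicit about which inputs are literature values and which are
assumptions; every run manifest lists the assumptions in force.

## Model structure

The body is a graph of well-stirred compartments. Fifteen organs (lung,
heart, brain, kidney, liver, spleen, gut, muscle, skin, adipose, bone,
gonads, pancreas, salivary gland, rest-of-body) connect in parallel between
an arterial and a venous blood pool; the lung sits in series on the venous
return, bridging venous to arterial blood. State variables are drug
amounts (ng). Because no blood-cell partitioning is modeled, drug is
carried in plasma and every flow is a plasma flow,
`Q_plasma = Q_blood * (1 - hematocrit)`.

For a perfusion-limited organ the mass balance is

    dA_i/dt = Q_i * (C_art - C_i / K_i) - E_i

where `C_i = A_i / V_i` is the total tissue concentration, `K_i` the
tissue-to-plasma partition coefficient (so `C_i / K_i` is the emergent
plasma concentration), and `E_i` an elimination term present only in
eliminating organs. The venous pool collects the organ outflows; a
cumulative `eliminated` state closes the mass balance, and the integrator
is required to conserve `amount in system + eliminated = dose` (the suite
checks `< 1e-6` relative at every output time; in practice the `lsoda`
defaults hold it near 1e-14).

Organs can individually be switched to *permeability-limited* transport:
the organ splits into a vascular sub-compartment (volume
`V_i * f_vas,i * (1 - hct)`) exchanging with tissue through a
permeability-surface-area product `PS_i`, with the capillary surface area
given by the organ vascularization rule `SA = k * f_vas * V_organ`. The
default is perfusion-limited throughout because no permeability value for
AT-RvD1 has been published; see "The early-time venous transient" below
for the one place this choice is visible.

### Saliva

Saliva is a first-order satellite of the salivary gland:

    dA_sal/dt = k_sal * V_sal * (K_saliva * C_sg,plasma - C_sal)

with `k_sal = 10 /hr` (fast equilibration) and `K_saliva = fu_plasma` by
default, i.e. saliva equilibrates with *unbound* gland plasma drug. Both
are configurable. The flux is mirrored in the gland so mass is conserved.
This reproduces the qualitative observation that salivary kinetics track
plasma kinetics for lipophilic drugs; it deliberately does not model
secretion-flow physiology, pH trapping, or stimulated/unstimulated flow
differences.

## Partition coefficients

Tissue-to-plasma partition coefficients come from tissue composition:

    K_organ = f_water + K_lipid * f_lipid + K_protein * f_protein * fu_plasma

The unbound fraction scales the protein term only, as the rule is printed;
the alternative precedence (fu scaling the whole sum) is exposed as
`fu_scales_all` in `build_model()` for users who prefer it. The two
auxiliary coefficients are derived from the compound:

* `K_lipid = 10^logP` — the minimal octanol/water reading of
  "derived from the physicochemical properties". Override-able.
* `K_protein = (1/fu_plasma - 1) / f_protein,plasma` with plasma 6%
  protein by volume — chosen so that the plasma compartment's own binding
  is self-consistent with the declared unbound fraction. Override-able.

Tissue composition fractions (`f_water`, `f_lipid`, `f_protein`) and
vascular fractions `f_vas` are not measurable inputs for this compound's
species of interest; the shipped defaults are anchored on the standard
rodent fractional-volume tables (lipid = neutral + phospholipid). They are
flagged `source = "default"` in the fixtures and surface in every run
manifest as assumptions. With `logP = 3.22`, `K_lipid ~ 1660` makes
lipid-rich tissues (adipose, brain) strong sinks; the whole-body
steady-state volume of the default mouse model (~160 L/kg) therefore
exceeds the ~41.5 L/kg apparent volume the reference software predicted
with its proprietary partition regressions. Tissue concentration maxima
are consequently indicative only — the model's plasma-side calibration
(below) does not depend on them.

## Clearance

AT-RvD1 is metabolized by eicosanoid oxidoreductase (EOR), but published
kinetic constants and organ abundances are incomplete, so the default
clearance mode is *calibrated*: a total plasma clearance (ml/min/kg,
multiplied by the individual's body weight) allocated to liver and kidney
in proportion to their blood flows. Each organ share `CL_i` is converted
to an intrinsic clearance by the well-stirred inversion

    CLint_i = CL_i * Qp_i / (Qp_i - CL_i)

so that the organ's effective plasma clearance equals its share *exactly*
and the model's venous AUC0-inf equals `dose / CL` identically. A naive
linear rate on organ plasma concentration would fall short of the
calibrated total (by ~10% in the mouse) because perfusion limits organ
exposure; the inversion removes that bias. A share exceeding an organ's
plasma flow is physically undeliverable: `build_model()` then errors. The
adult-human case is the practical example — a total plasma clearance of
14.02 ml/min/kg exceeds the combined hepatorenal plasma flow
(~11.9 ml/min/kg at hematocrit 0.45), so the human pipeline allocates over
all systemic organs (`eliminating_organs = "systemic"`), which is also the
mechanistically plausible reading for an enzyme as widely expressed as EOR.

The *enzymatic* mode implements Michaelis-Menten elimination on unbound
organ plasma concentration scaled by per-organ EOR abundance; it exists
for mechanistic studies once Vmax/Km/abundance values are available, and
ships with no default values.

A calibrated clearance of zero is admitted and yields a closed,
mass-conserving system, used by the conservation tests.

## Dosing, integration, and the early-time venous transient

A single IV bolus places `dose_mg_per_kg * body_weight` (as ng) in the
venous pool at `t = 0`; the stiff-capable `lsoda` integrator (default
`rtol = 1e-10`, `atol = 1e-8`) produces dense output on a reporting grid,
by default 0 to 24 hr in 0.05-hr (3-min) steps — the resolution needed to
place an early Tmax on the grid.

The instantaneous bolus makes the `t = 0` venous sample an artifact: the
pool momentarily holds `dose / V_venous,plasma` (thousands of ng/ml in the
mouse) and washes out with time constant `V_venous,plasma / Q_plasma`
(~9 s). Two reporting conventions follow:

* **Cmax/Tmax** are computed from the first positive grid time onward
  (`exclude_time_zero = TRUE` in `pk_summary()`).
* **AUC quadrature** must either resolve the washout or exclude it. A grid
  that samples `t = 0` but steps straight to 0.05 hr inflates the first
  log-down trapezoid several-fold (the segment is far from
  mono-exponential at that step). When an accurate venous AUC is the goal
  — e.g. verifying `AUC = dose/CL` — simulate on a composite grid with
  5e-4-hr steps across the first 0.06 hr. The acceptance script does
  exactly this and recovers the calibrated clearance to 0.02%.

A second, subtler consequence of the bolus-into-pool idealization: under
perfusion-limited distribution the venous concentration *rebounds* — the
pool empties within seconds, then refills as the recirculating front
returns — and with this compound's large partition coefficients the
rebound maximum falls near 0.10 hr, the second grid point, with the first
two grid values within ~1% of each other. Under the endothelial-barrier
(permeability-limited) structure, which is how the reference software
actually computes trans-capillary transport, the first-pass organ
extraction is partial, the venous curve declines monotonically from the
first grid point, and Tmax = 0.05 hr robustly across four orders of
magnitude of the (unpublished) permeability. The package therefore uses
the barrier variant when the grid-resolved Tmax itself is the quantity of
interest, and documents that the perfusion-limited default places it one
grid step later.

## Non-compartmental analysis

`pk_summary()` assembles the standard IV-bolus parameter set. Internals
are ml/hr/ng; clearance is reported in ml/min/kg and volume of
distribution in L/kg.

* **Terminal slope**: log-linear regression over suffix windows of the
  positive concentrations after Tmax; the window maximizing the adjusted
  R-squared wins, ties within 1e-4 going to the longer window. Candidate
  windows must have at least 3 points *and span at least 20% of the
  post-Tmax interval*. The span constraint is a deliberate refinement: on
  densely sampled profiles an unconstrained search routinely lets a
  3-point window win by chance, so estimator variance *grows* with
  sampling density; with the constraint, ke RMSE falls monotonically as
  the grid densifies (property-tested) and sparse-profile behaviour is
  unchanged. Zero concentrations are excluded from log fits; profiles with
  fewer than 3 usable points, or a non-negative slope, raise errors rather
  than returning numbers.
* **AUC/AUMC**: linear-up/log-down trapezoid, with the exponential tail
  `C_last/ke` (AUC) and `C_last*t_last/ke + C_last/ke^2` (AUMC) when a
  terminal slope is available; `extrapolated_fraction` is always reported
  so heavy extrapolation is visible.
* **Identities**: `t1/2 = ln2/ke`, `CL = dose/AUC0-inf`, `Vd = CL/ke`,
  `MRT = AUMC/AUC` hold to 1e-9 relative by construction and are
  property-tested.

One published inconsistency deserves note: the reference analysis reports
a ~104.6-hr mouse (91.1-hr human) terminal half-life from curves simulated
only to 24 hr — implying roughly 85% of AUC0-inf was tail extrapolation.
The package reproduces that 24-hr-window analysis in `reproduce_paper()`
(and reports the extrapolated fraction), but anchors its own AUC0-inf
verification on long-horizon simulation where the terminal phase is
actually sampled.

## Virtual populations

* **Mouse**: body weight uniform on 12-30 g (a distribution is not
  specified in the source data; uniform is the conservative choice, and a
  truncated normal is available), physiologies by allometric scaling of
  the 27.5-g reference — volumes with exponent 1, flows with exponent
  0.75, the standard interspecies/intraspecies convention.
* **Human**: age uniform on 20-80 years, exactly equal sex split, body
  weight from a piecewise-linear weight-by-age-and-sex reference table
  rescaled so its population expectation is exactly the 80.35-kg adult
  reference, then the same allometric scaling. Organ-level age ontogeny is
  out of scope; age and sex act through body weight only (a documented
  limitation).

All sampling is seed-deterministic end to end. Because the calibrated
clearance and the dose are both per-kg, AUC is essentially
weight-invariant and the simulated NCA dispersions are small in *both*
species; the large human standard deviations in the reference table stem
from covariate machinery (organ-level variability, enzyme ontogeny) that
is not public and is not emulated. Population summaries report mean, SD
and 5th/95th percentiles per NCA parameter plus per-time concentration
percentile bands.

## Sensitivity analysis

For parameter `p`, output `y` (AUC0-inf or total body clearance
`dose/AUC0-inf`, each from a full simulate + NCA of the perturbed model)
and variation factor `f`:

    S_f = (y(f*p) / y(p) - 1) / (f - 1)

and the reported sensitivity is the mean of `S_f` over the factor set,
default `{0.1, 0.5, 0.9, 1.1, 2, 10}` — a 10-fold change in both
directions plus a small-perturbation pair whose mean approaches the
analytic elasticity (for clearance against AUC, `S -> -1`, verified to
0.02). Factors multiply the parameter value itself; for `logP` at `f = 10`
that means 3.22 to 32.2, which is physically aggressive but is exactly
what a multiplicative variation prescribes — interpret large-factor rows
accordingly. Perturbations that produce an unphysical model (hematocrit
reaching 1, clearance beyond deliverable plasma flow) fail that factor
only: the single-cell API raises a partial-result error unless
`allow_partial = TRUE`; the screen warns and averages the surviving
factors, recording `n_factors_used`.

The screen ranks |sensitivity| within each output with stable alphabetical
tie-breaks and is replicated at 0.1, 0.25 and 0.5 mg/kg; with calibrated
(linear) kinetics the ranking is provably dose-invariant, which doubles as
a consistency check. In the shipped human configuration the top influences
on plasma and saliva AUC are the calibrated clearance, logP and (for
saliva) the unbound fraction — qualitatively mirroring the published
screen — but this ranking depends on the default partition rules and is
reported, not asserted.

## Synthetic data

`generate_profile()` produces mono-/bi-exponential decays exactly (to
closed form) or with multiplicative lognormal noise of stated CV (mean
one, so concentrations stay positive; additive Gaussian is available but
not default), seed-deterministically; `recovery_suite()` wraps replicate
generation + NCA into bias/RMSE tables (200 replicates at CV 10% keep
median ke bias under 2%). These generators emulate clean dense simulated
output — not assay quantification limits, sparse clinical sampling,
below-LOQ censoring, or correlated residuals — so passing recovery tests
demonstrates estimator correctness on the stated error model, not
performance on real bioanalytical data.

## Numerical choices and degenerate inputs

* `lsoda` with `rtol = 1e-10`, `atol = 1e-8` (ng scale); solver failure
  carries the failing time. Reported concentrations are floored at zero
  (solver noise is bounded by the tolerances and checked in tests).
* Reporting grid 0.05 hr over 0-24 hr by default; composite grids for
  venous AUC verification as described above. Problem sizes in the test
  and acceptance runs (24-2400 hr horizons, 80-200 replicate recoveries,
  populations of 3-100) are chosen so each check exercises the property it
  names at comfortable numerical margins.
* Cmax/Tmax ties break to the earliest time; terminal-fit ties to the
  longer window; zero concentrations never enter log fits; all-zero
  profiles, zero doses, non-increasing grids, unknown species/organs and
  unknown config keys are hard errors rather than silent defaults.
* Blood-pool volumes (not printed anywhere) default to a 1:2
  arterial:venous split of species blood volume and scale with body
  weight.

## Known limitations

* Plasma-side calibration is exact, but tissue maxima inherit the
  composition-based partition defaults; treat organ Cmax values as
  indicative.
* Single IV bolus only; no oral/topical absorption, no multiple dosing,
  no metabolite tracking.
* Saliva coupling is an equilibration model, not secretion physiology.
* Human variability is body-weight-only; disease-state (Sjögren's)
  physiology is not modeled.
* Ionization (pKa) is carried as metadata but does not enter the
  partition rules; the sensitivity screen correctly reports it inert.
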