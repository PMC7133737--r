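# salivapk

Whole-body physiologically based pharmacokinetic (PBPK) simulation of
aspirin-triggered resolvin D1 (AT-RvD1) — a specialized pro-resolving lipid
mediator under study for Sjögren's-syndrome hyposalivation — in NOD/ShiLtJ
mice and adult humans, with an explicit saliva compartment. The package is
aimed at pharmacokineticists and drug-development researchers who need
predicted plasma, tissue and *saliva* exposure for intravenous AT-RvD1
dosing before in vivo data exist.

## What it implements

* **Species physiologies**: registries for the NOD/ShiLtJ mouse (27.5 g)
  and an 80.35-kg adult human — 15 organs plus arterial/venous blood pools
  and saliva — with allometric scaling (volumes ∝ BW, flows ∝ BW^0.75) and
  strict invariants (flow conservation, composition bounds).
* **Mechanistic model**: per-organ mass balance
  `dA_i/dt = Q_i (C_art − C_i/K_i) − E_i`, lung in series on the venous
  return, partition coefficients from tissue composition
  `K = f_water + K_lipid f_lipid + K_protein f_protein · fu`, with
  `K_lipid = 10^logP`; clearance either calibrated (total plasma clearance
  allocated to eliminating organs with an exact well-stirred inversion) or
  Michaelis–Menten via eicosanoid oxidoreductase; optional
  permeability-limited transport with `SA = k · f_vas · V_organ`; saliva as
  a first-order satellite of the salivary gland.
* **Analysis**: IV-bolus simulation (stiff `lsoda` integration, tidy CSV
  profiles), non-compartmental analysis (Cmax/Tmax, terminal slope by
  best-adjusted-R² log-linear regression, linear-up/log-down AUC/AUMC with
  tail extrapolation, CL, Vd, MRT), seed-deterministic virtual populations
  (mouse weight 12–30 g uniform; human age 20–80, equal sex), and
  variation-factor local sensitivity analysis with ranked screens.
* **Synthetic data**: exact/noisy exponential profile generators and an
  estimator bias/RMSE recovery harness, so the whole pipeline is testable
  without any external data.

## Worked example

A single 0.1 mg/kg IV bolus in the mouse model, clearance calibrated to
4.58 ml/min/kg:

```r
library(salivapk)

mouse <- get_species_physiology("mouse")
model <- build_model(mouse, load_compound("at_rvd1"),
                     clearance_spec("calibrated_total",
                                    total_plasma_clearance_ml_min_kg = 4.58))
sim <- simulate_pbpk(model, dose_event(0.1), sim_config())  # 0–24 hr, 3-min grid
pk_summary(get_profile(sim, "plasma"), dose_mg_per_kg = 0.1)
```

```
<nca_result> Cmax 7.788 ng/ml @ 0.1 hr | ke 0.01394 /hr (t1/2 49.73 hr, R2 0.9994, n 103)
  AUC0-inf 159.775 ng*hr/ml (51.1% extrapolated) | MRT 51.36 hr | CL 10.43 ml/min/kg | Vd 44.9 L/kg
```

Half the exposure here is tail extrapolation (the terminal half-life far
exceeds the 24-hr window — `extrapolated_fraction` makes that visible).
Simulating on a long composite grid that resolves both the venous mixing
transient and the terminal phase recovers the calibrated clearance
exactly:

```r
times <- c(seq(0, 0.06, by = 5e-4), seq(0.1, 24, by = 0.05), seq(24.5, 2400, by = 0.5))
sim2 <- simulate_pbpk(model, dose_event(0.1),
                      sim_config(t_end_hr = 2400, output_times_hr = times))
pk_summary(get_profile(sim2, "plasma"), 0.1)$auc_0_inf
#> [1] 363.8404           # = dose / (4.58 ml/min/kg), CL recovered to 0.02%
```

The end-to-end pipeline — 100-animal mouse and 100-subject human
populations, NCA summary tables, and the sensitivity screen at 0.1/0.25/0.5
mg/kg — runs in about two minutes:

```r
reproduce_paper("out/", seed = 1, n = 100)
read.csv("out/mouse_nca_summary.csv")
```

In the resulting screen, plasma AUC0-inf is most sensitive to the
calibrated clearance (S ≈ −0.93) and logP (S ≈ −0.71), and salivary
exposure additionally to the unbound fraction (S ≈ +1.0) — hematocrit,
adipose volume and pKa rank far behind.

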