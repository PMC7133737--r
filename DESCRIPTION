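Package: salivapk
Title: Whole-Body Physiologically Based Pharmacokinetic Simulation with a
    Saliva Compartment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic whole-body physiologically based pharmacokinetic
    (PBPK) simulation of the specialized pro-resolving lipid mediator
    aspirin-triggered resolvin D1 (AT-RvD1) in NOD/ShiLtJ mice and adult
    humans, with an explicit saliva compartment for the study of salivary
    drug disposition. Provides species physiology registries with
    allometric scaling, tissue-to-plasma partition coefficient prediction
    from tissue composition, intravenous bolus dosing, stiff ODE
    integration of the multi-organ mass-balance system, virtual-population
    simulation, non-compartmental analysis (NCA), and variation-factor
    local sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
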