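{
  "name": "AT-RvD1",
  "description": "Aspirin-triggered resolvin D1 (17R epimer of resolvin D1). Physicochemical values from quantitative structure-property calculations; fu_plasma is an assumed value (never measured) and is flagged as such.",
  "molecular_weight_g_mol": 376.493,
  "formula": "C22H32O5",
  "logP": 3.22,
  "pKa": 4.47,
  "solubility_pH74_mg_ml": 3.1,
  "fu_plasma": 0.05,
  "fu_plasma_assumed": true,
  "binding_protein": "albumin"
}
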