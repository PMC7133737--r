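{
  "compound": {"fixture": "at_rvd1"},
  "physiology": {"species": "mouse"},
  "clearance": {"mode": "calibrated_total", "total_plasma_clearance_ml_min_kg": 4.58},
  "dose": {"amount_mg_per_kg": 0.1, "time_hr": 0},
  "simulation": {"t_end_hr": 24, "grid_step_hr": 0.05},
  "population": {"species": "mouse", "n": 100},
  "seed": 1
}
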