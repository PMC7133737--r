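{
  "species": "human_adult",
  "description": "Adult human reference physiology (30-year-old, 80.35 kg, BMI 25.22). Named-organ volumes, blood flows, body weight, hematocrit and saliva volume are literature values; organs marked source='default' carry package default values and are override-able assumptions.",
  "body_weight_kg": 80.35,
  "bmi_kg_m2": 25.22,
  "hematocrit": 0.45,
  "saliva_volume_ml": 6.6,
  "arterial_volume_ml": 1740,
  "venous_volume_ml": 3480,
  "organs": [
    {
      "name": "lung",
      "volume_ml": 1210.12,
      "blood_flow_ml_min": 6250,
      "f_vas": 0.26,
      "f_water": 0.811,
      "f_lipid": 0.015,
      "f_protein": 0.14,
      "eor_abundance": 0.3,
      "source": "printed"
    },
    {
      "name": "heart",
      "volume_ml": 416.52,
      "blood_flow_ml_min": 260,
      "f_vas": 0.1,
      "f_water": 0.758,
      "f_lipid": 0.028,
      "f_protein": 0.16,
      "eor_abundance": 0,
      "source": "printed"
    },
    {
      "name": "brain",
      "volume_ml": 1509.06,
      "blood_flow_ml_min": 780,
      "f_vas": 0.03,
      "f_water": 0.753,
      "f_lipid": 0.092,
      "f_protein": 0.08,
      "eor_abundance": 0,
      "source": "printed"
    },
    {
      "name": "kidney",
      "volume_ml": 437.33,
      "blood_flow_ml_min": 1320,
      "f_vas": 0.16,
      "f_water": 0.783,
      "f_lipid": 0.037,
      "f_protein": 0.16,
      "eor_abundance": 0.8,
      "source": "printed"
    },
    {
      "name": "liver",
      "volume_ml": 2366.5,
      "blood_flow_ml_min": 420,
      "f_vas": 0.21,
      "f_water": 0.751,
      "f_lipid": 0.06,
      "f_protein": 0.18,
      "eor_abundance": 1,
      "source": "printed"
    },
    {
      "name": "spleen",
      "volume_ml": 206.38,
      "blood_flow_ml_min": 170,
      "f_vas": 0.22,
      "f_water": 0.788,
      "f_lipid": 0.04,
      "f_protein": 0.16,
      "eor_abundance": 0,
      "source": "printed"
    },
    {
      "name": "gut",
      "volume_ml": 1100,
      "blood_flow_ml_min": 1100,
      "f_vas": 0.08,
      "f_water": 0.738,
      "f_lipid": 0.043,
      "f_protein": 0.15,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "muscle",
      "volume_ml": 29200,
      "blood_flow_ml_min": 750,
      "f_vas": 0.04,
      "f_water": 0.76,
      "f_lipid": 0.031,
      "f_protein": 0.18,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "skin",
      "volume_ml": 3408,
      "blood_flow_ml_min": 300,
      "f_vas": 0.05,
      "f_water": 0.651,
      "f_lipid": 0.04,
      "f_protein": 0.25,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "adipose",
      "volume_ml": 14500,
      "blood_flow_ml_min": 260,
      "f_vas": 0.05,
      "f_water": 0.14,
      "f_lipid": 0.85,
      "f_protein": 0.01,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "bone",
      "volume_ml": 10165,
      "blood_flow_ml_min": 250,
      "f_vas": 0.04,
      "f_water": 0.417,
      "f_lipid": 0.019,
      "f_protein": 0.2,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "gonads",
      "volume_ml": 35,
      "blood_flow_ml_min": 3,
      "f_vas": 0.07,
      "f_water": 0.8,
      "f_lipid": 0.02,
      "f_protein": 0.14,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "pancreas",
      "volume_ml": 104,
      "blood_flow_ml_min": 60,
      "f_vas": 0.09,
      "f_water": 0.664,
      "f_lipid": 0.049,
      "f_protein": 0.16,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "salivary_gland",
      "volume_ml": 85,
      "blood_flow_ml_min": 50,
      "f_vas": 0.08,
      "f_water": 0.75,
      "f_lipid": 0.03,
      "f_protein": 0.16,
      "eor_abundance": 0,
      "source": "default"
    },
    {
      "name": "rest_of_body",
      "volume_ml": 5500,
      "blood_flow_ml_min": 527,
      "f_vas": 0.05,
      "f_water": 0.75,
      "f_lipid": 0.04,
      "f_protein": 0.15,
      "eor_abundance": 0,
      "source": "default"
    }
  ]
}
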