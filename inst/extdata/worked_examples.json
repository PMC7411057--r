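{
  "comment": "Published setup constants and per-material measured scattering signals used by reproduce_worked_examples(); EPDM's normalized entries are carried but excluded from the exactness comparison (they are not reproducible from the rounded per-bin signals).",
  "geometry": {"d_s_g2_m": 0.571, "p_g2_um": 10.0, "design_energy_keV": 45.0},
  "bins_keV": {"low": [23.0, 64.0], "high": [64.0, 120.0]},
  "weighted_energy_keV": {"low": 43.0, "high": 80.9},
  "lambda_w_A": {"low": 0.29, "high": 0.15},
  "xi_w_um": {"low": 1.65, "high": 0.88},
  "neg_log_D": {
    "CR-L": {"low": 1.07, "high": 0.36},
    "EPDM": {"low": 1.05, "high": 0.37},
    "PU":   {"low": 0.50, "high": 0.13},
    "K1":   {"low": 0.65, "high": 0.24},
    "S60":  {"low": 2.05, "high": 0.93}
  },
  "normalized_printed": {
    "CR-L": {"low": 12.72, "high": 16.00},
    "EPDM": {"low": 12.60, "high": 16.00},
    "PU":   {"low": 5.95,  "high": 5.78},
    "K1":   {"low": 7.73,  "high": 10.67},
    "S60":  {"low": 24.38, "high": 41.33}
  },
  "excluded_from_comparison": ["EPDM"]
}
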