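{
  "schema_version": 1,
  "protein": "D. mawNgb*",
  "temperature_K": 293.15,
  "units": {
    "k_m2": "M^-1 s^-1",
    "k_m3": "M^-1 s^-1",
    "default": "s^-1"
  },
  "rates": {
    "k_m1": 3.0e7,
    "k_2": 8.5e7,
    "k_m2": 6.6e8,
    "k_3": 4.2e4,
    "k_m3": 8.1e5,
    "k_b": 670,
    "k_mb": 2.6,
    "k_c": 4.0e7,
    "k_mc": 4.3e7,
    "k_d": 6.0e6,
    "k_md": 2.9e5,
    "k_e": 3.6e4,
    "k_me": 3.1e3,
    "k_f": 1.4e5,
    "k_mf": 2.05e4
  },
  "delta_g_kcal": {
    "k_m1": 6.9, "k_2": 6.6, "k_m2": 5.3, "k_3": 11, "k_m3": 8,
    "k_b": 13, "k_mb": 16, "k_c": 7, "k_mc": 6.7, "k_d": 8,
    "k_md": 9.5, "k_e": 11, "k_me": 12, "k_f": 9.9, "k_mf": 12
  },
  "delta_g_err_kcal": {
    "k_m1": 0.1, "k_2": 0.7, "k_m2": 0.9, "k_3": 9, "k_m3": 1,
    "k_b": 3, "k_mb": 3, "k_c": 2, "k_mc": 0.8, "k_d": 1,
    "k_md": 0.1, "k_e": 2, "k_me": 5, "k_f": 0.5, "k_mf": 17
  }
}
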