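{
  "schema_version": 1,
  "protein": "C. aceNgb*",
  "temperature_K": 293.15,
  "units": {
    "k_m2": "M^-1 s^-1",
    "k_m3": "M^-1 s^-1",
    "default": "s^-1"
  },
  "rates": {
    "k_m1": 2.0e7,
    "k_2": 5.6e7,
    "k_m2": 8.3e8,
    "k_3": 1.59e4,
    "k_m3": 4.4e6,
    "k_b": 2900,
    "k_mb": 6.0,
    "k_c": 8.8e6,
    "k_mc": 1.0e6,
    "k_d": 3.0e6,
    "k_md": 1.4e6,
    "k_e": 4.2e4,
    "k_me": 2.6e3,
    "k_f": 1.4e5,
    "k_mf": 1.7e4
  },
  "delta_g_kcal": {
    "k_m1": 7.0, "k_2": 6.8, "k_m2": 5.4, "k_3": 11, "k_m3": 8,
    "k_b": 12, "k_mb": 16, "k_c": 7.6, "k_mc": 8.8, "k_d": 8.2,
    "k_md": 8.7, "k_e": 10.5, "k_me": 12, "k_f": 10, "k_mf": 11.4
  },
  "delta_g_err_kcal": {
    "k_m1": 0.7, "k_2": 0.2, "k_m2": 0.9, "k_3": 3, "k_m3": 5,
    "k_b": 1, "k_mb": 6, "k_c": 0.7, "k_mc": 0.9, "k_d": 0.8,
    "k_md": 0.1, "k_e": 0.9, "k_me": 6, "k_f": 4, "k_mf": 10
  }
}
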