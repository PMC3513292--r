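{
  "schema_version": 1,
  "protein": "human Ngb",
  "temperature_K": 293.15,
  "units": {
    "k_m2": "M^-1 s^-1",
    "k_m3": "M^-1 s^-1",
    "default": "s^-1"
  },
  "rates": {
    "k_m1": 1.7e7,
    "k_2": 1.05e8,
    "k_m2": 5.5e8,
    "k_3": 8.5e2,
    "k_m3": 2.9e6,
    "k_b": 545,
    "k_mb": 0.42,
    "k_c": 5.4e7,
    "k_mc": 1.28e8,
    "k_d": 7.02e7,
    "k_md": 3.49e7,
    "k_e": 1.2e7,
    "k_me": 5.5e5,
    "k_f": 8.5e4,
    "k_mf": 3.3e3
  },
  "delta_g_kcal": {
    "k_m1": 7.4, "k_2": 6.0, "k_m2": 5, "k_3": 13, "k_m3": 9,
    "k_b": 13, "k_mb": 16, "k_c": 7, "k_mc": 6, "k_d": 6.6,
    "k_md": 7.0, "k_e": 8, "k_me": 9, "k_f": 10, "k_mf": 12
  },
  "delta_g_err_kcal": {
    "k_m1": 0.4, "k_2": 0.4, "k_m2": 1, "k_3": 5, "k_m3": 3,
    "k_b": 2, "k_mb": 4, "k_c": 1, "k_mc": 0.8, "k_d": 0.9,
    "k_md": 0.1, "k_e": 1, "k_me": 5, "k_f": 2, "k_mf": 5
  }
}
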