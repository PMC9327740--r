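{
  "init_within_intervention": {
    "base": 0.9942,
    "low": 0.8948,
    "high": 1.0937
  },
  "init_below_intervention": {
    "base": 0.0029,
    "low": 0.0026,
    "high": 0.0032
  },
  "init_above_intervention": {
    "base": 0.0029,
    "low": 0.0026,
    "high": 0.0032
  },
  "init_within_control": {
    "base": 0.9855,
    "low": 0.8869,
    "high": 1.084
  },
  "init_below_control": {
    "base": 0.0058,
    "low": 0.0052,
    "high": 0.0063
  },
  "init_above_control": {
    "base": 0.0087,
    "low": 0.0079,
    "high": 0.0096
  },
  "p_within_to_below_intervention": {
    "base": 0.0225,
    "low": 0.0203,
    "high": 0.0248
  },
  "p_within_to_above_intervention": {
    "base": 0.0191,
    "low": 0.0172,
    "high": 0.021
  },
  "p_below_to_within_intervention": {
    "base": 0.4263,
    "low": 0.3837,
    "high": 0.4689
  },
  "p_above_to_within_intervention": {
    "base": 0.5712,
    "low": 0.5141,
    "high": 0.6283
  },
  "p_within_to_below_control": {
    "base": 0.0741,
    "low": 0.0667,
    "high": 0.0815
  },
  "p_within_to_above_control": {
    "base": 0.0383,
    "low": 0.0345,
    "high": 0.0421
  },
  "p_below_to_within_control": {
    "base": 0.1589,
    "low": 0.143,
    "high": 0.1748
  },
  "p_above_to_within_control": {
    "base": 0.291,
    "low": 0.2619,
    "high": 0.3201
  },
  "p_above_to_bleeding": {
    "base": 0.0115,
    "low": 0.0104,
    "high": 0.0127
  },
  "p_below_to_te": {
    "base": 0.0023,
    "low": 0.0021,
    "high": 0.0025
  },
  "p_te_to_bleeding": {
    "base": 0.00228,
    "low": 0.00205,
    "high": 0.00251
  },
  "p_te_to_reoperation": {
    "base": 0.00033,
    "low": 0.0003,
    "high": 0.00037
  },
  "p_te_to_death": {
    "base": 0.00374,
    "low": 0.00337,
    "high": 0.00412
  },
  "p_te_to_te": {
    "base": 0.08825,
    "low": 0.07942,
    "high": 0.09707
  },
  "p_bleeding_to_te": {
    "base": 0.00059,
    "low": 0.00053,
    "high": 0.00064
  },
  "p_bleeding_to_reoperation": {
    "base": 0.00033,
    "low": 0.0003,
    "high": 0.00037
  },
  "p_bleeding_to_death": {
    "base": 0.01078,
    "low": 0.00971,
    "high": 0.01186
  },
  "p_bleeding_to_bleeding": {
    "base": 0.02049,
    "low": 0.01844,
    "high": 0.02254
  },
  "p_reop_to_te": {
    "base": 0.00014,
    "low": 0.00012,
    "high": 0.00015
  },
  "p_reop_to_bleeding": {
    "base": 0.00028,
    "low": 0.00025,
    "high": 0.00031
  },
  "p_reop_to_death": {
    "base": 0.00035,
    "low": 0.00031,
    "high": 0.00038
  },
  "p_reop_to_reop": {
    "base": 0.00033,
    "low": 0.0003,
    "high": 0.00037
  },
  "p_recovery_to_te": {
    "base": 0.00059,
    "low": 0.00025,
    "high": 0.00109
  },
  "p_recovery_to_bleeding": {
    "base": 0.00228,
    "low": 0.00109,
    "high": 0.00532
  },
  "p_recovery_to_reoperation": {
    "base": 0.00033,
    "low": 0.00017,
    "high": 0.00075
  },
  "p_recovery_to_death": {
    "base": 0.00147,
    "low": 0.00131,
    "high": 0.00163
  },
  "rr_death_major_te": {
    "base": 2.25,
    "low": 1.75,
    "high": 2.75
  },
  "rr_death_major_bleeding": {
    "base": 1.5,
    "low": 1,
    "high": 2
  },
  "u_within_range": {
    "base": 0.987,
    "low": 0.967,
    "high": 0.998
  },
  "u_bleeding": {
    "base": 0.54,
    "low": 0.44,
    "high": 0.74
  },
  "u_te": {
    "base": 0.45,
    "low": 0.35,
    "high": 0.55
  },
  "u_reoperation": {
    "base": 0.45,
    "low": 0.35,
    "high": 0.75
  },
  "u_recovery": {
    "base": 0.668,
    "low": 0.61,
    "high": 0.76
  },
  "c_bleeding": {
    "base": 2777.78,
    "low": 2500,
    "high": 3055.56
  },
  "c_te": {
    "base": 2314.81,
    "low": 2083.33,
    "high": 2546.3
  },
  "c_reoperation": {
    "base": 16203.7,
    "low": 14583.33,
    "high": 17824.07
  },
  "discount_rate_cost": {
    "base": 0.035,
    "low": 0.02,
    "high": 0.06
  },
  "discount_rate_qaly": {
    "base": 0.035,
    "low": 0.02,
    "high": 0.06
  },
  "settings": {
    "cycle_length_months": 1,
    "horizon_cycles": 540,
    "half_cycle_correction": true,
    "cost_timing": "per_cycle",
    "inr_range_low": 2.5,
    "inr_range_high": 3.5
  }
}
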