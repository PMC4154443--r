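{
  "seed": 1,
  "field_diameter_mm": 0.243,
  "section_thickness_nm": 80,
  "n_sections": 401,
  "ipl_top_z": 60,
  "ipl_bottom_z": 360,
  "census": {
    "AII": 39,
    "RodBC": 104,
    "CBb3": 40,
    "CBb4w": 35,
    "CBb5w": 35,
    "CBb4-5i": 30,
    "CBb5-6i": 33,
    "CBb6": 20,
    "CBb7": 7,
    "CBa1": 30,
    "CBa2": 30,
    "CBa3": 30,
    "CBa4": 30,
    "CBa5": 30,
    "CBa6": 30,
    "TH1": 4,
    "AI": 8,
    "gammaAC": 30,
    "GAC": 20,
    "OFF-alpha-GC": 1,
    "OFF-delta-GC": 2
  },
  "aii_density_mm2": 841,
  "jitter_frac": 0.1,
  "arboreal_span_um": 70,
  "lobule_reach_um": 15,
  "rod_input_field_um": 60,
  "rodbc_terminal_span_um": 25,
  "ribbons_per_rodbc_mean": 31,
  "ribbons_per_rodbc_sd": 3.9,
  "aii_ribbon_intake_mean": 75.6,
  "aii_ribbon_intake_sd": 3,
  "n_gj_homo": 525,
  "n_gj_hetero": 172,
  "gj_homo_mean_nm": 267,
  "gj_homo_sd_nm": 95,
  "gj_hetero_mean_nm": 238,
  "gj_hetero_sd_nm": 95,
  "gj_trunc_nm": [50, 800],
  "cbb7_ribbons_range": [1, 3],
  "cbb7_gj_range": [2, 7],
  "offbc_ribbons_range": [2, 5],
  "ac_on_per_aii_range": [40, 60],
  "ac_off_per_aii_range": [18, 25],
  "th1_per_aii_range": [1, 3],
  "out_bc_per_aii_range": [3, 6],
  "out_ac_per_aii_range": [5, 10],
  "n_offgc_synapses": 23,
  "n_offgc_aii": 12,
  "n_gc_touches": 11,
  "n_ai_adherens": 12,
  "syn_diameter_mean_nm": 250,
  "syn_diameter_sd_nm": 60,
  "ratio_on_ac_to_rodbc": 8,
  "ratio_th1_to_coupling": 0.333333333333333,
  "ratio_coupling_homo_hetero": 7
}
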