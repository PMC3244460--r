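{
  "diffusion": {
    "D": 50,
    "delta": 20,
    "dt": 1,
    "p_move": 0.5,
    "c": 8,
    "dims": 2,
    "N_max": 1024,
    "normal_fallback": true
  },
  "rates": {
    "k_MI_max": 0.1,
    "K_P": 4000,
    "h_P": 4,
    "k_MR_basal": 0.005,
    "fold_f": 10,
    "K_B": 500,
    "h_B": 2,
    "k_tl": 0.02,
    "d_MI": 0.0005,
    "d_MR": 0.0005,
    "d_PR": 0.0002,
    "k_sec": 0.25,
    "k_on": 1e-05,
    "k_off": 0.0001,
    "F0": 2000
  },
  "culture": {
    "lattice_shape": [40, 40],
    "n_cells": 200,
    "moi": 1,
    "early_responder_fraction": 0.01,
    "pr_baseline": 1000,
    "pr_elevated": 20000,
    "pr_distribution": "two_point",
    "t_end": 36000,
    "record_dt": 600
  },
  "run": {
    "seed": 1,
    "out_dir": "ifnabm_out",
    "log_level": "info"
  }
}
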