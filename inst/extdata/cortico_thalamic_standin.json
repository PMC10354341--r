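{
  "model": "cortico_thalamic_standin",
  "description": "Synthetic stand-in parameter registry for the delayed seven-population cortico-thalamic neural mass model (tanh rate coupling). Not transcribed from any published supplementary material; tuned so the resting output shows an alpha-band resonance from the delayed thalamocortical loop and a gamma-band resonance from the fast superficial cortical pair, with healthy/pathological regimes encoded in the driving-noise variances.",
  "dynamics": {
    "tau_v": 0.005,
    "tau_w": 0.02,
    "tau_e": 0.01,
    "tau_i": 0.02,
    "tau_t": 0.01,
    "tau_r": 0.01,
    "delay": 0.052,
    "n_vv": 2.52,
    "n_vw": 2.52,
    "n_wv": 6.6,
    "n_ww": 6.6,
    "n_vt": 0.3,
    "n_ee": 1.2,
    "n_ei": 1.5,
    "n_et": 0.56,
    "n_ev": 0.15,
    "n_ie": 2.0,
    "n_te": 0.56,
    "n_tr": 0.6,
    "n_ti": 0.5,
    "n_it": 0.8,
    "n_re": 0.4,
    "n_rt": 0.3
  },
  "input_couplings": [
    0.18,
    0.18,
    0.14,
    0.14
  ],
  "observation_weights": [
    0.7,
    1.5
  ],
  "noise_variance": {
    "pathological": [
      1e-07,
      1e-07
    ],
    "healthy": [
      2.5e-08,
      3.6e-07
    ]
  }
}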