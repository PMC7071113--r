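{
  "title": "macx pipeline report",
  "required": [
    "selection",
    "wavelet_conditioning",
    "retained_bands",
    "rho_raw",
    "rho_conditioned",
    "algorithm",
    "snr_before",
    "snr_after",
    "snr_delta",
    "n_beats",
    "n_samples",
    "rate_hz",
    "config_hash",
    "versions",
    "timestamp"
  ]
}
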