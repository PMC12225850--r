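{
  "format": "strat-scheme",
  "name": "twentyeight_combined_synthetic",
  "tg_range": [0, 400],
  "tg_breaks": [50, 100, 150, 200, 300],
  "nonhdl_breaks_per_tg": [
    [100, 130, 160],
    [100, 130, 160, 190],
    [100, 130, 160, 190],
    [100, 130, 160, 190],
    [100, 130, 160, 190],
    [130, 160, 190]
  ]
}
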