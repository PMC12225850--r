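{
  "format": "strat-scheme",
  "name": "twelve_tg_synthetic",
  "tg_range": [0, 400],
  "tg_breaks": [25, 50, 75, 100, 125, 150, 175, 200, 250, 300, 350],
  "nonhdl_breaks_per_tg": [
    [],
    [],
    [],
    [],
    [],
    [],
    [],
    [],
    [],
    [],
    [],
    []
  ]
}
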