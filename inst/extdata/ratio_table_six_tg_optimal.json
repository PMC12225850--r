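{
  "format": "ratio-table",
  "scheme": {
    "name": "six_tg",
    "tg_range": [0, 400],
    "tg_breaks": [50, 100, 150, 200, 300],
    "nonhdl_breaks_per_tg": [
      [],
      [],
      [],
      [],
      [],
      []
    ]
  },
  "statistic": "optimal",
  "cells": [
    {
      "tg_lo": 0,
      "tg_hi": 50,
      "nonhdl_lo": 0,
      "nonhdl_hi": null,
      "af": "3.2",
      "n": 1140,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 50,
      "tg_hi": 100,
      "nonhdl_lo": 0,
      "nonhdl_hi": null,
      "af": "4.6",
      "n": 4648,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 100,
      "tg_hi": 150,
      "nonhdl_lo": 0,
      "nonhdl_hi": null,
      "af": "5.6",
      "n": 3127,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 150,
      "tg_hi": 200,
      "nonhdl_lo": 0,
      "nonhdl_hi": null,
      "af": "5.9",
      "n": 1523,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 200,
      "tg_hi": 300,
      "nonhdl_lo": 0,
      "nonhdl_hi": null,
      "af": "6.3",
      "n": 6132,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 300,
      "tg_hi": 400,
      "nonhdl_lo": 0,
      "nonhdl_hi": null,
      "af": "6.4",
      "n": 1752,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    }
  ]
}
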