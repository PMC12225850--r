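{
  "format": "ratio-table",
  "scheme": {
    "name": "twelve_combined",
    "tg_range": [0, 400],
    "tg_breaks": [50, 100, 150, 200, 300],
    "nonhdl_breaks_per_tg": [
      130,
      130,
      130,
      130,
      130,
      130
    ]
  },
  "statistic": "optimal",
  "cells": [
    {
      "tg_lo": 0,
      "tg_hi": 50,
      "nonhdl_lo": 0,
      "nonhdl_hi": 130,
      "af": "3.9",
      "n": 949,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 0,
      "tg_hi": 50,
      "nonhdl_lo": 130,
      "nonhdl_hi": null,
      "af": "2.9",
      "n": 191,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 50,
      "tg_hi": 100,
      "nonhdl_lo": 0,
      "nonhdl_hi": 130,
      "af": "4.8",
      "n": 2945,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 50,
      "tg_hi": 100,
      "nonhdl_lo": 130,
      "nonhdl_hi": null,
      "af": "4.5",
      "n": 1703,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 100,
      "tg_hi": 150,
      "nonhdl_lo": 0,
      "nonhdl_hi": 130,
      "af": "6.1",
      "n": 1211,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 100,
      "tg_hi": 150,
      "nonhdl_lo": 130,
      "nonhdl_hi": null,
      "af": "5.2",
      "n": 1916,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 150,
      "tg_hi": 200,
      "nonhdl_lo": 0,
      "nonhdl_hi": 130,
      "af": "6.4",
      "n": 400,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 150,
      "tg_hi": 200,
      "nonhdl_lo": 130,
      "nonhdl_hi": null,
      "af": "5.9",
      "n": 1123,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 200,
      "tg_hi": 300,
      "nonhdl_lo": 0,
      "nonhdl_hi": 130,
      "af": "6.8",
      "n": 1217,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 200,
      "tg_hi": 300,
      "nonhdl_lo": 130,
      "nonhdl_hi": null,
      "af": "6.1",
      "n": 4915,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 300,
      "tg_hi": 400,
      "nonhdl_lo": 0,
      "nonhdl_hi": 130,
      "af": "8.0",
      "n": 221,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    },
    {
      "tg_lo": 300,
      "tg_hi": 400,
      "nonhdl_lo": 130,
      "nonhdl_hi": null,
      "af": "6.4",
      "n": 1531,
      "ci_lo": null,
      "ci_hi": null,
      "acl": null,
      "tie": null
    }
  ]
}
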