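{
  "media": [
    {
      "name": "dmso",
      "dH_solv_proton": -1102.5,
      "dH_solv_electron": -85.0,
      "dH_solv_hatom": 4.0,
      "provenance": "synthetic example override for documentation/tests"
    }
  ]
}
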