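{
  "vertices": ["bcd", "BCD", "hb", "HB", "KNI", "TLL"],
  "activations": [
    {
      "source": "bcd",
      "target": "BCD"
    },
    {
      "source": "hb",
      "target": "HB"
    },
    {
      "source": "BCD",
      "target": "HB"
    },
    {
      "source": "BCD",
      "target": "KNI"
    }
  ],
  "repressions": [
    {
      "source": "HB",
      "target": "KNI"
    },
    {
      "source": "KNI",
      "target": "HB"
    },
    {
      "source": "TLL",
      "target": "KNI"
    }
  ],
  "annotations": {
    "bcd": {
      "is_mrna": true
    },
    "BCD": {
      "constant_input": true
    },
    "hb": {
      "is_mrna": true
    },
    "TLL": {
      "constant_input": true
    }
  }
}
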