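{
  "vertices": ["A", "B", "R"],
  "activations": [
    {
      "source": "A",
      "target": "B"
    }
  ],
  "repressions": [
    {
      "source": "R",
      "target": "B"
    }
  ],
  "annotations": []
}
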