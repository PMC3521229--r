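{
  "species": {"X": 10},
  "reactions": [
    {"reactants": {}, "products": {"X": 1}, "rate": 2.0},
    {"reactants": {"X": 1}, "products": {}, "rate": 0.2}
  ],
  "horizon": 20.0
}
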