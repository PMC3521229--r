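{
  "species": {"A": 1, "B": 0, "C": 0},
  "reactions": [
    {"reactants": {"A": 1}, "products": {"B": 1}, "rate": 1.0},
    {"reactants": {"A": 1}, "products": {"C": 1}, "rate": 1.0}
  ],
  "horizon": 10.0
}
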