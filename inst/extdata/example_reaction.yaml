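# Example reaction definition: ammonia synthesis.
reaction:
  name: "N2 + 3 H2 <=> 2 NH3"
  reactants: {N2: 1, H2: 3}
  products: {NH3: 2}
  bonds:
    N2: {"N#N": 1}
    H2: {"H-H": 1}
    NH3: {"N-H": 3}
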