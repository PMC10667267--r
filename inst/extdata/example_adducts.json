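{
  "[M+Cl]-": { "delta": { "Cl": 1 }, "charge": -1 },
  "[M-2H]2-": { "delta": { "H": -2 }, "charge": -2 }
}
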