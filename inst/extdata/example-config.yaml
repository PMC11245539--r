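# Example override configuration (merged over the package defaults).
# Shows the canonical YAML dialect: any subset of keys may be given;
# unknown keys are rejected with their key path.
sim:
  dt: 1
stimulus:
  rate: 30
  duration: 100
network:
  columns: [CS1, CS2]
  projection_sparsity: 0.1
plasticity:
  alpha_pfc: 1
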