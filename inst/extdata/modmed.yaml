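# Single-group moderated mediation (W moderates the a path), via the
# built-in preset; args override its defaults.
model:
  preset: modmed
  args:
    a.w0: 0.5
    a.mod: 0.3
    b: 0.4
    c.w0: 0.2
    n_per_cell: 25
monte_carlo:
  nRep: 1000
  seed: 777
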