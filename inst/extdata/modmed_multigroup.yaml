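# Multigroup moderated mediation: moderator W as grouping variable,
# shared b, heteroskedastic treatment variances (x 1.5).
model:
  preset: modmed_multigroup
  args:
    a.w0: 0.5
    a.w1: 0.8
    b: 0.4
    c: 0.2
    var_ratio: 1.5
    n_per_group: 50
monte_carlo:
  nRep: 1000
  seed: 12345
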