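# Single-group simple mediation: M ~ a*X, Y ~ b*M + c*X, standardized
# slopes (residual variances solved so total variances equal 1).
design:
  factors: [X]
  n_per_cell: 50
model:
  endogenous: [M, Y]
  meanstructure: false
  groups:
    g1:
      kappa:
        M: {X: a}
        Y: {X: c}
      beta:
        Y: {M: b}
      psi:
        M: psi.M
        Y: psi.Y
  population:
    a: 0.5
    b: 0.4
    c: 0.2
    psi.M: auto
    psi.Y: auto
  defined:
    - "ab := a*b"
    - "total := c + a*b"
monte_carlo:
  nRep: 1000
  seed: 12345
  alpha: 0.05
  methods: [delta, mcci]
  mcci_draws: 20000
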