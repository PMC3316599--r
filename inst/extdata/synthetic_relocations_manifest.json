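{
  "config": {
    "beta": 2.5,
    "eps": 0.12,
    "L": 250,
    "n": 400,
    "kind": "analytic"
  },
  "seed": 20260926,
  "package": "terriforage",
  "version": "0.1.0",
  "convention": "K1=1/(2*D*rho^2); K2=1/(4*D*rho); beta=v*L/D; D=F*a^2/2; eps^2=K_b/lambda",
  "timestamp": "2026-09-26T18:08:54+0000"
}
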