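# Example experiment configuration for the command-line front end:
#   hybridcast experiment --config lorenz_hybrid.yaml --out-dir results
# Fields not listed fall back to the lorenz63 preset (500 training samples,
# noise variance 4, horizon 20).
system: lorenz63
method: hybrid
uncertainty: 0.8
n_realizations: 25
seed: 1
embedding:
  d: 9
  tau: 1
  kappa: 20
replace: [y]
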