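payoff:
  type: payoff_spec
  benefit_mode: linear
  b: 1
  c: 1
  alpha: 2
environment:
  type: markov_env
  mu: 1
  sigma_E: 1
  lam: 0.9
measurement:
  type: measurement_model
  sigma_m: 1
# Optional: replace `environment` with a static prior block, e.g.
# prior:
#   type: gaussian_prior
#   mu: 1
#   sigma_E: 1
# or a bimodal mixture:
# prior:
#   type: mixture_prior
#   weights: [0.5, 0.5]
#   means: [-1.0, 1.0]
#   sds: [0.2, 0.2]
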