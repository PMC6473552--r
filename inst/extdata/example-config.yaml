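# Example pipeline configuration for the two-treatment / two-biomarker
# illustration (scaled-down replication counts for a quick run).
# Note: quote the "n" keys — bare `n:` is YAML 1.1 shorthand for false
# (the CLI repairs it either way).
K: 2
L: 2
seed: 1
phase2:
  "n": 400
  prevalence: [0.3, 0.3]
  # canonical order: alpha, beta1, beta2, gamma1, gamma2,
  #                  delta11, delta12, delta21, delta22
  theta: [-0.356, -0.213, 0.240, 1.0, 1.0, -0.182, 0.240, 0.527, -0.586]
  sigma2: 1.15
prior:
  theta0: [0, 0, 0, 0, 0, -0.1, 0, 0, -0.1]
  V0: [1, 1, 1, 1, 1, 2, 1, 1, 2]
weights:
  B: 1000
  kappa: 0.5
evaluate:
  "n": 1000
  prevalence: [0.3, 0.3]
  theta: [-0.326, -0.155, 0.324, 0.794, 1.061, -0.014, 0.290, 0.426, -0.784]
  sigma2: 1.15
  sigma2_test: 1
  alpha: 0.05
  reps_bio: 20
  reps_alloc: 20
  comparators: [rct, linked]
fixture:
  kind: phase2
  "n": 100
  prevalence: [0.3, 0.3]
  theta: [-0.356, -0.213, 0.240, 1.0, 1.0, -0.182, 0.240, 0.527, -0.586]
  sigma2: 1.15
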