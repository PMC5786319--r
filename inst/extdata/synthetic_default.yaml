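# Desk-scale synthetic scenario: a 3-state metastable system with designed
# stationary probabilities and exchange kinetics, used for validation and
# the package's worked examples.
synthetic:
  n_states: 3
  stationary: [0.50, 0.30, 0.20]
  jump: 0.01            # Metropolis attempt probability per step
  n_traj: 40
  n_steps: 5000
  dt_ns: 0.3
  emission_sd: 0.5
  seed: 1
tica:
  lag_frames: 5
  n_components: 4
msm:
  k_microstates: 100
  lag_frames: 5
  n_samples: 100        # Bayesian transition-matrix samples
pcca:
  n_ms: 3
  membership_threshold: 0.7
adaptive:
  min_frames: 10
  betweenness_tol: 0.2
  convergence_tol: 0.05
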