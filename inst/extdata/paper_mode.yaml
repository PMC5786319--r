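# Production parameter preset for users with real receptor-ligand
# trajectories: the settings used in the dopamine-receptor campaign the
# pipeline reproduces methodologically.
featurization:
  selection_cutoff_A: 7.0       # Cbeta-to-ligand-nitrogen residue selection
  contact_cutoff_A: 5.0
  contact_list_threshold: 0.25
  contact_display_threshold: 0.65
tica:
  n_components: 4
msm:
  k_microstates: 100
  k_candidates: [50, 75, 100, 150, 200, 300]
  lag_ns: 96
  n_samples: 500
  ck_n_bootstrap: 500
pcca:
  n_ms_wild_type: 2
  n_ms_mutant: 3
  membership_threshold: 0.7
adaptive:
  min_frames: 10
  betweenness_tol: 0.2
  convergence_tol: 0.05
  trajectory_length_ns: 300
conformation:
  frames_per_sample: 3
  n_replicate_sets: 3
  proportional_total: 3000
loops:
  rmsf_cutoff_A: 5.0
  rmsd_limit_A: 5.0
  small_cluster_frac: 0.05
  n_representatives: 5
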