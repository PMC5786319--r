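# posekin

Markov state model (MSM) analysis of dynamic ligand binding poses, as an R
package.

Bitopic GPCR ligands — one pharmacophore anchored in the orthosteric site,
the other reaching a secondary pocket between TM2 and TM7 — do not adopt a
single bound pose. The secondary moiety exchanges between metastable poses
on the 10–100 ns scale, and the observable of interest is the *equilibrium*
of those poses: how many metastable states exist, their stationary
probabilities π, and the exchange rates between them. posekin implements
the complete kinetic-analysis workflow used to answer such questions from
multi-trajectory molecular simulation data:

1. **Featurization** — ligand-nitrogen-to-residue-Cβ distances (residues
   selected by a 7.0 Å cutoff in a reference frame), intramolecular
   distances, and signed ring-orientation projections onto the membrane
   normal (16 features for the canonical setup);
2. **TICA** — the slow linear subspace from the generalized eigenproblem
   `C(τ) v = λ C(0) v` (lagged covariance symmetrized, ridge-regularized),
   projecting onto the leading components;
3. **Microstates** — seeded k-means++ discretization (100 microstates by
   default, selectable by `variational_cv_score()` — a cross-validated
   VAMP-2/GMRQ-type score — and implied-timescale convergence);
4. **Reversible MSMs** — maximum-likelihood transition matrices under
   detailed balance (`estimate_reversible_mle()`), Bayesian
   transition-matrix sampling for uncertainties (`bayesian_sample()`),
   implied timescales `t_i = −τ/ln|λ_i|`, and Chapman–Kolmogorov
   validation `P(kτ) = P(τ)^k` with bootstrapped 95% bands (`ck_test()`);
5. **Metastable states** — PCCA++ memberships (`pcca()`), per-state
   equilibrium probabilities with 1σ intervals (`ms_equilibrium()`),
   MFPT-based rates (`ms_rates()`, rate = 1/MFPT from the absorbing-chain
   linear solve), frame filtering at > 70% membership, and cross-condition
   state matching by shared microstates;
6. **Adaptive seeding** — restart-frame selection from single-frame and
   under-sampled between-state microstates, with the < 5-percentage-point
   π-change convergence rule (`select_seed_frames()`,
   `run_iteration_loop()`);
7. **Conformational statistics** — Bayesian-sample-weighted frame draws,
   contact frequencies (5.0 Å, mean ± SD over 3 replicate sets), H-bond
   frequencies, TM-subsegment COM distances;
8. **Loop clustering** — iterative RMSF filtering (> 5.0 Å excluded),
   pairwise superposed backbone RMSD (compiled Kabsch kernel), Ward
   clustering with the ≤ 5.0 Å / < 5% cluster rule, and metastable-state
   reweighting of cluster populations.

Because raw receptor trajectories are not shipped, the package includes a
first-class synthetic-data generator (`toy_system_spec()`,
`simulate_hidden_chain()`, `emit_features()`, `emit_coordinates()`) whose
hidden Markov chain, Gaussian feature emissions and toy 3-D templates
provide exact ground truth for every stage. See the methods vignette
(`vignettes/posekin-methods.Rmd`) for the model, assumptions and design
choices.

## Worked example

Run the end-to-end pipeline on the default synthetic scenario — 3
metastable states with designed stationary probabilities (0.50, 0.30,
0.20), reversible Metropolis exchange, 40 trajectories × 5,000 frames at
0.3 ns/frame, 16 Gaussian features:

```r
library(posekin)
report <- run_pipeline(load_pipeline_config(), seed = 1)
print(report)
#> <pipeline_report> synthetic 3 state system, 40 x 5000 frames
#>   designed pi : 0.500 0.300 0.200
#>   recovered pi: 0.491 0.306 0.203
#>   max |pi error| = 0.0085
#>   max MFPT rel. error = 0.043
```

The report says: after TICA, 100-microstate discretization, Bayesian MSM
estimation and PCCA++ coarse-graining, the three recovered metastable
states' equilibrium probabilities match the generating chain's designed
values to within 0.009, and every recovered inter-state mean first passage
time is within 4.3% of the chain's exact linear-algebra hitting time.
`report$partition` holds the full metastable partition (memberships,
filtered frame sets, π with 1σ intervals, pairwise rates);
`report$mfpt` tabulates estimated vs exact MFPTs per state pair.

Production settings for real trajectory data (96 ns lag, 500 Bayesian
samples, 7.0 Å residue selection, subsegment definitions, …) ship as the
editable preset `inst/extdata/paper_mode.yaml`.

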