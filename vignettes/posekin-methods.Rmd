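---
title: "Kinetic analysis of ligand binding poses with posekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of ligand binding poses with posekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posekin)
```

## The problem

A bitopic ligand engages a G-protein-coupled receptor with two linked
pharmacophores: one buried in the orthosteric binding site (OBS), the other
reaching into a shallower secondary binding pocket (SBP) between the
extracellular ends of TM2 and TM7. The secondary moiety does not sit still;
it exchanges between distinct poses on timescales of tens to hundreds of
nanoseconds. Characterizing that exchange — how many metastable poses exist,
their equilibrium probabilities, and the rates between them — requires a
statistical model over many trajectories rather than inspection of any
single one. posekin implements the standard Markov state model (MSM)
workflow for this problem, plus the structural post-analyses that interpret
the states: ensemble-weighted contact and distance statistics, and
RMSD-based clustering of a flexible N-terminal loop that lids the pocket.

## The model

The pipeline assumes the system's slow dynamics are captured by a
discrete-state Markov chain observed through geometric features.

**Featurization.** Binding-mode features are distances from the ligand's
nitrogen atoms to the Cβ atoms of binding-site residues (residues selected
once, in a reference frame, by a 7.0 Å cutoff — inclusive, `≤`), two
intramolecular distances anchored on the indole nitrogen, and the signed
projections of ring-COM→N4 vectors onto the membrane normal. With 12
qualifying Cβ–N pairs this yields 16 features. Distances are non-negative
and rigid-motion invariant; the projections are signed and invariant only
under rotations that preserve the membrane normal — both properties are
tested.

**TICA.** Time-lagged independent component analysis estimates the slowest
linear coordinates: solve `C(τ) v = λ C(0) v` with the lagged covariance
symmetrized and `C(0)` regularized by `ε·I`, `ε = 1e-10·tr(C0)/k`, which
makes near-duplicate distance columns harmless (a duplicated feature leaves
the projection unchanged — tested to 1e-4). For a symmetric two-state jump
process with flip probability `a` per step, the leading eigenvalue at lag
`τ` is `(1−2a)^τ`; the package recovers this within 10% at 10^5 frames, and
that closed form is the physics anchor of the TICA tests. Eigenvector signs
are fixed by making each component's largest-magnitude loading positive.
The TICA lag is a free parameter (`tica.lag_frames`); we default it to the
smallest MSM lag under consideration and log it, since no single value is
canonical.

**Discretization.** k-means (k-means++ initialization under a named seed,
Lloyd iterations) on the leading TICA components; 100 microstates is the
production default, selected in the original study via cross-validated
variational scores over (50, 75, 100, 150, 200, 300) and ITS convergence.
Centers are stored so frames from later sampling rounds are assigned into
the same microstate space — this is what makes adaptive rounds comparable.
`variational_cv_score()` implements the model selection: trajectories are
split into folds, the training folds re-discretized, and the training
model's leading eigenfunctions scored on held-out folds by the sum of
squared generalized Rayleigh quotients (a VAMP-2/GMRQ-type score whose
constant eigenfunction contributes exactly 1, so `k = 1` scores 1).

**Reversible MSM.** Sliding-window transition counts at lag τ (never
crossing trajectory boundaries), restricted to the largest connected
component of the symmetrized count graph; frames outside it are counted
and reported, never silently dropped. The maximum-likelihood reversible
transition matrix comes from the standard fixed-point iteration on
symmetric edge weights; convergence is declared on the *parameter* scale
(max |ΔP| ≤ 1e-12 per sweep) because the likelihood is flat near the
optimum and a likelihood-change rule would leave ~√tol parameter error. π
follows from the edge weights exactly, so detailed balance holds to machine
precision. For two states any irreducible chain is reversible, which makes
the 2×2 MLE analytically the row-normalized counts — a convenient exact
oracle used in the tests alongside a numerical constrained maximizer.

**Uncertainty.** `bayesian_sample()` draws reversible transition matrices
from the posterior given the counts with a multiplicative Metropolis
sampler on the edge weights (log-normal proposals; burn-in 10·k sweeps;
samples ≥ 1 sweep apart; 500 samples is the production default). The edge
prior is scale-invariant (uniform in log-weight), so the posterior mode
coincides with the reversible MLE; the sampler is proper because only
edges with observed counts are updated. Posterior calibration is tested:
symmetric counts give a posterior mean π of 1/2, and scaling the counts by
10 shrinks the posterior SD by ≈ √10. Summaries report the ML value with
1σ (15.87/84.13%) and 95% percentile intervals.

**Validation.** Implied timescales `t_i(τ) = −τ·dt/ln|λ_{i+1}(τ)|` should
be flat in τ for a Markovian discretization; Bayesian bands give the 95%
intervals. The Chapman–Kolmogorov test propagates each metastable state's
population with `P(τ)^k` and compares against `P(kτ)` re-estimated from the
data, with 95% bands from bootstrapping whole trajectories; a set passes
when the prediction stays inside the band at every k. Both directions are
exercised: data simulated from a Markov chain passes in ≥ 90% of seeded
repeats, and a deliberately lumped observation of a three-state chain (two
states merged into one visible state with slow internal exchange) fails in
the majority.

**Metastable states.** PCCA++ (inner-simplex vertex search on the leading
π-orthonormalized eigenvectors, memberships clipped to [0,1] and
row-normalized) stitches microstates into metastable states (MSs). Frames
enter an MS's structural analyses only if their microstate's membership
exceeds 0.7 (strict); the remainder form a first-class "unassigned" pool
that the adaptive sampler consumes. `π_MS = Σ_i π_i χ_im` aggregates
linearly, so Σπ_MS = 1 identically. Rates are inverse mean first passage
times between crisp microstate sets, computed by the absorbing-chain linear
solve with source states weighted by π; `rate·MFPT = 1` by construction.
MS identities across conditions are matched by shared-microstate counts
(ties: larger Jaccard, then lower index), which is well-defined because all
conditions share one combined discretization.

**Adaptive seeding.** After each round the selector returns (i) every
single-frame microstate and (ii) every microstate with < 10 frames whose
top-two MS memberships differ by ≤ 0.2 — our quantitative reading of
"similar probability to belong to two or more MSs", which the original
description leaves informal. The representative frame is the one with the
largest simulation time (ties: lowest trajectory id, then frame index),
operationalizing "more advanced stages" of sampling. A campaign converges
when the largest absolute change in any condition's π_MS is below 5
percentage points — read as absolute, not relative, change. The loop is a
pure function of (data, seeds, hooks): an MD engine can be plugged in as
the simulator hook; tests plug in the synthetic generator continuing from
the seed frames' hidden states.

**Structural statistics.** Contact frequencies per MS use three replicate
sets; in each, every Bayesian sample contributes three frames per MS,
drawn microstate-first with probability ∝ that sample's π restricted to
the MS, then uniformly within the microstate (the within-microstate rule
is our choice; nothing in the source constrains it). Contacts use a 5.0 Å
heavy-atom cutoff with 25% (listing) and 65% (display) flags. Proportional
sampling allocates `round(total·π_MS)` frames by largest remainder.
H-bonds default to donor–acceptor ≤ 3.5 Å with a donor–H···acceptor angle
≥ 120°, with a distance-only mode; the criterion is configurable because
the reported frequencies do not pin one down. Subsegment COM distances are
unweighted over heavy atoms by default (mass-weighting is a flag), and the
subsegment residue ranges are configuration, not constants.

**Loop clustering.** Flexible-loop conformations are compared by pairwise
backbone RMSD (N, CA, C, O — the atom set is our choice) after optimal
superposition (Kabsch, in compiled code). Residues with RMSF > 5.0 Å are
excluded iteratively before clustering; published residue ranges can bypass
the filter. Ward linkage is cut at the smallest k for which every cluster
has mean intra-cluster RMSD ≤ 5.0 Å *or* holds < 5% of frames (small
outlier clusters are exempt rather than forcing further splits). Cluster
populations are reweighted by `π_MS(frame's MS)/n_sampled(MS)` and reported
alongside raw percentages; representative ensembles are the medoid plus its
4 nearest neighbours.

## The synthetic test system

No trajectory data ship with this methodology, so the generator in
`toy_system_spec()` / `default_toy_structure()` defines the study
conditions under which everything is validated:

* a discrete-time Markov chain over 3 metastable states with stationary
  probabilities (0.50, 0.30, 0.20) and a reversible Metropolis exchange
  matrix (attempt probability 0.01 per step — slow enough for clear
  metastability, fast enough that 40 trajectories × 5,000 frames at
  dt = 0.3 ns contain hundreds of transitions);
* diagonal-covariance Gaussian emissions in a 16-feature space whose
  per-state mean offsets are deliberately *non-collinear* (each state
  perturbs its own feature subset), so the slow subspace is genuinely
  2-dimensional for 3 states;
* toy 3-D templates per state — ligand pseudo-atoms, four pseudo-helical
  TM subsegments whose designed COM separations shift with state, and an
  N-terminal pseudo-loop whose per-state backbone shapes are rescaled so
  the smallest inter-template superposed RMSD equals a designed value
  (12 Å by default) — plus isotropic coordinate jitter;
* one global seed fanning out into fixed per-trajectory substreams, so
  enlarging the trajectory count never reshuffles existing trajectories.

What the generator does *not* emulate: force-field physics, solvent and
membrane, non-Gaussian emission tails, state-dependent noise, or genuinely
diffusive transition paths (transitions are instantaneous in feature
space). Passing tests therefore demonstrate the correctness of the
estimators and the internal consistency of the pipeline on data satisfying
its assumptions — not that any particular receptor simulation is well
described by an MSM; that is what the ITS/CK diagnostics are for on real
data.

## Numerical choices

* MLE convergence: max |ΔP| ≤ 1e-12, with a stall detector that accepts
  when progress stops below 1e-9 (floating-point floor on large matrices).
* TICA regularization ε = 1e-10·tr(C0)/k; eigenvalue signs fixed by the
  largest loading.
* k-means ties go to the lowest center index; Lloyd non-convergence within
  `iter_max` is harmless because frames are re-assigned to the final
  centers.
* Degenerate inputs: an all-zero RMSD matrix yields one cluster; a
  single-state model short-circuits the MLE; λ→1 reports an infinite
  implied timescale rather than overflowing; unreachable MFPT targets are
  an error, never a silent infinity.
* Sub-seeds are derived arithmetically from the global seed per named
  stream (chain, emission, coordinates, k-means, sampler, bootstrap …), so
  every stochastic stage is independently reproducible.

## Scale of the shipped validation runs

The packaged tests and the acceptance script run the full pipeline on the
default 3-state scenario (200,000 frames), Chapman–Kolmogorov calibration
over seeded repeats with hundreds of bootstrap replicates, and a
10-repeat adaptive campaign, sized so the whole suite completes in minutes
on one CPU while keeping every statistical check meaningful at its stated
tolerance.

## Known limitations

* PCCA++ uses the inner-simplex construction with clipping; the subsequent
  constrained optimization refinement step of some implementations is
  omitted (memberships are crisp on well-separated systems either way).
* The Bayesian sampler explores edge weights with a fixed proposal scale;
  very large, sparsely-counted matrices may need longer burn-in than the
  10·k default.
* MS rates use crisp microstate sets, not fuzzy-committor coarse-graining;
  this matches the inverse-MFPT definition but can bias rates when
  memberships are genuinely soft.
* The CV score uses the training model's eigenfunctions on held-out counts;
  fold-empty active sets are skipped with a warning counter rather than
  imputed.
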