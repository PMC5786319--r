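#' Specification of a synthetic metastable-switching system
#'
#' Defines a discrete-time Markov chain over `n_states` hidden metastable
#' states with a designed stationary distribution and reversible exchange
#' matrix, plus Gaussian feature emissions in a 16-dimensional feature space.
#' This is the ground-truth generator used to validate every downstream
#' stage: the chain's stationary vector plays the role of the metastable
#' equilibrium probabilities and its hitting times are the reference MFPTs.
#'
#' @param n_states number of hidden metastable states.
#' @param stationary probability vector (length `n_states`, sums to 1).
#' @param exchange row-stochastic per-step jump matrix, reversible with
#'   respect to `stationary`; default is a Metropolis chain built by
#'   [metropolis_exchange()].
#' @param n_traj number of trajectories.
#' @param n_steps frames per trajectory.
#' @param dt time per frame in ns.
#' @param emission_means n_states x n_features matrix of per-state feature
#'   means (Angstrom); default a 16-feature layout with state-dependent
#'   offsets in a few features.
#' @param emission_sd per-feature emission standard deviation (recycled).
#' @param seed integer RNG seed; fans out into per-trajectory substreams.
#' @return object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(n_states = 3,
                            stationary = c(0.50, 0.30, 0.20),
                            exchange = metropolis_exchange(stationary),
                            n_traj = 40, n_steps = 5000, dt = 0.3,
                            emission_means = default_emission_means(n_states),
                            emission_sd = 0.5,
                            seed = 1L) {
  if (length(stationary) != n_states)
    stop2("stationary must have length n_states")
  check_prob_vector(stationary, "stationary")
  if (!all(dim(exchange) == c(n_states, n_states)))
    stop2("exchange must be n_states x n_states")
  check_stochastic(exchange, "exchange")
  check_detailed_balance(exchange, stationary, "exchange")
  if (n_traj < 1 || n_steps < 1) stop2("n_traj and n_steps must be >= 1")
  emission_means <- as.matrix(emission_means)
  if (nrow(emission_means) != n_states)
    stop2("emission_means must have one row per state")
  emission_sd <- rep_len(emission_sd, ncol(emission_means))
  if (any(emission_sd < 0)) stop2("emission_sd must be non-negative")
  structure(list(n_states = as.integer(n_states), stationary = stationary,
                 exchange = exchange, n_traj = n_traj, n_steps = n_steps,
                 dt = dt, emission_means = emission_means,
                 emission_sd = emission_sd, seed = as.integer(seed)),
            class = "toy_system_spec")
}

#' Reversible Metropolis exchange matrix for a target stationary vector
#'
#' Off-diagonal jump probabilities `jump * min(1, pi_j / pi_i)` with the
#' diagonal absorbing the remainder; reversible w.r.t. `pi` by construction.
#'
#' @param pi stationary probability vector.
#' @param jump per-step attempt probability toward each other state.
#' @return row-stochastic reversible matrix.
#' @export
metropolis_exchange <- function(pi, jump = 0.01) {
  n <- length(pi)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    P[i, j] <- jump * min(1, pi[j] / pi[i])
  diag(P) <- 1 - rowSums(P)
  if (any(diag(P) < 0)) stop2("jump probability too large for this stationary vector")
  P
}

## 16-feature layout mirroring a bitopic-ligand feature set: 12 ligand-N to
## residue-Cbeta distances, 2 intramolecular distances, 2 signed ring
## projections. States differ in a handful of features, as binding poses do.
default_emission_means <- function(n_states) {
  base <- c(rep(7, 12), 2.5, 3.5, 1.0, -1.0)
  offsets <- matrix(0, n_states, 16)
  ## distinct, non-collinear pose signatures: each state perturbs its own
  ## subset of contacts/orientations, as distinct binding modes do
  sig <- list(c(1, 4, 7), c(2, 5, 10), c(3, 8, 15), c(6, 9, 16),
              c(11, 12, 13))
  for (s in seq_len(n_states)[-1]) {
    f <- sig[[((s - 2) %% length(sig)) + 1]]
    offsets[s, f] <- offsets[s, f] + c(2.5, 2.0, -1.5)
    offsets[s, 16] <- offsets[s, 16] + 0.8 * (s - 1)
  }
  m <- sweep(offsets, 2, base, "+")
  colnames(m) <- c(outer(paste0("N", 1:4), paste0("res", 1:3),
                         function(n, r) paste(n, r, sep = "_")),
                   "N4_N3", "N4_Oamide", "proj_ring5", "proj_ring6")
  m
}

#' Simulate hidden metastable-state trajectories
#'
#' Draws `n_traj` independent realizations of the spec's Markov chain, each
#' `n_steps` long, with initial states drawn from the stationary vector.
#' Reproducible: trajectory `i` uses a deterministic substream of the spec
#' seed, so enlarging `n_traj` leaves earlier trajectories unchanged.
#'
#' @param spec a [toy_system_spec()].
#' @param start_states optional integer vector of initial states (one per
#'   trajectory, 1-based); overrides stationary initial sampling. Used by the
#'   adaptive-seeding loop to continue from selected frames.
#' @param seed_offset integer added to the substream index (used when
#'   generating additional rounds of trajectories).
#' @return list of integer vectors (1-based state indices).
#' @export
simulate_hidden_chain <- function(spec, start_states = NULL, seed_offset = 0L) {
  stopifnot(inherits(spec, "toy_system_spec"))
  cum <- matrix(apply(spec$exchange, 1, cumsum),
                nrow = spec$n_states)       # column s = cumulative row s
  lapply(seq_len(spec$n_traj), function(i) {
    set.seed(substream_seed(spec$seed, 1L, i + seed_offset))
    s <- integer(spec$n_steps)
    s[1] <- if (is.null(start_states))
      min(spec$n_states, findInterval(runif(1), cumsum(spec$stationary)) + 1L)
    else as.integer(start_states[[i]])
    u <- runif(spec$n_steps - 1L)
    for (t in seq_len(spec$n_steps - 1L))
      s[t + 1L] <- min(spec$n_states,
                       findInterval(u[t], cum[, s[t]], left.open = TRUE) + 1L)
    s
  })
}

#' Emit Gaussian feature trajectories from hidden-state sequences
#'
#' Frame `t` is drawn from a diagonal Gaussian centred on the emission mean
#' of its hidden state.
#'
#' @param states list of hidden-state index vectors (from
#'   [simulate_hidden_chain()]).
#' @param spec the generating [toy_system_spec()].
#' @param seed_offset substream offset, as in [simulate_hidden_chain()].
#' @return list of [feature_traj()] objects.
#' @export
emit_features <- function(states, spec, seed_offset = 0L) {
  k <- ncol(spec$emission_means)
  lapply(seq_along(states), function(i) {
    s <- states[[i]]
    if (any(s < 1 | s > spec$n_states))
      stop2("hidden state index outside [1, n_states]")
    set.seed(substream_seed(spec$seed, 2L, i + seed_offset))
    noise <- matrix(rnorm(length(s) * k), length(s), k)
    vals <- spec$emission_means[s, , drop = FALSE] +
      sweep(noise, 2, spec$emission_sd, "*")
    feature_traj(vals, colnames(spec$emission_means), dt = spec$dt,
                 id = i + seed_offset)
  })
}

#' Exact mean first passage time of the generating chain
#'
#' Linear-algebra hitting time of `target` from `source` for a known
#' transition matrix: the ground-truth reference against which the estimated
#' model's MFPTs are judged. Source states are weighted by the stationary
#' vector restricted to `source`.
#'
#' @param P row-stochastic matrix.
#' @param source,target disjoint 1-based state index sets.
#' @param dt time per step (ns).
#' @param pi stationary vector (computed from `P` if omitted).
#' @return MFPT in ns.
#' @export
chain_mfpt <- function(P, source, target, dt = 1, pi = NULL) {
  n <- nrow(P)
  if (length(intersect(source, target)))
    stop2("source and target must be disjoint")
  pi <- pi %||% stationary_distribution(P)
  keep <- setdiff(seq_len(n), target)
  Q <- P[keep, keep, drop = FALSE]
  h <- solve(diag(length(keep)) - Q, rep(1, length(keep)))
  hh <- numeric(n)
  hh[keep] <- h
  w <- pi[source] / sum(pi[source])
  sum(w * hh[source]) * dt
}
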