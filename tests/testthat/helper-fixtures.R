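# shared fixture builders; everything is generated in code at test time

two_state_spec <- function(a = 0.01, n_traj = 10, n_steps = 5000,
                           sep = 5, sd = 0.5, seed = 1) {
  toy_system_spec(
    n_states = 2, stationary = c(0.5, 0.5),
    exchange = matrix(c(1 - a, a, a, 1 - a), 2, byrow = TRUE),
    n_traj = n_traj, n_steps = n_steps,
    emission_means = rbind(rep(0, 16), c(sep, rep(0, 15))),
    emission_sd = sd, seed = seed)
}

# random reversible transition matrix via symmetric weights
random_reversible <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * n, 0.05, 1), n)
  x <- x + t(x)
  diag(x) <- diag(x) + n          # metastable-ish diagonal
  P <- x / rowSums(x)
  list(P = P, pi = rowSums(x) / sum(x))
}

# Monte-Carlo mean hitting time of `target` starting from `start`
mc_hitting_time <- function(P, start, target, n_chains = 1e4,
                            max_steps = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(P)
  cum <- apply(P, 1, cumsum)
  state <- rep(as.integer(start), n_chains)
  steps <- rep(NA_integer_, n_chains)
  alive <- !(state %in% target)
  steps[!alive] <- 0L
  for (t in seq_len(max_steps)) {
    if (!any(alive)) break
    u <- runif(sum(alive))
    s_new <- vapply(seq_along(u), function(i)
      min(n, findInterval(u[i], cum[, state[alive][i]],
                          left.open = TRUE) + 1L), integer(1))
    state[alive] <- s_new
    done <- s_new %in% target
    steps[which(alive)[done]] <- t
    alive[which(alive)[done]] <- FALSE
  }
  stopifnot(!anyNA(steps))
  list(mean = mean(steps), se = sd(steps) / sqrt(n_chains))
}

# continue the synthetic generator from selected seed frames: the simulator
# hook used by adaptive-sampling tests
make_toy_simulator <- function(spec, hidden0, n_steps = 500) {
  reg <- new.env()
  reg$hidden <- hidden0
  function(seeds, round) {
    start <- vapply(seq_len(nrow(seeds)), function(i)
      reg$hidden[[seeds$traj[i]]][seeds$frame[i] + 1L], integer(1))
    sp <- spec
    sp$n_traj <- length(start)
    sp$n_steps <- n_steps
    off <- 10000L * round
    hh <- simulate_hidden_chain(sp, start_states = start, seed_offset = off)
    reg$hidden <- c(reg$hidden, hh)
    emit_features(hh, sp, seed_offset = off)
  }
}

# small labeled loop ensemble with n1/n2 frames of two templates
loop_fixture <- function(n1 = 70, n2 = 30, jitter = 0.5, seed = 2,
                         separation = 12) {
  sspec <- default_toy_structure(n_states = 2, jitter_sd = jitter,
                                 loop_separation = separation, seed = seed)
  ens <- emit_coordinates(list(rep(c(1L, 2L), c(n1, n2))), sspec, dt = 1)
  ens$frames$ms <- ens$frames$state
  ens
}

nt_residues <- function(ens) sort(unique(ens$atoms$resid[ens$atoms$segment == "NT"]))
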