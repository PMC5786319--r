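test_that("k-means discretization is seeded, assigns by nearest center, and separates distant clouds", {
  set.seed(21)
  cloud1 <- matrix(rnorm(500, sd = 0.1), ncol = 2)
  cloud2 <- matrix(rnorm(500, sd = 0.1) + 10, ncol = 2)
  X <- rbind(cloud1, cloud2)
  d <- kmeans_discretize(X, 2, seed = 3)
  lab <- d$dtrajs[[1]]
  expect_identical(length(unique(lab[1:250])), 1L)
  expect_identical(length(unique(lab[251:500])), 1L)
  expect_false(lab[1] == lab[500])
  expect_identical(kmeans_discretize(X, 2, seed = 3)$dtrajs[[1]], lab)
  ## k = 1 puts everything in one microstate
  expect_identical(unique(kmeans_discretize(X, 1, seed = 1)$dtrajs[[1]]), 1L)
  expect_error(kmeans_discretize(matrix(1, 10, 2), 2, seed = 1), "distinct")
  ## assignment of new frames uses the stored centers
  expect_identical(assign_microstates(cloud1[1:5, , drop = FALSE], d$centers),
                   lab[1:5])
})

test_that("count matrix matches hand counts and a brute-force recount", {
  cm <- count_matrix(list(c(1L, 1L, 2L, 2L)), 1)
  expect_equal(cm$C, rbind(c(1, 1), c(0, 1)))
  cm3 <- count_matrix(list(c(1L, 1L, 2L, 2L)), 3)
  expect_equal(cm3$C, rbind(c(0, 1), c(0, 0)))
  set.seed(22)
  dtrajs <- lapply(1:3, function(i) sample.int(4, 60, replace = TRUE))
  lag <- 5
  cm_r <- count_matrix(dtrajs, lag, n_states = 4)
  brute <- matrix(0, 4, 4)
  for (s in dtrajs)
    for (t in seq_len(length(s) - lag))
      brute[s[t], s[t + lag]] <- brute[s[t], s[t + lag]] + 1
  expect_equal(cm_r$C, brute)
  expect_error(count_matrix(list(1:3), 5), "shorter")
})

test_that("reversible MLE: symmetric counts give row normalization, and 2x2 matches a constrained optimizer", {
  cm <- count_matrix(list(c(1L, 2L)), 1, n_states = 2)
  cm$C <- rbind(c(90, 10), c(10, 90)); cm$active_set <- 1:2
  m <- estimate_reversible_mle(cm)
  expect_equal(m$P, rbind(c(0.9, 0.1), c(0.1, 0.9)), tolerance = 1e-10)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-10)

  ## asymmetric 2x2 against direct numerical maximization of the
  ## reversible likelihood parameterized by (p01, pi0)
  C <- rbind(c(80, 20), c(10, 90))
  cm$C <- C
  m2 <- estimate_reversible_mle(cm)
  nll <- function(par) {
    p <- plogis(par[1]); pi0 <- plogis(par[2])
    q <- pi0 * p / (1 - pi0)          # detailed balance
    if (q >= 1) return(1e10)
    P <- rbind(c(1 - p, p), c(q, 1 - q))
    -sum(C * log(P))
  }
  opt <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  p_hat <- plogis(opt$par[1]); pi0_hat <- plogis(opt$par[2])
  expect_equal(m2$P[1, 2], p_hat, tolerance = 1e-6)
  expect_equal(m2$pi[1], pi0_hat, tolerance = 1e-6)

  ## detailed balance and row sums at 1e-10; pi is the leading left eigenvector
  F <- m2$pi * m2$P
  expect_lt(max(abs(F - t(F))), 1e-10)
  expect_lt(max(abs(rowSums(m2$P) - 1)), 1e-10)
  e <- eigen(t(m2$P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  expect_equal(m2$pi, v / sum(v), tolerance = 1e-8)
})

test_that("MLE recovers the generating chain from a long simulation", {
  spec <- toy_system_spec(n_traj = 10, n_steps = 20000, seed = 23)
  h <- simulate_hidden_chain(spec)
  m <- estimate_reversible_mle(count_matrix(h, 1, n_states = 3))
  expect_lt(max(abs(m$P - spec$exchange)), 0.004)
  expect_lt(max(abs(m$pi - spec$stationary)), 0.03)
})

test_that("implied timescales follow the closed form and diverge safely as lambda -> 1", {
  ## exact 2-state chain with lambda2 = 0.8 at lag 1, dt 1 ns
  a <- 0.1; P <- rbind(c(1 - a, a), c(a, 1 - a))   # lambda2 = 1 - 2a = 0.8
  set.seed(24)
  s <- integer(2e5); s[1] <- 1L
  for (t in 2:length(s))
    s[t] <- if (runif(1) < P[s[t - 1], 1]) 1L else 2L
  its <- implied_timescales(list(s), lags = c(1L, 2L), n_its = 1)
  expect_equal(its$ml[its$lag == 1], -1 / log(0.8), tolerance = 0.05)
  ## Markovian data: flat in lag
  expect_equal(its$ml[its$lag == 2], its$ml[its$lag == 1], tolerance = 0.1)
  ## lambda -> 1: infinite timescale reported, no overflow/NaN
  mod <- transition_model(rbind(c(1, 0), c(0, 1)), pi = c(0.5, 0.5))
  expect_identical(mod$eigenvalues, c(1, 1))
  cm <- count_matrix(list(rep(1L, 10)), 1, n_states = 1)
  expect_error(implied_timescales(list(rep(1L, 10)), 1, n_its = 3),
               "active-set")
})

test_that("MFPT matches the geometric closed form and a Monte-Carlo hitting-time oracle", {
  P <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  mod <- transition_model(P, lag = 1L, dt = 1)
  expect_equal(mod$pi, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(mfpt(mod, 1, 2), 10)
  expect_equal(mfpt(mod, 2, 1), 5)
  ## rate * MFPT = 1 by definition throughout
  expect_equal((1 / mfpt(mod, 1, 2)) * mfpt(mod, 1, 2), 1)

  rr <- random_reversible(6, seed = 25)
  mod6 <- transition_model(rr$P, pi = rr$pi, lag = 1L, dt = 1)
  mc <- mc_hitting_time(rr$P, start = 2, target = 5, n_chains = 2e4,
                        seed = 26)
  lin <- mfpt(mod6, 2, 5)
  expect_lt(abs(lin - mc$mean), 2 * mc$se + 1e-9)

  expect_error(mfpt(mod, 1, 1), "disjoint")
  Pr <- rbind(c(1, 0), c(0.5, 0.5))   # state 2 unreachable from 1
  modr <- structure(list(P = Pr, pi = c(1, 0), lag = 1L, dt = 1),
                    class = "transition_model")
  expect_error(mfpt(modr, 1, 2), "unreachable")
})

test_that("Bayesian sampler is calibrated: symmetric posterior mean, sqrt(10) SD shrinkage, reproducible", {
  cm <- count_matrix(list(c(1L, 2L)), 1, n_states = 2)
  cm$C <- rbind(c(50, 10), c(10, 50)); cm$active_set <- 1:2
  ens <- bayesian_sample(cm, n = 400, seed = 31)
  expect_length(ens$samples, 400)
  pis <- vapply(ens$samples, function(s) s$pi[1], numeric(1))
  expect_equal(mean(pis), 0.5, tolerance = 0.02)
  ## every sample is a valid reversible stochastic matrix
  for (s in ens$samples[seq(1, 400, by = 50)]) {
    expect_lt(max(abs(rowSums(s$P) - 1)), 1e-10)
    F <- s$pi * s$P
    expect_lt(max(abs(F - t(F))), 1e-10)
  }
  cm10 <- cm; cm10$C <- cm$C * 10
  ens10 <- bayesian_sample(cm10, n = 400, seed = 32)
  sd1 <- sd(pis)
  sd10 <- sd(vapply(ens10$samples, function(s) s$pi[1], numeric(1)))
  expect_gt(sd1 / sd10, sqrt(10) * 0.6)
  expect_lt(sd1 / sd10, sqrt(10) * 1.6)
  ## reproducibility under seed
  ens_b <- bayesian_sample(cm, n = 10, seed = 31)
  expect_equal(ens_b$samples[[5]]$P, ens$samples[[5]]$P)
  expect_error(bayesian_sample(cm, n = 1), "2 samples")
  ## ensemble_summary covers the ML value
  su <- ensemble_summary(ens, function(P, pi) pi[1])
  expect_true(su$lower_95 <= su$ml && su$ml <= su$upper_95)
})
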