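test_that("spec validation rejects broken stationary/exchange input", {
  expect_error(toy_system_spec(stationary = c(0.6, 0.3, 0.2)), "sum to 1")
  expect_error(toy_system_spec(n_states = 2, stationary = c(0.5, 0.5),
                               exchange = matrix(c(0.9, 0.2, 0.2, 0.8), 2)),
               "sum to 1")
  bad <- matrix(c(0.95, 0.05, 0.01, 0.99), 2, byrow = TRUE)
  expect_error(toy_system_spec(n_states = 2, stationary = c(0.5, 0.5),
                               exchange = bad), "detailed balance")
})

test_that("a single-state chain stays in state one", {
  spec <- toy_system_spec(n_states = 1, stationary = 1,
                          exchange = matrix(1, 1, 1),
                          emission_means = matrix(rep(1, 16), 1),
                          n_traj = 3, n_steps = 50)
  h <- simulate_hidden_chain(spec)
  expect_true(all(unlist(h) == 1L))
  expect_true(all(lengths(h) == 50L))
})

test_that("occupancy and per-step transition rate match the designed chain", {
  spec <- two_state_spec(a = 0.01, n_traj = 20, n_steps = 10000, seed = 42)
  h <- simulate_hidden_chain(spec)
  s <- unlist(h)
  occ <- mean(s == 1L)
  expect_gt(occ, 0.47)
  expect_lt(occ, 0.53)
  ## empirical 1->2 jumps per step spent in 1 vs the design value 0.01;
  ## 3 SE under the binomial count of exits
  from1 <- 0; jumps <- 0
  for (tr in h) {
    from1 <- from1 + sum(tr[-length(tr)] == 1L)
    jumps <- jumps + sum(tr[-length(tr)] == 1L & tr[-1] == 2L)
  }
  rate <- jumps / from1
  se <- sqrt(0.01 * 0.99 / from1)
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("lag-1 empirical transition matrix converges to the exchange matrix", {
  spec <- toy_system_spec(n_traj = 10, n_steps = 10000, seed = 9)
  h <- simulate_hidden_chain(spec)
  cm <- count_matrix(h, 1, n_states = 3)
  P_emp <- cm$C / rowSums(cm$C)
  expect_lt(max(abs(P_emp - spec$exchange)), 0.005)
})

test_that("identical seeds reproduce trajectories; different seeds do not; extra trajectories leave earlier ones unchanged", {
  spec <- two_state_spec(n_traj = 3, n_steps = 200, seed = 5)
  h1 <- simulate_hidden_chain(spec)
  h2 <- simulate_hidden_chain(spec)
  expect_identical(h1, h2)
  spec_b <- two_state_spec(n_traj = 3, n_steps = 200, seed = 6)
  expect_false(identical(h1, simulate_hidden_chain(spec_b)))
  spec_more <- two_state_spec(n_traj = 5, n_steps = 200, seed = 5)
  h_more <- simulate_hidden_chain(spec_more)
  expect_identical(h1, h_more[1:3])
  f1 <- emit_features(h1, spec)
  f2 <- emit_features(h1, spec)
  expect_identical(f1, f2)
})

test_that("zero-noise emissions equal the state means exactly and a midpoint classifier recovers well-separated labels", {
  spec0 <- two_state_spec(n_traj = 2, n_steps = 100, sd = 0, seed = 3)
  h <- simulate_hidden_chain(spec0)
  f <- emit_features(h, spec0)
  for (i in 1:2)
    expect_equal(unname(f[[i]]$values),
                 unname(spec0$emission_means[h[[i]], ]))
  ## means separated by 10 sd in feature 1 -> midpoint threshold recovers
  ## at least 99.9% of hidden labels (Gaussian tail beyond 5 sd)
  spec10 <- two_state_spec(n_traj = 5, n_steps = 2000, sep = 5, sd = 0.5,
                           seed = 8)
  h10 <- simulate_hidden_chain(spec10)
  f10 <- emit_features(h10, spec10)
  pred <- lapply(f10, function(tr) ifelse(tr$values[, 1] < 2.5, 1L, 2L))
  acc <- mean(unlist(pred) == unlist(h10))
  expect_gte(acc, 0.999)
  expect_equal(ncol(f10[[1]]$values), 16L)
})

test_that("coordinate emission respects templates, jitter and labels", {
  sspec <- default_toy_structure(n_states = 2, jitter_sd = 0, seed = 1)
  ens <- emit_coordinates(list(rep(1L, 5)), sspec)
  ## zero jitter, one state: all frames identical, pairwise RMSD zero
  D <- pairwise_rmsd_matrix(ens, nt_residues(ens), segment = "NT")
  expect_equal(max(D), 0, tolerance = 1e-10)
  expect_identical(ens$frames$state, rep(1L, 5))
  ## missing template errors
  expect_error(emit_coordinates(list(c(1L, 3L)), sspec), "template")
  ## COM distance of designed subsegments propagates jitter as ~sd/sqrt(n)
  sspecj <- default_toy_structure(n_states = 1, jitter_sd = 0.4, seed = 4)
  ensj <- emit_coordinates(list(rep(1L, 200)), sspecj)
  d0 <- subsegment_com_distance(matrix(sspecj$templates[[1]], ncol = 3),
                                sspecj$atoms, "TM1e", "TM2e")
  n_at <- sum(sspecj$atoms$segment == "TM1e")
  ds <- vapply(1:200, function(f)
    as.numeric(subsegment_com_distance(matrix(ensj$coords[f, , ], ncol = 3),
                                       ensj$atoms, "TM1e", "TM2e")),
    numeric(1))
  expect_lt(abs(mean(ds) - d0), 3 * 0.4 / sqrt(n_at))
})
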