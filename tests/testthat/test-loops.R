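test_that("pairwise RMSD obeys symmetry, zero diagonal, superposition invariance, and closed forms", {
  ens <- loop_fixture(n1 = 6, n2 = 4, jitter = 0.4, seed = 91)
  res <- nt_residues(ens)
  D <- pairwise_rmsd_matrix(ens, res, segment = "NT")
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, nrow(D)))
  ## frame vs a rigidly rotated + translated copy of itself: RMSD ~ 0
  idx <- which(ens$atoms$segment == "NT")
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ens2 <- subset_frames(ens, c(1L, 1L))
  ens2$coords[2, , ] <- matrix(ens2$coords[1, , ], ncol = 3) %*% t(R) +
    matrix(c(5, 6, 7), dim(ens2$coords)[2], 3, byrow = TRUE)
  D2 <- pairwise_rmsd_matrix(ens2, res, segment = "NT")
  expect_lt(D2[1, 2], 1e-6)
  ## one atom displaced by 3 A out of N atoms -> RMSD <= 3/sqrt(N) (the
  ## optimal fit can only reduce it); without refitting it is exact
  N <- length(idx)
  ens3 <- subset_frames(ens, c(1L, 1L))
  ens3$coords[2, idx[1], 1] <- ens3$coords[2, idx[1], 1] + 3
  D3 <- pairwise_rmsd_matrix(ens3, res, segment = "NT")
  expect_lte(D3[1, 2], 3 / sqrt(N) + 1e-9)
  expect_gt(D3[1, 2], 0.5 * 3 / sqrt(N))
})

test_that("package RMSD agrees with the bio3d superposition oracle", {
  skip_if_not_installed("bio3d")
  ens <- loop_fixture(n1 = 4, n2 = 4, jitter = 1.0, seed = 92)
  res <- nt_residues(ens)
  idx <- which(ens$atoms$segment == "NT" & ens$atoms$resid %in% res)
  D <- pairwise_rmsd_matrix(ens, res, segment = "NT")
  for (i in 1:3) for (j in (i + 1):4) {
    a <- as.numeric(t(matrix(ens$coords[i, idx, ], ncol = 3)))
    b <- as.numeric(t(matrix(ens$coords[j, idx, ], ncol = 3)))
    ref <- bio3d::rmsd(a, b, fit = TRUE)   # bio3d rounds to 3 decimals
    expect_equal(D[i, j], ref, tolerance = 1e-3)
  }
})

test_that("iterative RMSF filter keeps rigid residues and drops a designed jitterer", {
  ## rigid ensemble: everything retained in one pass
  sspec <- default_toy_structure(n_states = 1, jitter_sd = 0.2, seed = 93)
  ens <- emit_coordinates(list(rep(1L, 30)), sspec)
  res <- nt_residues(ens)
  out <- iterative_rmsf_filter(ens, res, segment = "NT")
  expect_identical(out$retained, res)
  expect_identical(max(out$history$iteration), 1L)
  ## one residue jitters with ~8 A amplitude: exactly it is excluded
  idx_r5 <- which(ens$atoms$segment == "NT" & ens$atoms$resid == 5)
  set.seed(94)
  ens_j <- ens
  for (f in seq_len(30))
    ens_j$coords[f, idx_r5, ] <- ens_j$coords[f, idx_r5, ] +
      matrix(rnorm(3, sd = 8), length(idx_r5), 3, byrow = TRUE)
  out_j <- iterative_rmsf_filter(ens_j, res, segment = "NT")
  expect_identical(setdiff(res, out_j$retained), 5L)
  expect_error(iterative_rmsf_filter(ens, res[1:2], segment = "NT"), "3 residues")
})

test_that("Ward cut separates designed templates and exempts small outlier clusters", {
  ens <- loop_fixture(n1 = 70, n2 = 30, jitter = 0.5, seed = 95)
  D <- pairwise_rmsd_matrix(ens, nt_residues(ens), segment = "NT")
  lab <- ward_cluster_cut(D)
  expect_identical(attr(lab, "k"), 2L)
  agree <- max(mean((lab == 1) == (ens$frames$state == 1)),
               mean((lab == 2) == (ens$frames$state == 1)))
  expect_gt(agree, 0.99)
  ## all-identical frames: one cluster
  lab0 <- ward_cluster_cut(matrix(0, 5, 5))
  expect_identical(attr(lab0, "k"), 1L)
  ## a 4% outlier cluster with internal spread over the limit is exempt
  set.seed(96)
  n_main <- 96; n_out <- 4
  D_syn <- matrix(0, n_main + n_out, n_main + n_out)
  main <- 1:n_main; outl <- (n_main + 1):(n_main + n_out)
  D_syn[main, main] <- 1; D_syn[outl, outl] <- 7
  D_syn[main, outl] <- 100; D_syn[outl, main] <- 100
  diag(D_syn) <- 0
  lab_syn <- ward_cluster_cut(D_syn, rmsd_limit = 5, small_cluster_frac = 0.05)
  expect_identical(attr(lab_syn, "k"), 2L)
  ## clustering invariant to frame order
  perm <- sample(nrow(D))
  lab_perm <- ward_cluster_cut(D[perm, perm])
  expect_identical(attr(lab_perm, "k"), 2L)
  expect_gt(abs(cor(lab_perm == 1, lab[perm] == 1)), 0.99)
})

test_that("reweighting matches analytic values and an explicit weighted recount", {
  ## 70/30 sampled mixture reweighted to 50/50 equilibrium
  lab <- rep(c(1L, 2L), c(70, 30))
  ms <- rep(c(1L, 2L), c(70, 30))
  pops <- reweight_populations(lab, ms, c(0.5, 0.5))
  expect_equal(pops$reweighted_pct, c(50, 50), tolerance = 1e-9)
  expect_equal(pops$raw_pct, c(70, 30))
  ## two MSs with pi 0.8/0.2 equally sampled
  lab2 <- rep(c(1L, 2L), each = 50)
  ms2 <- rep(c(1L, 2L), each = 50)
  expect_equal(reweight_populations(lab2, ms2, c(0.8, 0.2))$reweighted_pct,
               c(80, 20))
  ## random assignment vs brute-force recount
  set.seed(97)
  lab_r <- sample(1:4, 200, replace = TRUE)
  ms_r <- sample(1:3, 200, replace = TRUE)
  pi_r <- c(0.5, 0.3, 0.2)
  pops_r <- reweight_populations(lab_r, ms_r, pi_r)
  w <- pi_r[ms_r] / table(ms_r)[ms_r]
  brute <- tapply(as.numeric(w), lab_r, sum)
  brute <- brute / sum(brute) * 100
  expect_equal(pops_r$reweighted_pct, as.numeric(brute), tolerance = 1e-9)
  expect_equal(sum(pops_r$reweighted_pct), 100, tolerance = 1e-9)
  expect_error(reweight_populations(lab_r, ms_r, c(a = 0.5)), "unknown")
})

test_that("the full loop analysis reports populations, intra-RMSD and 5-frame representatives", {
  ens <- loop_fixture(n1 = 60, n2 = 40, jitter = 0.5, seed = 98)
  res <- loop_cluster_analysis(ens, nt_residues(ens),
                               pi_ms = c(0.5, 0.5), segment = "NT")
  expect_identical(res$k, 2L)
  expect_equal(sum(res$populations$reweighted_pct), 100, tolerance = 1e-6)
  expect_equal(res$populations$reweighted_pct, c(50, 50), tolerance = 2)
  expect_true(all(res$intra_rmsd <= 5))
  expect_true(all(lengths(res$representatives) == 5))
  ## medoid first: it belongs to its own cluster
  for (cl in 1:2)
    expect_true(res$labels[res$representatives[[cl]][1]] == cl)
})
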