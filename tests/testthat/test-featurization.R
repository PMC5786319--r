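# a tiny hand-built ensemble: 1 ligand nitrogen layout + 2 residues with
# Cbeta atoms at controlled distances
make_mini_ens <- function(cb1 = c(-6.9, 0, 0), cb2 = c(10, 0, 0),
                          n_frames = 1) {
  atoms <- data.frame(
    name = c("N1", "N2", "N3", "N4", "Oamide",
             paste0("C5", letters[1:5]), paste0("C6", letters[1:6]),
             "CB", "CB"),
    resid = c(rep(900L, 16), 10L, 20L),
    resname = c(rep("LIG", 16), "ASP", "GLU"),
    segment = c(rep("LIG", 16), "PROT", "PROT"),
    element = c(rep("N", 4), "O", rep("C", 11), "C", "C"))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 2, 2),
               c(2, 2, 2),
               matrix(rnorm(15, sd = 0.1), 5, 3),             # ring5 near 0
               matrix(rnorm(18, sd = 0.1) + 3, 6, 3),         # ring6 near 3
               cb1, cb2)
  coords <- array(rep(as.numeric(xyz), each = n_frames),
                  c(n_frames, nrow(xyz), 3))
  conformer_ensemble(coords, atoms)
}

test_that("residue selection honors the 7 A boundary inclusively", {
  set.seed(1)
  ens <- make_mini_ens(cb1 = c(-6.9, 0, 0), cb2 = c(30, 0, 0))
  spec <- feature_spec()
  sel <- select_feature_residues(ens, spec)
  expect_identical(sel$resid, 10L)
  expect_identical(sel$nitrogen, "N1")
  ## exactly at 7.0 is included ("within")
  ens_b <- make_mini_ens(cb1 = c(-7.0, 0, 0), cb2 = c(30, 0, 0))
  expect_identical(nrow(select_feature_residues(ens_b, spec)), 1L)
  ## just outside is not
  ens_c <- make_mini_ens(cb1 = c(-7.1, 0, 0), cb2 = c(30, 0, 0))
  expect_identical(nrow(select_feature_residues(ens_c, spec)), 0L)
  ## missing Cbeta on a candidate residue is a named error
  expect_error(select_feature_residues(ens, spec, candidate_resids = 99),
               "99")
})

test_that("12 qualifying pairs plus intramolecular and ring features give 16 columns", {
  set.seed(2)
  ens <- make_mini_ens()
  spec <- feature_spec()
  pairs <- data.frame(nitrogen = rep(c("N1", "N2", "N3", "N4"), 3),
                      resid = rep(c(10L, 20L, 900L), each = 4))
  pairs$resid <- rep(c(10L, 20L), 6)    # 12 pairs over the two residues
  ft <- compute_feature_matrix(ens, pairs, spec)[[1]]
  expect_identical(ncol(ft$values), 16L)
  expect_identical(tail(ft$feature_names, 2), c("proj_ring5", "proj_ring6"))
})

test_that("distances and ring projections match hand geometry", {
  set.seed(3)
  ens <- make_mini_ens()
  ## place N4 at (1,2,2) over ring5 whose COM ~ origin: projection ~ +2
  spec <- feature_spec()
  ft <- compute_feature_matrix(ens, data.frame(nitrogen = "N1", resid = 10L),
                               spec)[[1]]
  expect_equal(unname(ft$values[1, "N1_res10"]), 6.9, tolerance = 1e-10)
  expect_equal(unname(ft$values[1, "proj_ring5"]), 2, tolerance = 0.2)
  ## 3-4-5 triangle
  at <- data.frame(name = c("A", "B"), resid = 1:2, resname = "X",
                   segment = "P", element = "C")
  co <- array(c(0, 3, 0, 0, 0, 4), c(1, 2, 3))
  xyz <- matrix(co[1, , ], ncol = 3)
  expect_equal(min_group_distance(xyz, 1, 2), 5)
})

test_that("feature matrix agrees with an explicit per-frame loop recomputation", {
  sspec <- default_toy_structure(n_states = 2, jitter_sd = 0.5, seed = 6)
  ens <- emit_coordinates(list(c(1L, 2L, 1L, 2L, 2L)), sspec)
  spec <- feature_spec(selection_cutoff = 12)
  pairs <- select_feature_residues(ens, spec)
  expect_gt(nrow(pairs), 0)
  ft <- compute_feature_matrix(ens, pairs, spec)[[1]]
  for (f in seq_len(5)) {
    xyz <- matrix(ens$coords[f, , ], ncol = 3)
    for (p in seq_len(nrow(pairs))) {
      ni <- which(ens$atoms$name == pairs$nitrogen[p])[1]
      ci <- which(ens$atoms$name == "CB" & ens$atoms$resid == pairs$resid[p])
      expect_equal(unname(ft$values[f, p]),
                   sqrt(sum((xyz[ni, ] - xyz[ci, ])^2)), tolerance = 1e-10)
    }
  }
})

test_that("min_group_distance equals the exhaustive double loop", {
  set.seed(7)
  xyz <- matrix(rnorm(60), 20, 3)
  a <- 1:10; b <- 11:20
  brute <- Inf
  for (i in a) for (j in b)
    brute <- min(brute, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  expect_equal(min_group_distance(xyz, a, b), brute)
  ## min over a 2-atom group
  xyz2 <- rbind(c(0, 0, 0), c(3.1, 0, 0), c(2.5, 0, 0))
  expect_equal(min_group_distance(xyz2, 1, 2:3), 2.5)
  expect_error(min_group_distance(xyz2, integer(0), 1), "non-empty")
})

test_that("contact frequencies report replicate mean/SD and flag thresholds", {
  ## 100 frames; residue 10 in contact in 66, residue 20 in 64 -> only the
  ## former crosses the display threshold
  n <- 100
  atoms <- data.frame(name = c("L1", "CB", "CB"), resid = c(900L, 10L, 20L),
                      resname = c("LIG", "A", "A"),
                      segment = c("LIG", "P", "P"), element = "C")
  coords <- array(0, c(n, 3, 3))
  coords[, 2, 1] <- ifelse(seq_len(n) <= 66, 4, 8)
  coords[, 3, 1] <- ifelse(seq_len(n) <= 64, 4, 8)
  ens <- conformer_ensemble(coords, atoms)
  ens$frames$set <- rep(1:2, each = n / 2)
  res <- contact_frequencies(ens, ligand_idx = 1, resids = c(10, 20))
  expect_equal(res$mean, c(0.66, 0.64), tolerance = 1e-12)
  expect_identical(res$display, c(TRUE, FALSE))
  expect_identical(res$listed, c(TRUE, TRUE))
  ## always-in-contact residue: frequency 1, SD 0
  coords2 <- coords; coords2[, 2, 1] <- 4
  ens2 <- conformer_ensemble(coords2, atoms)
  ens2$frames$set <- rep(1:2, each = n / 2)
  r2 <- contact_frequencies(ens2, 1, 10)
  expect_equal(r2$mean, 1)
  expect_equal(r2$sd, 0)
  ens2$frames$weight <- rep(0, n)
  expect_error(contact_frequencies(ens2, 1, 10), "zero")
})

test_that("hydrogen-bond criterion distinguishes geometry and supports distance-only mode", {
  atoms <- data.frame(name = c("D", "H", "A"), resid = 1:3, resname = "X",
                      segment = "P", element = c("O", "H", "O"))
  good <- array(c(0, 1.0, 2.75,  0, 0, 0.1,  0, 0, 0), c(1, 3, 3))
  ens_good <- conformer_ensemble(good, atoms)
  expect_equal(hbond_frequency(ens_good, 1, 3, hydrogen_idx = 2), 1)
  far <- good; far[1, 3, 1] <- 4.5
  expect_equal(hbond_frequency(conformer_ensemble(far, atoms), 1, 3,
                               hydrogen_idx = 2), 0)
  ## bad angle (~90 deg): distance passes, angle fails
  bent <- good; bent[1, 3, ] <- c(1.0, 2.8, 0)
  expect_equal(hbond_frequency(conformer_ensemble(bent, atoms), 1, 3,
                               hydrogen_idx = 2), 0)
  expect_equal(hbond_frequency(conformer_ensemble(bent, atoms), 1, 3,
                               criterion = "distance"), 1)
  ## constructed 30% ensemble
  n <- 200
  co <- array(0, c(n, 3, 3))
  co[, 2, 1] <- 1
  co[, 3, 1] <- ifelse(seq_len(n) <= 60, 2.8, 5)
  expect_equal(hbond_frequency(conformer_ensemble(co, atoms), 1, 3,
                               hydrogen_idx = 2), 0.3)
})

test_that("subsegment COM distances match hand values and support mass weighting", {
  atoms <- data.frame(name = c("CA", "CA", "CA", "CA"), resid = c(1, 1, 2, 2),
                      resname = "A", segment = c("S1", "S1", "S2", "S2"),
                      element = c("C", "C", "C", "O"))
  xyz <- rbind(c(-5, 0, 0), c(-5, 0, 0), c(5, 0, 0), c(5, 0, 0))
  expect_equal(as.numeric(subsegment_com_distance(xyz, atoms, "S1", "S2")), 10)
  ## single-atom subsegments 8 A apart
  xyz2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(8, 0, 0), c(8, 0, 0))
  expect_equal(as.numeric(subsegment_com_distance(xyz2, atoms, 1, 2)), 8)
  ## mass weighting shifts the COM toward the oxygen
  xyz3 <- rbind(c(-5, 0, 0), c(-5, 0, 0), c(4, 0, 0), c(6, 0, 0))
  dm <- subsegment_com_distance(xyz3, atoms, "S1", "S2", mass_weighted = TRUE)
  expect_gt(as.numeric(dm), 10)
  expect_identical(attr(dm, "weighting"), "mass")
  expect_error(subsegment_com_distance(xyz, atoms, "S1", "NOPE"), "no heavy")
})

test_that("features are rigid-motion invariant except signed ring projections", {
  sspec <- default_toy_structure(n_states = 1, jitter_sd = 0.3, seed = 10)
  ens <- emit_coordinates(list(rep(1L, 3)), sspec)
  spec <- feature_spec(selection_cutoff = 12)
  pairs <- select_feature_residues(ens, spec)
  ft <- compute_feature_matrix(ens, pairs, spec)[[1]]
  ## rotation about the membrane normal (z): everything invariant
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ens_z <- ens
  for (f in 1:3)
    ens_z$coords[f, , ] <- matrix(ens$coords[f, , ], ncol = 3) %*% t(Rz) +
      matrix(c(3, -2, 7), dim(ens$coords)[2], 3, byrow = TRUE)
  ft_z <- compute_feature_matrix(ens_z, pairs, spec)[[1]]
  expect_equal(ft_z$values, ft$values, tolerance = 1e-8)
  ## rotation moving the normal: distances invariant, projections not
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  ens_x <- ens
  for (f in 1:3)
    ens_x$coords[f, , ] <- matrix(ens$coords[f, , ], ncol = 3) %*% t(Rx)
  ft_x <- compute_feature_matrix(ens_x, pairs, spec)[[1]]
  dist_cols <- seq_len(ncol(ft$values) - 2)
  expect_equal(ft_x$values[, dist_cols], ft$values[, dist_cols],
               tolerance = 1e-8)
  expect_gt(max(abs(ft_x$values[, "proj_ring5"] - ft$values[, "proj_ring5"])),
            0.1)
})
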