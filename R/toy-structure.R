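#' Specification of a toy 3-D structure ensemble
#'
#' Per-state coordinate templates for a pseudo system comprising a ligand
#' (pseudo-atoms named after a bitopic ligand's nitrogens, amide oxygen and
#' two rings), four pseudo-helical TM subsegments, a small shell of
#' binding-site residues carrying Cbeta atoms, and a flexible N-terminal
#' pseudo-loop with backbone atoms. Frames are emitted as the template of a
#' frame's hidden state plus isotropic Gaussian jitter.
#'
#' @param templates list (one per state) of n_atoms x 3 coordinate matrices
#'   sharing atom count and ordering.
#' @param atoms atom metadata data.frame matching the templates (columns
#'   `name`, `resid`, `resname`, `segment`, `element`).
#' @param jitter_sd per-atom isotropic Gaussian noise, Angstrom.
#' @param seed RNG seed for coordinate emission substreams.
#' @return object of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(templates, atoms, jitter_sd = 0.3, seed = 1L) {
  if (!length(templates)) stop2("at least one state template is required")
  na <- nrow(templates[[1]])
  for (tm in templates)
    if (!is.matrix(tm) || nrow(tm) != na || ncol(tm) != 3)
      stop2("all templates must be matrices with identical atom count and 3 columns")
  if (nrow(atoms) != na) stop2("atoms table must match template atom count")
  if (jitter_sd < 0) stop2("jitter_sd must be >= 0")
  if (is.null(atoms$heavy)) atoms$heavy <- atoms$element != "H"
  structure(list(templates = templates, atoms = atoms,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "toy_structure_spec")
}

## helix of backbone pseudo-atoms (CA only) around an axis through `center`
helix_coords <- function(center, n_res = 8, rise = 1.5, radius = 2.3) {
  t <- seq_len(n_res)
  cbind(center[1] + radius * cos(t * 100 * pi / 180),
        center[2] + radius * sin(t * 100 * pi / 180),
        center[3] + rise * (t - mean(t)))
}

## loop backbone (N, CA, C, O per residue) threaded along one of several
## qualitatively different curves; `shape` 1 = extended, 2 = arc,
## 3 = compact helix, 4+ = kinked variants. Distinct shapes keep a large
## pairwise RMSD even after optimal superposition.
loop_coords <- function(n_res, shape = 1, scale = 1) {
  t <- seq_len(n_res)
  ca <- switch(((shape - 1) %% 4) + 1,
    cbind(3.5 * t, 0 * t, 0 * t),
    cbind(14 * cos(pi * t / n_res), 14 * sin(pi * t / n_res), 0 * t),
    cbind(4.5 * cos(t * 100 * pi / 180), 4.5 * sin(t * 100 * pi / 180),
          1.5 * t),
    cbind(3.5 * pmin(t, n_res / 2),
          3.5 * pmax(0, t - n_res / 2), 0.5 * t))
  ca <- sweep(ca, 2, colMeans(ca)) * scale
  out <- matrix(0, n_res * 4, 3)
  for (r in seq_len(n_res)) {
    offs <- rbind(c(-1.2, 0.5, 0),     # N
                  c(0, 0, 0),          # CA
                  c(1.2, 0.4, 0.3),    # C
                  c(1.4, 1.5, 0.5))    # O
    out[(r - 1) * 4 + 1:4, ] <- sweep(offs, 2, ca[r, ], "+")
  }
  out
}

#' Default toy structure: ligand + subsegments + Cbeta shell + loop
#'
#' Builds per-state templates in which the ligand's secondary-pharmacophore
#' pseudo-atoms reorient between states, two of the four subsegment helices
#' shift apart, and the N-terminal pseudo-loop switches between distinct
#' backbone templates (large inter-template RMSD), emulating the structural
#' signatures the conformational-analysis and loop-clustering stages are
#' meant to detect.
#'
#' @param n_states number of hidden states.
#' @param n_loop_res residues in the pseudo-loop.
#' @param loop_separation approximate scale (Angstrom) of the inter-template
#'   loop difference.
#' @param subsegment_shift per-state outward shift (Angstrom) of the TM2e
#'   subsegment, changing designed subsegment COM distances.
#' @param jitter_sd,seed passed to [toy_structure_spec()].
#' @return a [toy_structure_spec()].
#' @export
default_toy_structure <- function(n_states = 3, n_loop_res = 12,
                                  loop_separation = 12, subsegment_shift = 2,
                                  jitter_sd = 0.3, seed = 1L) {
  lig_names <- c("N1", "N2", "N3", "N4", "Oamide",
                 paste0("C5", letters[1:5]), paste0("C6", letters[1:6]))
  lig_elem <- c(rep("N", 4), "O", rep("C", 11))
  seg_names <- c("TM1e", "TM2e", "TM3e", "TM7e")
  seg_centers <- rbind(c(-8, -8, 0), c(8, -8, 0), c(8, 8, 0), c(-8, 8, 0))
  n_seg_res <- 8
  shell_resid <- 101:106

  atoms <- data.frame(
    name = c(lig_names,
             rep("CA", length(seg_names) * n_seg_res),
             rep("CB", length(shell_resid)),
             rep(c("N", "CA", "C", "O"), n_loop_res)),
    resid = c(rep(900L, length(lig_names)),
              rep(seq_len(length(seg_names) * n_seg_res)) + 200L,
              shell_resid,
              rep(seq_len(n_loop_res), each = 4)),
    resname = c(rep("LIG", length(lig_names)),
                rep("ALA", length(seg_names) * n_seg_res),
                rep("ALA", length(shell_resid)),
                rep("GLY", n_loop_res * 4)),
    segment = c(rep("LIG", length(lig_names)),
                rep(seg_names, each = n_seg_res),
                rep("SHELL", length(shell_resid)),
                rep("NT", n_loop_res * 4)),
    element = c(lig_elem,
                rep("C", length(seg_names) * n_seg_res),
                rep("C", length(shell_resid)),
                rep(c("N", "C", "C", "O"), n_loop_res)))

  ## build per-state loop shapes first and rescale them so the smallest
  ## inter-template superposed RMSD equals loop_separation
  loops <- lapply(seq_len(n_states), function(s)
    loop_coords(n_loop_res, shape = s))
  if (n_states > 1) {
    flat <- t(vapply(loops, function(m) as.numeric(t(m)),
                     numeric(n_loop_res * 4 * 3)))
    D <- pairwise_rmsd_cpp(flat, n_loop_res * 4L)
    min_sep <- min(D[upper.tri(D)])
    loops <- lapply(loops, function(m) m * (loop_separation / min_sep))
  }

  templates <- lapply(seq_len(n_states), function(s) {
    lig <- rbind(c(0, 0, -6), c(1.5, 0, -5), c(3, 1, 2), c(4, 1, 3 + s),
                 c(3.5, 2, 1.5),
                 helix_coords(c(4.5, 1, 3 + s), 5, 0.8, 1.1),
                 helix_coords(c(5.5, 2, 3 + s), 6, 0.8, 1.4))
    centers <- seg_centers
    centers[2, ] <- centers[2, ] + c(subsegment_shift * (s - 1), 0, 0)
    segs <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      helix_coords(centers[i, ], n_seg_res)))
    shell <- cbind(5 + 0.5 * seq_along(shell_resid), -2, 2 * (s - 1))
    loop <- sweep(loops[[s]], 2, c(-20, 10, 5), "+")
    rbind(lig, segs, shell, loop)
  })
  toy_structure_spec(templates, atoms, jitter_sd = jitter_sd, seed = seed)
}

#' Emit a toy coordinate ensemble from hidden-state sequences
#'
#' Each frame's coordinates are its hidden state's template plus isotropic
#' Gaussian jitter; frames carry trajectory id, frame index and the hidden
#' state label.
#'
#' @param states list of hidden-state index vectors.
#' @param spec a [toy_structure_spec()].
#' @param stride keep every `stride`-th frame (coordinate ensembles are
#'   usually analysed on a subsample).
#' @param dt time per (unstrided) frame, ns; stored per frame as `time`.
#' @return a [conformer_ensemble()] with `state` labels.
#' @export
emit_coordinates <- function(states, spec, stride = 1L, dt = 1) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  n_states_seen <- max(unlist(states))
  if (n_states_seen > length(spec$templates))
    stop2("missing structure template for state ", n_states_seen)
  na <- nrow(spec$templates[[1]])
  frames <- do.call(rbind, lapply(seq_along(states), function(i) {
    idx <- seq(1L, length(states[[i]]), by = stride)
    data.frame(traj = i, frame = idx - 1L, time = (idx - 1L) * dt,
               state = states[[i]][idx])
  }))
  coords <- array(0, c(nrow(frames), na, 3))
  row <- 1L
  for (i in seq_along(states)) {
    set.seed(substream_seed(spec$seed, 3L, i))
    idx <- seq(1L, length(states[[i]]), by = stride)
    for (t in idx) {
      jit <- if (spec$jitter_sd > 0)
        matrix(rnorm(na * 3, sd = spec$jitter_sd), na, 3) else 0
      coords[row, , ] <- spec$templates[[states[[i]][t]]] + jit
      row <- row + 1L
    }
  }
  conformer_ensemble(coords, spec$atoms, frames)
}
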