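#' Feature specification for binding-mode featurization
#'
#' Defines the geometric observables describing a bitopic ligand's pose:
#' distances from ligand nitrogen atoms to the Cbeta atoms of nearby
#' binding-site residues, intramolecular distances anchored on the indole
#' nitrogen, and signed projections of ring-COM-to-N4 vectors onto the
#' membrane normal.
#'
#' @param ligand_nitrogens atom names of the ligand nitrogens (N1..N4).
#' @param selection_cutoff Angstrom; residues whose Cbeta lies within this
#'   distance of any ligand nitrogen in the reference frame are selected
#'   (boundary inclusive).
#' @param intramolecular_pairs list of 2-vectors of ligand atom names.
#' @param ring_definitions named list of member-atom name vectors (>= 3
#'   atoms each) for the ligand rings.
#' @param ring_reference ligand atom from which ring-COM vectors are drawn.
#' @param membrane_normal unit 3-vector.
#' @param cb_name atom name carrying the residue side-chain reference.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(ligand_nitrogens = c("N1", "N2", "N3", "N4"),
                         selection_cutoff = 7.0,
                         intramolecular_pairs = list(c("N4", "N3"),
                                                     c("N4", "Oamide")),
                         ring_definitions = list(
                           ring5 = paste0("C5", letters[1:5]),
                           ring6 = paste0("C6", letters[1:6])),
                         ring_reference = "N4",
                         membrane_normal = c(0, 0, 1),
                         cb_name = "CB") {
  if (selection_cutoff <= 0) stop2("selection_cutoff must be positive")
  nrm <- sqrt(sum(membrane_normal^2))
  if (abs(nrm - 1) > 1e-9)
    membrane_normal <- membrane_normal / nrm
  for (r in ring_definitions)
    if (length(r) < 3) stop2("ring definitions need at least 3 member atoms")
  structure(list(ligand_nitrogens = ligand_nitrogens,
                 selection_cutoff = selection_cutoff,
                 intramolecular_pairs = intramolecular_pairs,
                 ring_definitions = ring_definitions,
                 ring_reference = ring_reference,
                 membrane_normal = membrane_normal,
                 cb_name = cb_name),
            class = "feature_spec")
}

atom_index <- function(ens, name, resid = NULL, segment = NULL) {
  sel <- ens$atoms$name %in% name
  if (!is.null(resid)) sel <- sel & ens$atoms$resid %in% resid
  if (!is.null(segment)) sel <- sel & ens$atoms$segment %in% segment
  which(sel)
}

#' Select binding-site residues by Cbeta proximity to ligand nitrogens
#'
#' A (nitrogen, residue) pair is retained iff the residue's Cbeta lies within
#' `selection_cutoff` (<=, boundary inclusive) of that nitrogen in the given
#' reference frame. Output ordered by residue id, then nitrogen index, so the
#' resulting feature layout is deterministic.
#'
#' @param ens a [conformer_ensemble()] containing ligand and Cbeta atoms.
#' @param spec a [feature_spec()].
#' @param frame reference frame index (1-based) used for the selection.
#' @param candidate_resids residues to consider (default: all with a Cbeta).
#' @return data.frame with columns `nitrogen`, `resid`, `distance`.
#' @export
select_feature_residues <- function(ens, spec, frame = 1L,
                                    candidate_resids = NULL) {
  xyz <- frame_coords(ens, frame)
  cb_idx <- atom_index(ens, spec$cb_name)
  if (!is.null(candidate_resids)) {
    missing <- setdiff(candidate_resids, ens$atoms$resid[cb_idx])
    if (length(missing))
      stop2("candidate residue(s) without a ", spec$cb_name, " atom: ",
            paste(missing, collapse = ", "))
    cb_idx <- cb_idx[ens$atoms$resid[cb_idx] %in% candidate_resids]
  }
  out <- list()
  for (r in cb_idx) {
    for (ni in seq_along(spec$ligand_nitrogens)) {
      n_idx <- atom_index(ens, spec$ligand_nitrogens[ni], segment = "LIG")
      if (!length(n_idx))
        n_idx <- atom_index(ens, spec$ligand_nitrogens[ni])
      if (!length(n_idx))
        stop2("ligand nitrogen atom ", spec$ligand_nitrogens[ni], " not found")
      d <- sqrt(sum((xyz[r, ] - xyz[n_idx[1], ])^2))
      if (d <= spec$selection_cutoff)
        out[[length(out) + 1L]] <- data.frame(
          nitrogen = spec$ligand_nitrogens[ni],
          resid = ens$atoms$resid[r], distance = d)
    }
  }
  if (!length(out))
    return(data.frame(nitrogen = character(), resid = integer(),
                      distance = numeric()))
  res <- do.call(rbind, out)
  res[order(res$resid, match(res$nitrogen, spec$ligand_nitrogens)), ,
      drop = FALSE]
}

#' Compute the per-frame feature matrix from coordinates
#'
#' Columns in fixed order: Cbeta-nitrogen distances for the selected pairs,
#' the intramolecular distances, then for each ring the scalar projection of
#' (reference atom - ring COM) onto the membrane normal. COM is the
#' unweighted mean of the ring's member heavy atoms. Units Angstrom.
#'
#' @param ens a [conformer_ensemble()].
#' @param pairs selected (nitrogen, residue) pairs from
#'   [select_feature_residues()].
#' @param spec a [feature_spec()].
#' @return list of [feature_traj()], one per trajectory in `ens`.
#' @export
compute_feature_matrix <- function(ens, pairs, spec) {
  if (!nrow(pairs) && !length(spec$intramolecular_pairs) &&
      !length(spec$ring_definitions))
    stop2("no features requested")
  nm <- character(0); ia <- integer(0); ib <- integer(0)
  for (p in seq_len(nrow(pairs))) {
    ni <- atom_index(ens, pairs$nitrogen[p])[1]
    ci <- atom_index(ens, spec$cb_name, resid = pairs$resid[p])[1]
    ia <- c(ia, ni); ib <- c(ib, ci)
    nm <- c(nm, paste0(pairs$nitrogen[p], "_res", pairs$resid[p]))
  }
  for (ip in spec$intramolecular_pairs) {
    ia <- c(ia, atom_index(ens, ip[1])[1])
    ib <- c(ib, atom_index(ens, ip[2])[1])
    nm <- c(nm, paste(ip[1], ip[2], sep = "_"))
  }
  ring_idx <- lapply(spec$ring_definitions, function(r) {
    idx <- atom_index(ens, r)
    idx[ens$atoms$heavy[idx]]
  })
  ref_idx <- atom_index(ens, spec$ring_reference)[1]
  nmr <- paste0("proj_", names(spec$ring_definitions) %||%
                  seq_along(spec$ring_definitions))

  nf <- n_frames(ens)
  vals <- matrix(0, nf, length(nm) + length(ring_idx))
  for (f in seq_len(nf)) {
    xyz <- matrix(ens$coords[f, , ], ncol = 3)
    if (length(ia))
      vals[f, seq_along(ia)] <-
        sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2))
    for (ri in seq_along(ring_idx)) {
      com <- colMeans(xyz[ring_idx[[ri]], , drop = FALSE])
      vals[f, length(ia) + ri] <-
        sum((xyz[ref_idx, ] - com) * spec$membrane_normal)
    }
  }
  colnames(vals) <- c(nm, nmr)
  dt <- if (!is.null(ens$frames$time) && nrow(ens$frames) > 1) {
    dts <- diff(ens$frames$time[ens$frames$traj == ens$frames$traj[1]])
    if (length(dts) && dts[1] > 0) dts[1] else 1
  } else 1
  lapply(split(seq_len(nf), ens$frames$traj), function(idx)
    feature_traj(vals[idx, , drop = FALSE], colnames(vals), dt = dt,
                 id = ens$frames$traj[idx[1]]))
}

#' Minimum cross-pair distance between two atom groups
#'
#' @param xyz frame coordinate matrix (atoms x 3).
#' @param group_a,group_b non-empty atom index vectors.
#' @return minimum Euclidean distance, Angstrom.
#' @export
min_group_distance <- function(xyz, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop2("atom groups must be non-empty")
  d2 <- outer(seq_along(group_a), seq_along(group_b),
              Vectorize(function(i, j)
                sum((xyz[group_a[i], ] - xyz[group_b[j], ])^2)))
  sqrt(min(d2))
}

#' Ligand-residue contact frequencies with replicate-set uncertainty
#'
#' Per replicate set, a residue's frequency is the weighted fraction of
#' frames in which the minimum heavy-atom distance between the ligand and
#' the residue is within `cutoff`. Mean and SD are reported over the
#' replicate sets, with flags for the listing (>= 25%) and figure-display
#' (>= 65%) thresholds.
#'
#' @param ens a [conformer_ensemble()] whose `frames` carry a `set`
#'   (replicate id) column and optionally `weight`.
#' @param ligand_idx heavy-atom indices of the ligand.
#' @param resids residue ids to report.
#' @param cutoff contact cutoff, Angstrom (default 5.0).
#' @param list_threshold,display_threshold flag thresholds (fractions).
#' @return data.frame: resid, mean, sd, listed, display.
#' @export
contact_frequencies <- function(ens, ligand_idx, resids, cutoff = 5.0,
                                list_threshold = 0.25,
                                display_threshold = 0.65) {
  w <- ens$frames$weight %||% rep(1, n_frames(ens))
  if (all(w == 0)) stop2("all frame weights are zero")
  sets <- ens$frames$set %||% rep(1L, n_frames(ens))
  lig_heavy <- ligand_idx[ens$atoms$heavy[ligand_idx]]
  out <- lapply(resids, function(r) {
    r_idx <- which(ens$atoms$resid == r & ens$atoms$heavy)
    if (!length(r_idx)) stop2("residue ", r, " has no heavy atoms")
    freqs <- vapply(unique(sets), function(s) {
      fi <- which(sets == s)
      contact <- vapply(fi, function(f) {
        xyz <- matrix(ens$coords[f, , ], ncol = 3)
        min_group_distance(xyz, lig_heavy, r_idx) <= cutoff
      }, logical(1))
      sum(w[fi] * contact) / sum(w[fi])
    }, numeric(1))
    data.frame(resid = r, mean = mean(freqs),
               sd = if (length(freqs) > 1) sd(freqs) else 0)
  })
  res <- do.call(rbind, out)
  res$listed <- res$mean >= list_threshold
  res$display <- res$mean >= display_threshold
  res
}

#' Hydrogen-bond frequency under a configurable geometric criterion
#'
#' Default criterion: donor-acceptor heavy-atom distance <= 3.5 Angstrom and
#' donor-H...acceptor angle >= 120 degrees. A distance-only mode (minimum
#' heavy-atom distance <= cutoff) is available for analyses where no
#' hydrogen positions exist.
#'
#' @param ens a [conformer_ensemble()].
#' @param donor_idx,acceptor_idx atom indices (heavy atoms).
#' @param hydrogen_idx index of the donor hydrogen (required for the
#'   `"distance_angle"` criterion).
#' @param criterion `"distance_angle"` or `"distance"`.
#' @param dist_cutoff Angstrom; `angle_cutoff` degrees.
#' @return weighted fraction of frames satisfying the criterion.
#' @export
hbond_frequency <- function(ens, donor_idx, acceptor_idx, hydrogen_idx = NULL,
                            criterion = c("distance_angle", "distance"),
                            dist_cutoff = 3.5, angle_cutoff = 120) {
  criterion <- match.arg(criterion)
  if (criterion == "distance_angle" && is.null(hydrogen_idx))
    stop2("the distance_angle criterion requires a donor hydrogen index")
  w <- ens$frames$weight %||% rep(1, n_frames(ens))
  hits <- vapply(seq_len(n_frames(ens)), function(f) {
    xyz <- matrix(ens$coords[f, , ], ncol = 3)
    d <- min_group_distance(xyz, donor_idx, acceptor_idx)
    if (d > dist_cutoff) return(FALSE)
    if (criterion == "distance") return(TRUE)
    h <- xyz[hydrogen_idx[1], ]
    v1 <- xyz[donor_idx[1], ] - h
    v2 <- xyz[acceptor_idx[1], ] - h
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    ang >= angle_cutoff
  }, logical(1))
  sum(w * hits) / sum(w)
}

#' Distance between the centers of mass of two helix subsegments
#'
#' Euclidean distance between the COMs of the two subsegments' heavy atoms;
#' unweighted by default, mass-weighted optionally (flagged in the result's
#' `weighting` attribute).
#'
#' @param xyz frame coordinate matrix (atoms x 3).
#' @param atoms atom metadata data.frame aligned with `xyz`.
#' @param seg_a,seg_b segment names or residue-id vectors.
#' @param mass_weighted logical.
#' @return distance in Angstrom with attribute `weighting`.
#' @export
subsegment_com_distance <- function(xyz, atoms, seg_a, seg_b,
                                    mass_weighted = FALSE) {
  heavy <- atoms$heavy %||% (atoms$element != "H")
  resolve <- function(seg) {
    idx <- if (is.character(seg)) which(atoms$segment %in% seg)
           else which(atoms$resid %in% seg)
    idx <- idx[heavy[idx]]
    if (!length(idx)) stop2("subsegment resolves to no heavy atoms")
    idx
  }
  com <- function(idx) {
    if (mass_weighted) {
      m <- atom_masses(atoms$element[idx])
      colSums(xyz[idx, , drop = FALSE] * m) / sum(m)
    } else colMeans(xyz[idx, , drop = FALSE])
  }
  d <- sqrt(sum((com(resolve(seg_a)) - com(resolve(seg_b)))^2))
  attr(d, "weighting") <- if (mass_weighted) "mass" else "unweighted"
  d
}

atom_masses <- function(elements) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  out <- m[elements]
  out[is.na(out)] <- 12.011
  unname(out)
}
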