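backbone_atom_idx <- function(ens, residues, segment = NULL,
                              atom_names = c("N", "CA", "C", "O")) {
  at <- ens$atoms
  sel <- at$resid %in% residues & at$name %in% atom_names
  if (!is.null(segment)) sel <- sel & at$segment %in% segment
  idx <- which(sel)
  if (!length(idx)) stop2("no backbone atoms resolve for the residue selection")
  idx
}

flatten_coords <- function(ens, atom_idx) {
  nf <- n_frames(ens)
  out <- matrix(0, nf, 3 * length(atom_idx))
  for (k in 1:3)
    out[, seq(k, by = 3, length.out = length(atom_idx))] <-
      ens$coords[, atom_idx, k]
  out
}

#' Iterative RMSF-based residue filter for loop clustering
#'
#' Repeats: superimpose all frames on the current residue set (least-squares
#' on backbone atoms, against the ensemble mean structure), compute
#' per-residue RMSF about the mean, drop residues above the cutoff; until
#' no residue is dropped. Residue ranges chosen a priori can bypass the
#' filter by being passed directly to the downstream functions.
#'
#' @param ens a [conformer_ensemble()] with loop backbone atoms.
#' @param residues initial residue ids (>= 3).
#' @param rmsf_cutoff Angstrom (default 5.0).
#' @param segment optional segment restriction (e.g. `"NT"`).
#' @return list: `retained` residue ids, `history` (data.frame of iteration,
#'   residue, rmsf, dropped).
#' @export
iterative_rmsf_filter <- function(ens, residues, rmsf_cutoff = 5.0,
                                  segment = NULL) {
  if (n_frames(ens) < 2) stop2("at least 2 frames are required")
  retained <- sort(unique(residues))
  history <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    if (length(retained) < 3)
      stop2("fewer than 3 residues remain; superposition is ill-posed")
    idx <- backbone_atom_idx(ens, retained, segment)
    flat <- flatten_coords(ens, idx)
    ## iterate mean-structure superposition once (converges very quickly)
    ref <- matrix(colMeans(flat), ncol = 3, byrow = TRUE)
    for (pass in 1:2) {
      flat <- superpose_cpp(flat, ref, seq_along(idx))
      ref <- matrix(colMeans(flat), ncol = 3, byrow = TRUE)
    }
    resid_of <- ens$atoms$resid[idx]
    dev2 <- sweep(flat, 2, colMeans(flat))^2
    atom_msf <- vapply(seq_along(idx), function(a)
      mean(rowSums(dev2[, 3 * (a - 1) + 1:3, drop = FALSE])), numeric(1))
    rmsf <- vapply(retained, function(r)
      sqrt(mean(atom_msf[resid_of == r])), numeric(1))
    drop <- retained[rmsf > rmsf_cutoff]
    history[[it]] <- data.frame(iteration = it, residue = retained,
                                rmsf = rmsf, dropped = retained %in% drop)
    if (!length(drop)) break
    retained <- setdiff(retained, drop)
  }
  list(retained = retained, history = do.call(rbind, history))
}

#' Pairwise minimum RMSD matrix over selected loop residues
#'
#' For every frame pair, the selected residues' backbone atoms are optimally
#' superimposed (least squares) and the RMSD over the same atoms reported.
#' Symmetric with a zero diagonal.
#'
#' @param ens a [conformer_ensemble()].
#' @param residues residue ids defining the selection.
#' @param segment optional segment restriction.
#' @return n_frames x n_frames numeric matrix, Angstrom.
#' @export
pairwise_rmsd_matrix <- function(ens, residues, segment = NULL) {
  idx <- backbone_atom_idx(ens, residues, segment)
  pairwise_rmsd_cpp(flatten_coords(ens, idx), length(idx))
}

#' Ward clustering with an intra-cluster RMSD stopping rule
#'
#' Ward linkage on the pairwise RMSD matrix; the number of clusters is the
#' smallest `k` such that every cluster has mean intra-cluster pairwise RMSD
#' at most `rmsd_limit`, unless the cluster holds less than
#' `small_cluster_frac` of all frames (small outlier clusters are exempt
#' from the rule rather than forcing further splits).
#'
#' @param D pairwise RMSD matrix.
#' @param rmsd_limit Angstrom (default 5.0).
#' @param small_cluster_frac exemption size fraction (default 0.05).
#' @param max_k largest cluster count tried.
#' @return integer vector of cluster labels (1-based, relabeled by
#'   decreasing cluster size), with attribute `k`.
#' @export
ward_cluster_cut <- function(D, rmsd_limit = 5.0, small_cluster_frac = 0.05,
                             max_k = nrow(D)) {
  n <- nrow(D)
  if (all(D == 0)) {
    labels <- rep(1L, n)
    attr(labels, "k") <- 1L
    return(labels)
  }
  hc <- hclust(as.dist(D), method = "ward.D2")
  for (k in seq_len(max_k)) {
    labels <- cutree(hc, k)
    ok <- vapply(seq_len(k), function(cl) {
      mem <- which(labels == cl)
      if (length(mem) < small_cluster_frac * n) return(TRUE)
      if (length(mem) < 2) return(TRUE)
      sub <- D[mem, mem]
      mean(sub[upper.tri(sub)]) <= rmsd_limit
    }, logical(1))
    if (all(ok)) break
  }
  ## relabel by decreasing size (stable, deterministic)
  sizes <- table(labels)
  new_id <- integer(k)
  new_id[order(-as.integer(sizes), as.integer(names(sizes)))] <- seq_len(k)
  labels <- new_id[labels]
  attr(labels, "k") <- k
  labels
}

#' Reweight cluster populations by metastable-state probabilities
#'
#' Each frame's weight is `pi_MS(its MS) / n_sampled(its MS)`, so a
#' metastable state's total weight equals its equilibrium probability
#' regardless of how many of its frames entered the sample. Cluster
#' populations are the summed member weights, normalized to 100%.
#'
#' @param labels cluster labels per frame.
#' @param frame_ms metastable-state id per frame.
#' @param pi_ms named or positional vector of equilibrium probabilities.
#' @return data.frame: cluster, raw_pct, reweighted_pct.
#' @export
reweight_populations <- function(labels, frame_ms, pi_ms) {
  if (length(labels) != length(frame_ms))
    stop2("labels and frame_ms must have equal length")
  ms_levels <- sort(unique(frame_ms))
  pi_of <- if (!is.null(names(pi_ms))) pi_ms[as.character(ms_levels)]
           else pi_ms[ms_levels]
  if (anyNA(pi_of)) stop2("frame mapped to a metastable state with unknown pi")
  n_ms <- table(factor(frame_ms, levels = ms_levels))
  w <- as.numeric(pi_of[match(frame_ms, ms_levels)]) /
    as.numeric(n_ms[match(frame_ms, ms_levels)])
  agg <- tapply(w, labels, sum)
  raw <- table(labels) / length(labels) * 100
  data.frame(cluster = as.integer(names(agg)),
             raw_pct = as.numeric(raw),
             reweighted_pct = as.numeric(agg) / sum(agg) * 100)
}

#' Representative frames of each cluster
#'
#' The medoid (minimum summed RMSD to its cluster) plus the `n_extra`
#' frames nearest to it, for ensemble-style depictions of each loop
#' conformation.
#'
#' @param D pairwise RMSD matrix; `labels` cluster labels.
#' @param n_extra neighbours beyond the medoid (default 4).
#' @return list per cluster of frame indices (medoid first).
#' @export
cluster_representatives <- function(D, labels, n_extra = 4) {
  lapply(sort(unique(labels)), function(cl) {
    mem <- which(labels == cl)
    med <- mem[which.min(rowSums(D[mem, mem, drop = FALSE]))]
    near <- mem[order(D[med, mem])]
    near <- setdiff(near, med)
    c(med, head(near, n_extra))
  })
}

#' Loop-conformation clustering report
#'
#' End-to-end driver: optional RMSF filtering, pairwise RMSD, Ward
#' clustering with the size/RMSD rule, metastable-state reweighting, and
#' representative frames; mirrors a three-largest-clusters summary table.
#'
#' @param ens a [conformer_ensemble()] of sampled loop frames whose `frames`
#'   table carries an `ms` column.
#' @param residues residue ids (post-filter, or initial if `filter = TRUE`).
#' @param pi_ms equilibrium probabilities per metastable state.
#' @param filter run [iterative_rmsf_filter()] first.
#' @param segment optional segment restriction.
#' @param rmsd_limit,small_cluster_frac passed to [ward_cluster_cut()].
#' @return object of class `loop_cluster_result`.
#' @export
loop_cluster_analysis <- function(ens, residues, pi_ms, filter = FALSE,
                                  segment = NULL, rmsd_limit = 5.0,
                                  small_cluster_frac = 0.05) {
  retained <- if (filter)
    iterative_rmsf_filter(ens, residues, rmsf_cutoff = rmsd_limit,
                          segment = segment)$retained
  else sort(unique(residues))
  D <- pairwise_rmsd_matrix(ens, retained, segment)
  labels <- ward_cluster_cut(D, rmsd_limit, small_cluster_frac)
  pops <- reweight_populations(as.integer(labels), ens$frames$ms, pi_ms)
  intra <- vapply(sort(unique(as.integer(labels))), function(cl) {
    mem <- which(labels == cl)
    if (length(mem) < 2) return(0)
    sub <- D[mem, mem]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  structure(list(retained = retained, labels = as.integer(labels),
                 k = attr(labels, "k"), populations = pops,
                 intra_rmsd = intra,
                 representatives = cluster_representatives(D, labels),
                 rmsd_matrix = D),
            class = "loop_cluster_result")
}

#' @export
print.loop_cluster_result <- function(x, ...) {
  cat("<loop_cluster_result>", x$k, "clusters on",
      length(x$labels), "frames; residues:",
      paste(range(x$retained), collapse = "-"), "\n")
  top <- x$populations[order(-x$populations$reweighted_pct), ][
    seq_len(min(3, nrow(x$populations))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  cluster %d: %.1f%% (raw %.1f%%)\n", top$cluster[i],
                top$reweighted_pct[i], top$raw_pct[i]))
  invisible(x)
}
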