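#' Per-frame feature trajectory
#'
#' A frames x features matrix of geometric observables (Angstrom) sampled at
#' a fixed time step, the unit of data entering TICA and the Markov state
#' model stages.
#'
#' @param values numeric matrix, frames in rows, features in columns.
#' @param feature_names character vector naming the columns.
#' @param dt time per frame in nanoseconds.
#' @param id trajectory identifier.
#' @return object of class `feature_traj`.
#' @export
feature_traj <- function(values, feature_names = colnames(values),
                         dt = 1, id = 1L) {
  values <- as.matrix(values)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(values)))
  if (length(feature_names) != ncol(values))
    stop2("feature_names length must equal the number of feature columns")
  if (anyNA(values)) stop2("feature values must not contain missing values")
  if (dt <= 0) stop2("dt must be positive")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 dt = dt, id = id),
            class = "feature_traj")
}

#' @export
print.feature_traj <- function(x, ...) {
  cat("<feature_traj> id", x$id, ":", nrow(x$values), "frames x",
      ncol(x$values), "features, dt =", x$dt, "ns\n")
  invisible(x)
}

#' Labeled 3-D coordinate ensemble
#'
#' Holds frame coordinates (frames x atoms x 3, Angstrom) plus atom metadata
#' and per-frame labels. This is the container consumed by the featurization,
#' conformational-analysis and loop-clustering stages.
#'
#' @param coords numeric array of dimension (frames, atoms, 3).
#' @param atoms data.frame with one row per atom; expected columns
#'   `name`, `resid`, `resname`, `segment`, `element`, `heavy`.
#' @param frames data.frame with one row per frame; at least `traj` and
#'   `frame` columns, optionally `state` (hidden/metastable label) and
#'   `weight` (non-negative).
#' @return object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(coords, atoms, frames = NULL) {
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    stop2("coords must be a (frames, atoms, 3) array")
  if (nrow(atoms) != d[2])
    stop2("atoms table must have one row per atom (", d[2], ")")
  if (is.null(frames))
    frames <- data.frame(traj = 1L, frame = seq_len(d[1]) - 1L)
  if (nrow(frames) != d[1])
    stop2("frames table must have one row per frame (", d[1], ")")
  if (!is.null(frames$weight) && any(frames$weight < 0))
    stop2("frame weights must be non-negative")
  if (is.null(atoms$heavy)) atoms$heavy <- atoms$element != "H"
  structure(list(coords = coords, atoms = atoms, frames = frames),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble>", dim(x$coords)[1], "frames x",
      dim(x$coords)[2], "atoms (",
      length(unique(x$frames$traj)), "trajectories )\n")
  invisible(x)
}

n_frames <- function(ens) dim(ens$coords)[1]

frame_coords <- function(ens, i) {
  matrix(ens$coords[i, , ], ncol = 3,
         dimnames = list(ens$atoms$name, c("x", "y", "z")))
}

#' Subset an ensemble by frame index
#'
#' @param ens a [conformer_ensemble()].
#' @param idx integer frame indices to keep.
#' @return a `conformer_ensemble` with the selected frames.
#' @export
subset_frames <- function(ens, idx) {
  conformer_ensemble(ens$coords[idx, , , drop = FALSE], ens$atoms,
                     ens$frames[idx, , drop = FALSE])
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Minimal PDB writer for toy ensembles (one MODEL per frame, ATOM records
#' only); intended for visual inspection of representative frames.
#'
#' @param ens a [conformer_ensemble()].
#' @param path output file path.
#' @param frames frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, frames = seq_len(n_frames(ens))) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- ens$atoms
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frame_coords(ens, frames[m])
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), substr(at$name, 1, 4), substr(at$resname, 1, 3),
      at$resid, xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write/read feature trajectories as columnar text
#'
#' One tab-separated file per trajectory, header row of feature names; the
#' interchange format for pre-computed feature tables.
#'
#' @param traj a [feature_traj()].
#' @param path file path.
#' @return `path` (write) or a `feature_traj` (read).
#' @export
write_feature_traj <- function(traj, path) {
  utils::write.table(traj$values, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_traj
#' @param dt,id passed to [feature_traj()] on read.
#' @export
read_feature_traj <- function(path, dt = 1, id = 1L) {
  v <- as.matrix(utils::read.delim(path, check.names = FALSE))
  feature_traj(v, colnames(v), dt = dt, id = id)
}
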