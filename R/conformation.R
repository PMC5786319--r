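#' Draw structural frames weighted by Bayesian model samples
#'
#' For each of `n_sets` replicate sets and each transition-matrix sample in
#' the ensemble, `frames_per_sample` frames are drawn per metastable state:
#' the microstate is chosen with probability proportional to that sample's
#' stationary vector restricted to the state's (filtered) microstates, and
#' the frame uniformly within the chosen microstate. The replicate sets are
#' what the mean +/- SD of downstream contact and distance statistics are
#' computed over.
#'
#' @param ensemble a [bayesian_sample()] result.
#' @param partition a [metastable_partition()] (its filtered `frame_sets`
#'   are the eligible frames).
#' @param frames_per_sample frames drawn per sample per MS (default 3).
#' @param n_sets replicate sets (default 3).
#' @param seed RNG seed.
#' @return data.frame: set, sample, ms, microstate, traj, frame.
#' @export
draw_frames_by_ensemble <- function(ensemble, partition,
                                    frames_per_sample = 3, n_sets = 3,
                                    seed = 1L) {
  a <- ensemble$active_set
  out <- list()
  for (s in seq_len(n_sets)) {
    set.seed(substream_seed(seed, 11L, s))
    for (b in seq_along(ensemble$samples)) {
      pi_b <- ensemble$samples[[b]]$pi
      for (m in seq_along(partition$frame_sets)) {
        fs <- partition$frame_sets[[m]]
        if (!nrow(fs)) {
          if (s == 1 && b == 1)
            warning("metastable state ", m, " has no eligible frames; skipped",
                    call. = FALSE)
          next
        }
        mis <- unique(fs$microstate)           # active-set positions
        w <- pi_b[mis]
        pick_mi <- mis[sample.int(length(mis), frames_per_sample,
                                  replace = TRUE, prob = w)]
        for (mi in pick_mi) {
          cand <- which(fs$microstate == mi)
          row <- fs[cand[sample.int(length(cand), 1)], ]
          out[[length(out) + 1L]] <- data.frame(
            set = s, sample = b, ms = m, microstate = mi,
            traj = row$traj, frame = row$frame)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Allocate frame draws proportionally to equilibrium probabilities
#'
#' Per-MS sample counts are `total * pi_MS` rounded with the
#' largest-remainder rule so the counts sum exactly to `total`.
#'
#' @param pi_ms equilibrium probability vector (sums to 1).
#' @param total total number of samples (default 3000).
#' @return integer vector of per-MS counts summing to `total`.
#' @export
proportional_counts <- function(pi_ms, total = 3000) {
  raw <- total * pi_ms / sum(pi_ms)
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    add <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  as.integer(counts)
}

#' Draw frames across metastable states proportional to pi_MS
#'
#' Combines [proportional_counts()] with per-MS microstate draws weighted by
#' the maximum-likelihood stationary vector.
#'
#' @param ensemble a [bayesian_sample()] result.
#' @param partition a [metastable_partition()].
#' @param total total frames (default 3000).
#' @param seed RNG seed.
#' @return data.frame: ms, microstate, traj, frame.
#' @export
draw_frames_proportional <- function(ensemble, partition, total = 3000,
                                     seed = 1L) {
  counts <- proportional_counts(partition$pi_ms$pi, total)
  pi_ml <- ensemble$ml$pi
  set.seed(substream_seed(seed, 12L))
  out <- list()
  for (m in seq_along(counts)) {
    fs <- partition$frame_sets[[m]]
    if (!nrow(fs) || counts[m] == 0) next
    mis <- unique(fs$microstate)
    pick_mi <- mis[sample.int(length(mis), counts[m], replace = TRUE,
                              prob = pi_ml[mis])]
    for (mi in pick_mi) {
      cand <- which(fs$microstate == mi)
      row <- fs[cand[sample.int(length(cand), 1)], ]
      out[[length(out) + 1L]] <- data.frame(
        ms = m, microstate = mi, traj = row$traj, frame = row$frame)
    }
  }
  do.call(rbind, out)
}

#' Per-metastable-state distributions of a structural observable
#'
#' Evaluates `observable` (a function of a frame coordinate matrix and the
#' atom table, returning one or two numbers) on every drawn frame and
#' summarizes per metastable state: weighted mean, SD, and a normalized
#' histogram (or paired 2-D values for two-number observables).
#'
#' @param sample frame draw table (from [draw_frames_by_ensemble()] or
#'   [draw_frames_proportional()]).
#' @param ens the [conformer_ensemble()] the draws refer to (matched on
#'   traj and frame columns).
#' @param observable `function(xyz, atoms) -> numeric(1 or 2)`.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list per MS: `values` (matrix), `mean`, `sd`, `hist` (for 1-D).
#' @export
ms_distance_distributions <- function(sample, ens, observable, breaks = 30) {
  key_ens <- paste(ens$frames$traj, ens$frames$frame)
  idx <- match(paste(sample$traj, sample$frame), key_ens)
  if (anyNA(idx)) stop2("sampled frames missing from the ensemble")
  w <- sample$weight %||% rep(1, nrow(sample))
  out <- list()
  for (m in sort(unique(sample$ms %||% rep(1L, nrow(sample))))) {
    rows <- which((sample$ms %||% rep(1L, nrow(sample))) == m)
    vals <- t(vapply(rows, function(r) {
      v <- observable(matrix(ens$coords[idx[r], , ], ncol = 3), ens$atoms)
      if (length(v) == 1) c(v, NA_real_) else v[1:2]
    }, numeric(2)))
    one_d <- all(is.na(vals[, 2]))
    wm <- w[rows] / sum(w[rows])
    mu <- colSums(vals * wm, na.rm = TRUE)
    sdv <- sqrt(pmax(0, colSums(sweep(vals, 2, mu)^2 * wm, na.rm = TRUE)))
    h <- if (one_d) {
      hh <- hist(vals[, 1], breaks = breaks, plot = FALSE)
      hh$density <- hh$counts / sum(hh$counts)
      hh
    } else NULL
    out[[as.character(m)]] <- list(
      values = if (one_d) vals[, 1, drop = FALSE] else vals,
      mean = if (one_d) mu[1] else mu,
      sd = if (one_d) sdv[1] else sdv, hist = h)
  }
  out
}
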