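#' Assign frames to metastable states through their microstates
#'
#' A frame joins metastable state `m` iff its microstate's membership row
#' attains its maximum at `m` with value strictly above `threshold`
#' (default 0.7, i.e. > 70% probability of belonging). Frames of
#' low-confidence ("in between") microstates go to a first-class unassigned
#' pool, which the adaptive sampler consumes.
#'
#' @param dtrajs list of discrete trajectories over the active-set indices
#'   of the model `chi` was computed from.
#' @param chi membership matrix (microstates x metastable states).
#' @param threshold membership threshold (strict inequality).
#' @param dt frame time, ns (stored as per-frame `time`).
#' @return list with `sets` (per-MS data.frames: traj, frame, time,
#'   microstate) and `unassigned` (same columns).
#' @export
assign_frames <- function(dtrajs, chi, threshold = 0.7, dt = 1) {
  chi <- as.matrix(chi)
  if (max(unlist(dtrajs)) > nrow(chi))
    stop2("chi does not cover all microstates present in the trajectories")
  best <- max.col(chi, ties.method = "first")
  conf <- chi[cbind(seq_len(nrow(chi)), best)]
  ms_of <- ifelse(conf > threshold, best, NA_integer_)
  frames <- do.call(rbind, lapply(seq_along(dtrajs), function(i)
    data.frame(traj = i, frame = seq_along(dtrajs[[i]]) - 1L,
               time = (seq_along(dtrajs[[i]]) - 1L) * dt,
               microstate = dtrajs[[i]])))
  frames$ms <- ms_of[frames$microstate]
  sets <- lapply(seq_len(ncol(chi)), function(m)
    frames[!is.na(frames$ms) & frames$ms == m,
           c("traj", "frame", "time", "microstate"), drop = FALSE])
  unassigned <- frames[is.na(frames$ms),
                       c("traj", "frame", "time", "microstate"), drop = FALSE]
  list(sets = sets, unassigned = unassigned, threshold = threshold)
}

#' Metastable-state equilibrium probabilities
#'
#' `pi_MS(m) = sum_i pi_i chi_im`; linear aggregation, so the probabilities
#' always sum to 1. With a Bayesian ensemble, the maximum-likelihood value
#' plus 1-sigma percentile bounds over the samples are reported.
#'
#' @param x a `transition_model` or a [bayesian_sample()] ensemble.
#' @param chi membership matrix.
#' @return data.frame with `ms`, `pi` and, for an ensemble, `lower_1s`,
#'   `upper_1s`.
#' @export
ms_equilibrium <- function(x, chi) {
  chi <- as.matrix(chi)
  agg <- function(pi) as.numeric(crossprod(chi, pi))
  if (inherits(x, "transition_model"))
    return(data.frame(ms = seq_len(ncol(chi)), pi = agg(x$pi)))
  stopifnot(inherits(x, "bayesian_ensemble"))
  samp <- vapply(x$samples, function(s) agg(s$pi), numeric(ncol(chi)))
  samp <- matrix(samp, nrow = ncol(chi))
  data.frame(ms = seq_len(ncol(chi)), pi = agg(x$ml$pi),
             lower_1s = apply(samp, 1, quantile, 0.1587),
             upper_1s = apply(samp, 1, quantile, 0.8413))
}

#' Metastable-state exchange rates from mean first passage times
#'
#' `rate(A -> B) = 1 / MFPT(A -> B)` on the crisp microstate sets of the
#' partition, for every ordered pair of metastable states. With a Bayesian
#' ensemble the ML value and 1-sigma percentile interval are reported.
#'
#' @param x a `transition_model` or [bayesian_sample()] ensemble.
#' @param chi membership matrix.
#' @return data.frame: from, to, mfpt_ns, rate_per_ns (+ bounds for an
#'   ensemble).
#' @export
ms_rates <- function(x, chi) {
  chi <- as.matrix(chi)
  sets <- crisp_sets(chi, nrow(chi))
  if (length(sets) < 2) stop2("at least 2 metastable states are required")
  ml_model <- if (inherits(x, "transition_model")) x else x$ml
  pairs <- expand.grid(from = seq_along(sets), to = seq_along(sets))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    A <- sets[[pairs$from[i]]]; B <- sets[[pairs$to[i]]]
    m_ml <- mfpt(ml_model, A, B)
    row <- data.frame(from = pairs$from[i], to = pairs$to[i],
                      mfpt_ns = m_ml, rate_per_ns = 1 / m_ml)
    if (inherits(x, "bayesian_ensemble")) {
      vals <- vapply(x$samples, function(s) {
        mod <- structure(list(P = s$P, pi = s$pi, lag = x$lag, dt = x$dt),
                         class = "transition_model")
        1 / mfpt(mod, A, B)
      }, numeric(1))
      row$rate_lower_1s <- quantile(vals, 0.1587, names = FALSE)
      row$rate_upper_1s <- quantile(vals, 0.8413, names = FALSE)
    }
    row
  })
  do.call(rbind, rows)
}

#' Full metastable partition of one condition
#'
#' Convenience constructor running [pcca()], [assign_frames()],
#' [ms_equilibrium()] and [ms_rates()] for one simulated condition.
#'
#' @param ensemble a [bayesian_sample()] result for the condition.
#' @param dtrajs the condition's discrete trajectories (original microstate
#'   indices).
#' @param n_ms number of metastable states.
#' @param threshold frame-filter membership threshold.
#' @param condition label.
#' @return object of class `metastable_partition`: chi, crisp assignment,
#'   pi table, rate table, frame sets, unassigned pool, condition.
#' @export
metastable_partition <- function(ensemble, dtrajs, n_ms, threshold = 0.7,
                                 condition = "condition") {
  model <- ensemble$ml
  chi <- pcca(model, n_ms)
  a <- model$active_set
  ## map dtrajs (original indices) onto active-set positions; frames outside
  ## the active set are reported, never silently dropped
  pos <- match(seq_len(max(unlist(dtrajs), max(a))), a)
  dtrajs_act <- lapply(dtrajs, function(s) pos[s])
  outside <- sum(is.na(unlist(dtrajs_act)))
  dtrajs_act <- lapply(dtrajs_act, function(s) ifelse(is.na(s), 0L, s))
  chi_full <- rbind(matrix(0, 1, n_ms), chi)   # row 1 = outside active set
  fr <- assign_frames(lapply(dtrajs_act, function(s) s + 1L), chi_full,
                      threshold = threshold, dt = ensemble$dt)
  fr$sets <- lapply(fr$sets, function(d) {
    d$microstate <- d$microstate - 1L
    d$microstate_orig <- a[d$microstate]
    d
  })
  fr$unassigned$microstate <- fr$unassigned$microstate - 1L
  structure(list(chi = chi,
                 assignment = max.col(chi, ties.method = "first"),
                 pi_ms = ms_equilibrium(ensemble, chi),
                 rates = ms_rates(ensemble, chi),
                 frame_sets = fr$sets, unassigned = fr$unassigned,
                 n_outside_active = outside,
                 active_set = a, threshold = threshold,
                 condition = condition),
            class = "metastable_partition")
}

#' @export
print.metastable_partition <- function(x, ...) {
  cat("<metastable_partition>", x$condition, ":", ncol(x$chi),
      "metastable states over", nrow(x$chi), "microstates\n")
  p <- x$pi_ms
  for (i in seq_len(nrow(p)))
    cat(sprintf("  MS %d: pi = %.3f%s\n", p$ms[i], p$pi[i],
                if (!is.null(p$lower_1s))
                  sprintf(" [%.3f, %.3f]", p$lower_1s[i], p$upper_1s[i])
                else ""))
  invisible(x)
}

#' Match metastable states across conditions
#'
#' Conditions discretized in a shared (combined-clustering) microstate space
#' are matched greedily by the number of shared crisp microstates; ties are
#' broken by the larger Jaccard index, then by the lower metastable-state
#' index. Unmatched states receive fresh labels. The matching is symmetric:
#' `match(A, B)` is the inverse correspondence of `match(B, A)`.
#'
#' @param partitions list of `metastable_partition` objects (the first is
#'   the label reference), all on the same microstate index space.
#' @return list with `labels`: per partition, an integer vector giving each
#'   MS's common label; and `overlap`: list of pairwise overlap matrices
#'   with the reference.
#' @export
match_ms_across_conditions <- function(partitions) {
  sets_of <- function(p) {
    lapply(seq_len(ncol(p$chi)), function(m)
      p$active_set[p$assignment == m])
  }
  ref_sets <- sets_of(partitions[[1]])
  n_labels <- length(ref_sets)
  labels <- list(seq_len(n_labels))
  overlaps <- list()
  for (ci in seq_along(partitions)[-1]) {
    cur_sets <- sets_of(partitions[[ci]])
    if (!length(intersect(unlist(ref_sets), unlist(cur_sets))))
      stop2("partitions do not share a microstate space")
    ov <- matrix(0L, length(cur_sets), length(ref_sets))
    jac <- matrix(0, length(cur_sets), length(ref_sets))
    for (i in seq_along(cur_sets)) for (j in seq_along(ref_sets)) {
      ov[i, j] <- length(intersect(cur_sets[[i]], ref_sets[[j]]))
      un <- length(union(cur_sets[[i]], ref_sets[[j]]))
      jac[i, j] <- if (un) ov[i, j] / un else 0
    }
    lab <- rep(NA_integer_, length(cur_sets))
    taken <- logical(length(ref_sets))
    repeat {
      cand <- which(!is.na(ov) & ov > 0 &
                      outer(is.na(lab), !taken, "&"), arr.ind = TRUE)
      if (!nrow(cand)) break
      sc <- ov[cand]
      best <- which(sc == max(sc))
      if (length(best) > 1) {
        jb <- jac[cand[best, , drop = FALSE]]
        best <- best[jb == max(jb)]
      }
      pick <- cand[best[order(cand[best, 2], cand[best, 1])[1]], ]
      lab[pick[1]] <- pick[2]
      taken[pick[2]] <- TRUE
    }
    for (i in which(is.na(lab))) {
      n_labels <- n_labels + 1L
      lab[i] <- n_labels
    }
    labels[[ci]] <- lab
    overlaps[[ci]] <- ov
  }
  list(labels = labels, overlap = overlaps)
}
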