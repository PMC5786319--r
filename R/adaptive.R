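#' Select restart frames for the next round of adaptive sampling
#'
#' Two selection rules: (i) every single-frame microstate; (ii) every
#' under-sampled microstate (fewer than `min_frames` frames) that lies "in
#' between" metastable states, operationalized as a top-two membership gap
#' of at most `betweenness_tol`. The representative frame of a selected
#' microstate is its frame with the largest simulation time (the most
#' advanced stage of sampling); ties go to the lowest trajectory id, then
#' the lowest frame index. Selection is deterministic and invariant to
#' trajectory ordering.
#'
#' @param dtrajs list of discrete trajectories (microstate indices matching
#'   the rows of `chi`).
#' @param chi membership matrix.
#' @param min_frames microstates with fewer frames than this qualify for
#'   rule (ii).
#' @param betweenness_tol maximum top-two membership gap for rule (ii).
#' @param dt frame time, ns.
#' @return data.frame of class `seed_selection`: microstate, reason
#'   (`"single-frame"` or `"under-sampled-between-MS"`), traj, frame, time.
#' @export
select_seed_frames <- function(dtrajs, chi, min_frames = 10,
                               betweenness_tol = 0.2, dt = 1) {
  if (!length(dtrajs) || !sum(lengths(dtrajs)))
    stop2("no trajectory data supplied")
  chi <- as.matrix(chi)
  frames <- do.call(rbind, lapply(seq_along(dtrajs), function(i)
    data.frame(traj = i, frame = seq_along(dtrajs[[i]]) - 1L,
               microstate = dtrajs[[i]])))
  frames$time <- frames$frame * dt
  counts <- tabulate(frames$microstate, nbins = nrow(chi))
  gap <- apply(chi, 1, function(r) {
    s <- sort(r, decreasing = TRUE)
    if (length(s) < 2) Inf else s[1] - s[2]
  })
  single <- which(counts == 1L)
  between <- which(counts >= 1L & counts < min_frames &
                     gap <= betweenness_tol)
  between <- setdiff(between, single)
  sel <- rbind(
    if (length(single)) data.frame(microstate = single,
                                   reason = "single-frame"),
    if (length(between)) data.frame(microstate = between,
                                    reason = "under-sampled-between-MS"))
  if (is.null(sel))
    sel <- data.frame(microstate = integer(), reason = character())
  reps <- lapply(sel$microstate, function(mi) {
    f <- frames[frames$microstate == mi, , drop = FALSE]
    f <- f[order(-f$time, f$traj, f$frame), , drop = FALSE]
    f[1, c("traj", "frame", "time")]
  })
  out <- cbind(sel, do.call(rbind, reps) %||%
                 data.frame(traj = integer(), frame = integer(),
                            time = numeric()))
  out <- out[order(out$microstate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seed_selection", "data.frame")
  out
}

#' Convergence check between sampling rounds
#'
#' The campaign has converged when the biggest absolute change in the
#' metastable-state equilibrium probabilities, across conditions and states
#' (with matched labels), is strictly below `tol` (default 0.05, i.e. 5
#' percentage points). Symmetric in its two arguments.
#'
#' @param prev_pi,new_pi named lists (one entry per condition) of named
#'   numeric vectors of pi_MS; names must match between rounds.
#' @param tol convergence tolerance on absolute probability change.
#' @return list: `converged` (logical), `max_change`, `changes`
#'   (per-condition max absolute change).
#' @export
check_convergence <- function(prev_pi, new_pi, tol = 0.05) {
  if (!is.list(prev_pi)) prev_pi <- list(condition = prev_pi)
  if (!is.list(new_pi)) new_pi <- list(condition = new_pi)
  if (!identical(sort(names(prev_pi)), sort(names(new_pi))))
    stop2("condition labels differ between rounds")
  changes <- vapply(names(prev_pi), function(cn) {
    a <- prev_pi[[cn]]; b <- new_pi[[cn]]
    if (!is.null(names(a)) && !is.null(names(b))) {
      if (!setequal(names(a), names(b)))
        stop2("metastable-state labels of condition '", cn, "' do not ",
              "match between rounds; run match_ms_across_conditions() first")
      b <- b[names(a)]
    } else if (length(a) != length(b)) {
      stop2("metastable-state counts of condition '", cn, "' differ; ",
            "run match_ms_across_conditions() first")
    }
    max(abs(a - b))
  }, numeric(1))
  list(converged = max(changes) < tol, max_change = max(changes),
       changes = changes)
}

#' MSM-guided iterative sampling loop
#'
#' Round 0 data are discretized (TICA + seeded k-means, centers frozen for
#' the whole campaign so all rounds share one microstate space); each round
#' estimates an MSM, derives the metastable partition and pi_MS, selects
#' restart frames with [select_seed_frames()], asks the simulator hook for
#' new trajectories started there, and re-estimates. The loop stops when
#' [check_convergence()] passes or `max_rounds` is reached (an explicit
#' "not converged" verdict, not an error).
#'
#' @param trajs0 initial list of [feature_traj()].
#' @param simulator hook `function(seeds, round)` returning a list of new
#'   `feature_traj` started from the selected frames (for tests: the
#'   synthetic generator continuing from the seed frames' hidden states; for
#'   production: an MD submission layer).
#' @param lag MSM lag, frames.
#' @param k microstates; `n_ms` metastable states; `n_components` TICA
#'   dimensions; `tica_lag` TICA lag in frames.
#' @param tol convergence tolerance on pi_MS change.
#' @param max_rounds maximum additional rounds.
#' @param min_frames,betweenness_tol passed to [select_seed_frames()].
#' @param seed campaign seed.
#' @return campaign report: per-round pi_MS, seed counts, delta-pi, verdict.
#' @export
run_iteration_loop <- function(trajs0, simulator, lag, k = 50, n_ms = 3,
                               n_components = 4, tica_lag = lag,
                               tol = 0.05, max_rounds = 5,
                               min_frames = 10, betweenness_tol = 0.2,
                               seed = 1L) {
  tica <- fit_tica(trajs0, tica_lag)
  nc <- min(n_components, length(tica$eigenvalues))
  project_all <- function(trajs) lapply(trajs, function(tr)
    tica_project(tica, tr, n_components = nc))
  disc <- kmeans_discretize(project_all(trajs0), k = k,
                            seed = substream_seed(seed, 10L),
                            dt = trajs0[[1]]$dt)
  centers <- disc$centers
  trajs <- trajs0
  dtrajs <- disc$dtrajs

  estimate <- function(dtrajs) {
    cm <- count_matrix(dtrajs, lag, n_states = k, dt = trajs0[[1]]$dt)
    mod <- estimate_reversible_mle(cm)
    chi <- pcca(mod, n_ms)
    pi_ms <- sort(as.numeric(crossprod(chi, mod$pi)), decreasing = TRUE)
    list(model = mod, chi = chi, pi_ms = pi_ms)
  }

  est <- estimate(dtrajs)
  rounds <- list(list(round = 0L, pi_ms = est$pi_ms, n_seeds = NA_integer_,
                      max_change = NA_real_))
  converged <- FALSE
  for (r in seq_len(max_rounds)) {
    ## seeds are selected on active-set microstate indices mapped back
    a <- est$model$active_set
    chi_full <- matrix(0, k, n_ms)
    chi_full[a, ] <- est$chi
    seeds <- select_seed_frames(dtrajs, chi_full, min_frames = min_frames,
                                betweenness_tol = betweenness_tol,
                                dt = trajs0[[1]]$dt)
    if (!nrow(seeds)) {
      converged <- TRUE
      rounds[[length(rounds) + 1L]] <-
        list(round = r, pi_ms = est$pi_ms, n_seeds = 0L, max_change = 0)
      break
    }
    new_trajs <- simulator(seeds, r)
    trajs <- c(trajs, new_trajs)
    new_d <- lapply(project_all(new_trajs), assign_microstates,
                    centers = centers)
    dtrajs <- c(dtrajs, new_d)
    est_new <- estimate(dtrajs)
    ## pi_MS vectors are compared in sorted order: the microstate space is
    ## shared, and sorting is the label matching for a single condition
    cv <- check_convergence(list(c = est$pi_ms), list(c = est_new$pi_ms),
                            tol = tol)
    rounds[[length(rounds) + 1L]] <-
      list(round = r, pi_ms = est_new$pi_ms, n_seeds = nrow(seeds),
           max_change = cv$max_change)
    est <- est_new
    if (cv$converged) { converged <- TRUE; break }
  }
  list(converged = converged, rounds = rounds, final = est,
       dtrajs = dtrajs, trajs = trajs, centers = centers, tica = tica)
}
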