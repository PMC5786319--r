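#' Reversible maximum-likelihood Markov state model
#'
#' Maximum-likelihood transition matrix under the detailed-balance
#' constraint, via the standard self-consistent fixed-point iteration on
#' symmetric edge weights `x_ij`:
#' `x_ij <- (C_ij + C_ji) / (c_i / x_i + c_j / x_j)`,
#' with `x_i = sum_j x_ij` and `c_i` the observed row counts. Iteration stops
#' when the largest absolute change of any transition probability falls
#' below `tol` (a parameter-space criterion: the likelihood is flat near the
#' optimum, so a likelihood-change rule leaves parameter error of order
#' sqrt(tol)). The stationary distribution is `pi_i = x_i / sum(x)`, exact
#' by construction, and the returned matrix satisfies detailed balance to
#' machine precision.
#'
#' @param counts a [count_matrix()] result.
#' @param tol convergence tolerance on max |delta P_ij| per sweep.
#' @param maxiter maximum sweeps.
#' @return object of class `transition_model`: `P` (row-stochastic, on the
#'   active set), `pi`, `eigenvalues`, `active_set`, `lag`, `dt`.
#' @export
estimate_reversible_mle <- function(counts, tol = 1e-12, maxiter = 1e6) {
  stopifnot(inherits(counts, "count_model"))
  a <- counts$active_set
  if (!length(a)) stop2("empty active set")
  C <- counts$C[a, a, drop = FALSE]
  n <- nrow(C)
  if (n == 1L) {
    P <- matrix(1, 1, 1)
    return(transition_model(P, pi = 1, active_set = a,
                            lag = counts$lag, dt = counts$dt))
  }
  fit <- reversible_mle_cpp(C, tol, as.integer(maxiter))
  if (!fit$converged)
    stop2("reversible MLE did not converge in ", maxiter,
          " sweeps (last max |delta P| ", format(fit$delta), ")")
  ## exact symmetrization guard against drift
  x <- (fit$x + t(fit$x)) / 2
  xi <- rowSums(x)
  transition_model(x / xi, pi = xi / sum(xi), active_set = a,
                   lag = counts$lag, dt = counts$dt)
}

#' Construct a transition model
#'
#' Validates row-stochasticity and detailed balance; computes real
#' eigenvalues through the symmetrized similarity transform
#' `diag(sqrt(pi)) P diag(1/sqrt(pi))`.
#'
#' @param P row-stochastic matrix on the active set.
#' @param pi stationary vector (computed from `P` if omitted).
#' @param active_set original microstate indices of `P`'s rows.
#' @param lag lag in frames; `dt` time per frame in ns.
#' @return object of class `transition_model`.
#' @export
transition_model <- function(P, pi = NULL, active_set = seq_len(nrow(P)),
                             lag = 1L, dt = 1) {
  P <- as.matrix(P)
  check_stochastic(P, tol = 1e-10)
  pi <- pi %||% stationary_distribution(P)
  check_detailed_balance(P, pi, "transition matrix", tol = 1e-8)
  lambda <- msm_eigenvalues(P, pi)
  structure(list(P = P, pi = pi, eigenvalues = lambda,
                 active_set = active_set, lag = lag, dt = dt),
            class = "transition_model")
}

msm_eigenvalues <- function(P, pi) {
  s <- sqrt(pi)
  S <- (P * outer(s, 1 / s))
  S <- (S + t(S)) / 2
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

msm_eigen <- function(P, pi, m) {
  s <- sqrt(pi)
  S <- P * outer(s, 1 / s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)[seq_len(m)]
  list(values = e$values[ord],
       right = e$vectors[, ord, drop = FALSE] / s,   # right eigvecs of P
       left = e$vectors[, ord, drop = FALSE] * s)
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model>", nrow(x$P), "states, lag", x$lag, "frames (",
      x$lag * x$dt, "ns ); slowest implied timescale",
      signif(-x$lag * x$dt / log(abs(x$eigenvalues[2])), 4), "ns\n")
  invisible(x)
}

#' Implied relaxation timescales across lag times
#'
#' For each lag, estimates a reversible MLE model and reports
#' `t_i(tau) = -tau * dt / log(|lambda_{i+1}(tau)|)`. With `n_samples > 0`,
#' Bayesian transition-matrix samples provide the mean and 95% interval per
#' timescale, as used to judge ITS convergence.
#'
#' @param dtrajs list of discrete trajectories.
#' @param lags integer vector of lags (frames).
#' @param n_its number of timescales to report.
#' @param dt frame time, ns.
#' @param n_samples Bayesian samples per lag (0 = maximum likelihood only).
#' @param seed RNG seed for the Bayesian sampler.
#' @return data.frame: lag, its index, ml estimate, and (if sampled)
#'   `mean`, `lower`, `upper` (95% interval), all in ns.
#' @export
implied_timescales <- function(dtrajs, lags, n_its = 3, dt = 1,
                               n_samples = 0, seed = 1L) {
  out <- list()
  for (lag in lags) {
    cm <- count_matrix(dtrajs, lag, dt = dt)
    mod <- estimate_reversible_mle(cm)
    if (n_its + 1 > length(mod$eigenvalues))
      stop2("requested timescale index exceeds the active-set size")
    its_of <- function(lambda) {
      l <- abs(lambda[2:(n_its + 1)])
      ifelse(l >= 1, Inf, -lag * dt / log(l))
    }
    ml <- its_of(mod$eigenvalues)
    row <- data.frame(lag = lag, index = seq_len(n_its), ml = ml)
    if (n_samples > 0) {
      ens <- bayesian_sample(cm, n = n_samples,
                             seed = substream_seed(seed, 5L, lag))
      samp <- vapply(ens$samples,
                     function(s) its_of(msm_eigenvalues(s$P, s$pi)),
                     numeric(n_its))
      samp <- matrix(samp, nrow = n_its)
      row$mean <- rowMeans(samp)
      row$lower <- apply(samp, 1, quantile, 0.025)
      row$upper <- apply(samp, 1, quantile, 0.975)
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Mean first passage time between microstate sets
#'
#' Solves the absorbing-chain linear system for the expected hitting time of
#' `target`, then averages over `source` states weighted by the stationary
#' distribution restricted to `source`. Returned in ns
#' (`steps * lag * dt`); the associated transition rate is `1 / MFPT`.
#'
#' @param model a `transition_model`.
#' @param source,target disjoint index sets (positions within the active
#'   set).
#' @return MFPT in ns.
#' @export
mfpt <- function(model, source, target) {
  P <- model$P
  n <- nrow(P)
  source <- as.integer(source); target <- as.integer(target)
  if (length(intersect(source, target)))
    stop2("source and target sets must be disjoint")
  if (!length(source) || !length(target)) stop2("source/target must be non-empty")
  if (any(c(source, target) < 1 | c(source, target) > n))
    stop2("state index outside the active set")
  ## reachability check on the directed graph of P
  reach <- reachable_from(P > 0, source)
  if (!any(target %in% reach))
    stop2("target set is unreachable from the source set")
  keep <- setdiff(seq_len(n), target)
  h <- solve(diag(length(keep)) - P[keep, keep, drop = FALSE],
             rep(1, length(keep)))
  hh <- numeric(n); hh[keep] <- h
  w <- model$pi[source] / sum(model$pi[source])
  sum(w * hh[source]) * model$lag * model$dt
}

reachable_from <- function(adj, start) {
  seen <- logical(nrow(adj))
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  which(seen)
}
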