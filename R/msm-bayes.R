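#' Bayesian sampling of reversible transition matrices
#'
#' Markov chain Monte Carlo over the posterior of reversible transition
#' matrices given the observed counts, parameterized by symmetric edge
#' weights (multiplicative Metropolis updates, one sweep touching every
#' non-zero edge). Burn-in defaults to `10 * n_states` sweeps and samples
#' are at least one sweep apart. The chain starts from the reversible
#' maximum-likelihood model, which is also returned as the reference.
#'
#' @param counts a [count_matrix()] result.
#' @param n number of samples (>= 2; 500 is the conventional choice).
#' @param seed RNG seed.
#' @param n_burnin burn-in sweeps (default `10 * n_states`).
#' @param n_thin sweeps between retained samples (default 1).
#' @param step log-scale proposal standard deviation.
#' @return object of class `bayesian_ensemble`: `samples` (list of
#'   `list(P, pi)`), `ml` (the maximum-likelihood `transition_model`),
#'   `seed`, `lag`, `dt`.
#' @export
bayesian_sample <- function(counts, n = 500, seed = 1L, n_burnin = NULL,
                            n_thin = 1L, step = 0.1) {
  stopifnot(inherits(counts, "count_model"))
  if (n < 2) stop2("at least 2 samples are required")
  ml <- estimate_reversible_mle(counts)
  a <- counts$active_set
  C <- counts$C[a, a, drop = FALSE]
  x0 <- ml$P * ml$pi            # pi_i P_ij, symmetric
  x0 <- (x0 + t(x0)) / 2
  n_burnin <- n_burnin %||% (10L * nrow(C))
  set.seed(substream_seed(seed, 6L))
  samples <- sample_reversible_cpp(C, x0, as.integer(n),
                                   as.integer(n_burnin),
                                   as.integer(max(1L, n_thin)), step)
  samples <- lapply(samples, function(s)
    list(P = s$P, pi = as.numeric(s$pi)))
  structure(list(samples = samples, ml = ml, seed = as.integer(seed),
                 lag = counts$lag, dt = counts$dt, active_set = a),
            class = "bayesian_ensemble")
}

#' @export
print.bayesian_ensemble <- function(x, ...) {
  cat("<bayesian_ensemble>", length(x$samples), "samples,",
      nrow(x$ml$P), "states, lag", x$lag, "frames\n")
  invisible(x)
}

#' Posterior summary of a scalar model functional
#'
#' Applies `fun(P, pi)` to the maximum-likelihood model and to every
#' Bayesian sample; reports the ML value, posterior mean and SD, and both
#' 1-sigma (15.87/84.13%) and 95% percentile intervals — the convention used
#' to annotate equilibrium probabilities and rates.
#'
#' @param ensemble a [bayesian_sample()] result.
#' @param fun function of `(P, pi)` returning a scalar.
#' @return one-row data.frame: ml, mean, sd, lower_1s, upper_1s, lower_95,
#'   upper_95.
#' @export
ensemble_summary <- function(ensemble, fun) {
  vals <- vapply(ensemble$samples, function(s) fun(s$P, s$pi), numeric(1))
  data.frame(ml = fun(ensemble$ml$P, ensemble$ml$pi),
             mean = mean(vals), sd = sd(vals),
             lower_1s = quantile(vals, 0.1587, names = FALSE),
             upper_1s = quantile(vals, 0.8413, names = FALSE),
             lower_95 = quantile(vals, 0.025, names = FALSE),
             upper_95 = quantile(vals, 0.975, names = FALSE))
}
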