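#' Chapman-Kolmogorov test
#'
#' Checks `P(k * tau) == P(tau)^k` at the metastable-set level: for each
#' set, the population starting in that set is propagated with the model's
#' `P(tau)^k` (prediction) and compared to the population under a model
#' re-estimated from the data at lag `k * tau` (reference). The 95%
#' confidence band of the reference comes from bootstrapping whole
#' trajectories. A set passes when the prediction lies within the band at
#' every `k`.
#'
#' @param dtrajs list of discrete trajectories.
#' @param model a `transition_model` estimated at lag `tau = model$lag`.
#' @param memberships microstate x set membership matrix (chi from
#'   [pcca()]), or a list of crisp microstate index sets.
#' @param k_values integer multiples of the lag to test.
#' @param n_bootstrap bootstrap replicates for the band (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `ck_test`: per-set data.frame of
#'   (k, predicted, estimated, lower, upper, within) plus `pass` per set.
#' @export
ck_test <- function(dtrajs, model, memberships, k_values = 1:5,
                    n_bootstrap = 500, seed = 1L) {
  if (any(k_values < 1)) stop2("k_values must be >= 1")
  sets <- crisp_sets(memberships, nrow(model$P))
  tau <- model$lag
  a <- model$active_set
  n_act <- nrow(model$P)

  ## initial distributions: pi restricted to each set
  p0 <- lapply(sets, function(A) {
    p <- numeric(n_act)
    p[A] <- model$pi[A] / sum(model$pi[A])
    p
  })

  occupancy <- function(P_est, act_est, A, p) {
    ## align the lag-k model's active set with the reference model's
    common <- intersect(a, act_est)
    ia <- match(common, a); ib <- match(common, act_est)
    pv <- p[ia]; pv <- pv / sum(pv)
    pk <- as.numeric(pv %*% P_est[ib, ib, drop = FALSE])
    sum(pk[match(intersect(a[A], common), common)])
  }

  results <- vector("list", length(sets))
  pass <- logical(length(sets))
  set.seed(substream_seed(seed, 7L))
  boot_idx <- replicate(n_bootstrap,
                        sample.int(length(dtrajs), replace = TRUE),
                        simplify = FALSE)
  for (si in seq_along(sets)) {
    A <- sets[[si]]
    rows <- list()
    for (k in sort(unique(as.integer(k_values)))) {
      predicted <- sum((p0[[si]] %*% matpow(model$P, k))[A])
      est <- tryCatch({
        cmk <- count_matrix(dtrajs, k * tau,
                            n_states = max(unlist(dtrajs)), dt = model$dt)
        mk <- estimate_reversible_mle(cmk)
        occupancy(mk$P, mk$active_set, A, p0[[si]])
      }, error = function(e) NA_real_)
      bvals <- vapply(boot_idx, function(idx) {
        tryCatch({
          cmb <- count_matrix(dtrajs[idx], k * tau,
                              n_states = max(unlist(dtrajs)), dt = model$dt)
          mb <- estimate_reversible_mle(cmb, tol = 1e-10)
          occupancy(mb$P, mb$active_set, A, p0[[si]])
        }, error = function(e) NA_real_)
      }, numeric(1))
      bvals <- bvals[!is.na(bvals)]
      lower <- if (length(bvals)) quantile(bvals, 0.025, names = FALSE) else NA
      upper <- if (length(bvals)) quantile(bvals, 0.975, names = FALSE) else NA
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, predicted = predicted, estimated = est,
        lower = lower, upper = upper,
        within = !is.na(lower) && predicted >= lower & predicted <= upper)
    }
    results[[si]] <- do.call(rbind, rows)
    pass[si] <- all(results[[si]]$within, na.rm = FALSE)
  }
  structure(list(sets = results, pass = pass, k_values = k_values,
                 lag = tau), class = "ck_test")
}

crisp_sets <- function(memberships, n_states) {
  if (is.list(memberships)) return(memberships)
  chi <- as.matrix(memberships)
  if (nrow(chi) != n_states)
    stop2("membership matrix rows must match the model's active set")
  assign <- max.col(chi, ties.method = "first")
  lapply(seq_len(ncol(chi)), function(m) which(assign == m))
}

matpow <- function(P, k) {
  R <- diag(nrow(P))
  B <- P
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% B
    B <- B %*% B
    k <- k %/% 2
  }
  R
}

#' @export
print.ck_test <- function(x, ...) {
  cat("<ck_test> lag", x$lag, "frames;",
      sum(x$pass), "of", length(x$pass), "metastable sets pass\n")
  invisible(x)
}
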