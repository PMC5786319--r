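`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_prob_vector <- function(p, what = "probability vector", tol = 1e-12) {
  if (any(p <= 0)) stop2(what, " must have strictly positive entries")
  if (abs(sum(p) - 1) > tol) stop2(what, " must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

check_stochastic <- function(P, what = "transition matrix", tol = 1e-12) {
  if (any(P < 0)) stop2(what, " must be non-negative")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > tol))
    stop2(what, " rows must sum to 1 (max deviation ",
          format(max(abs(rs - 1))), ")")
  invisible(P)
}

check_detailed_balance <- function(P, pi, what = "exchange matrix",
                                   tol = 1e-10) {
  F <- pi * P                         # flux matrix pi_i P_ij
  if (max(abs(F - t(F))) > tol)
    stop2(what, " violates detailed balance w.r.t. the stationary vector ",
          "(max |pi_i P_ij - pi_j P_ji| = ", format(max(abs(F - t(F)))), ")")
  invisible(P)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Leading left eigenvector of `P`, normalized to sum to 1.
#'
#' @param P row-stochastic matrix.
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P, tol = 1e-8)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop2("leading eigenvector has negative entries; P may be reducible")
  pmax(v, 0) / sum(pmax(v, 0))
}

## Deterministic per-stream sub-seeds: one global seed fans out so that
## adding trajectories never reshuffles existing ones.
substream_seed <- function(seed, stream, index = 0L) {
  (as.integer(seed) + 97561L * as.integer(stream) + 1013L * as.integer(index)) %% 2147483629L
}

## largest connected component of an undirected graph given a logical
## adjacency matrix (BFS); returns sorted vertex indices
largest_connected_set <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  sort(which(comp == which.max(sizes)))
}
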