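#' k-means microstate discretization
#'
#' Pools the projected frames of all trajectories, runs k-means with
#' seeded k-means++ initialization (Lloyd iterations), and assigns every
#' frame to its nearest center (ties broken toward the lowest center index).
#' Centers are returned so that frames from later sampling rounds can be
#' assigned into the same microstate space.
#'
#' @param ptrajs list of projected trajectories (matrices frames x dims), or
#'   a single matrix.
#' @param k number of microstates.
#' @param seed RNG seed for the initialization.
#' @param iter_max maximum Lloyd iterations.
#' @param dt time per frame (ns), carried into the discrete trajectories.
#' @return list with `dtrajs` (list of integer vectors, 1-based microstate
#'   indices), `centers` (k x dims), `k`, `dt`.
#' @export
kmeans_discretize <- function(ptrajs, k, seed = 1L, iter_max = 100L, dt = 1) {
  if (is.matrix(ptrajs)) ptrajs <- list(ptrajs)
  ptrajs <- lapply(ptrajs, function(p) {
    p <- as.matrix(p)
    attr(p, "n_components") <- NULL
    p
  })
  X <- do.call(rbind, ptrajs)
  if (nrow(unique(X)) < k)
    stop2("k exceeds the number of distinct data points")
  set.seed(substream_seed(seed, 4L))
  init <- kmeanspp_init(X, k)
  ## Lloyd iterations can cycle on continuous data without harming the
  ## partition; frames are re-assigned to the final centers below anyway
  km <- if (k == 1L) list(centers = matrix(colMeans(X), 1))
        else suppressWarnings(stats::kmeans(X, centers = init,
                                            iter.max = iter_max,
                                            algorithm = "Lloyd"))
  centers <- unname(km$centers)
  lens <- vapply(ptrajs, nrow, integer(1))
  assign_all <- assign_microstates(X, centers)
  dtrajs <- split(assign_all, rep(seq_along(ptrajs), lens))
  names(dtrajs) <- NULL
  list(dtrajs = dtrajs, centers = centers, k = k, dt = dt)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Assign frames to the nearest microstate center
#'
#' @param X frames x dims matrix.
#' @param centers k x dims matrix.
#' @return integer vector of 1-based microstate indices; ties go to the
#'   lowest center index (`which.min` semantics).
#' @export
assign_microstates <- function(X, centers) {
  X <- as.matrix(X)
  ## ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; row-wise argmin
  G <- X %*% t(centers)
  cc <- rowSums(centers^2)
  D <- sweep(-2 * G, 2, cc, "+")
  max.col(-D, ties.method = "first")
}

#' Transition count matrix at a lag
#'
#' Sliding-window counting: `C[i, j] += 1` for every in-trajectory pair
#' `(t, t + lag)`; counts never cross trajectory boundaries. The active set
#' is the largest connected component of the symmetrized count graph.
#'
#' @param dtrajs list of integer state vectors (1-based).
#' @param lag lag in frames (>= 1; at least one trajectory must be longer).
#' @param n_states total number of microstates (default: max observed).
#' @param dt time per frame, ns.
#' @return object of class `count_model`: `C`, `lag`, `dt`, `active_set`,
#'   `n_states`, `counting = "sliding"`.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL, dt = 1) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1) stop2("lag must be >= 1")
  n_states <- n_states %||% max(unlist(dtrajs))
  if (all(vapply(dtrajs, length, integer(1)) <= lag))
    stop2("all trajectories are shorter than the lag")
  C <- matrix(0, n_states, n_states)
  for (s in dtrajs) {
    T <- length(s)
    if (T <= lag) next
    from <- s[1:(T - lag)]
    to <- s[(1 + lag):T]
    C <- C + matrix(tabulate(from + n_states * (to - 1L),
                             nbins = n_states * n_states),
                    n_states, n_states)
  }
  visited <- which(rowSums(C) + colSums(C) > 0)
  adj <- (C + t(C))[visited, visited, drop = FALSE] > 0
  diag(adj) <- TRUE
  active <- visited[largest_connected_set(adj)]
  structure(list(C = C, lag = lag, dt = dt, active_set = active,
                 n_states = n_states, counting = "sliding"),
            class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  cat("<count_model>", x$n_states, "states, lag", x$lag, "frames,",
      sum(x$C), "counts, active set", length(x$active_set), "states\n")
  invisible(x)
}

#' Write/read discrete trajectories as integer text files
#'
#' One microstate index per line (0-based on disk, for interoperability with
#' common MSM toolchains).
#'
#' @param dtrajs list of 1-based integer vectors; `dir` output directory.
#' @return file paths (write) or list of 1-based vectors (read).
#' @export
write_dtrajs <- function(dtrajs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("dtraj_%03d.txt", seq_along(dtrajs)))
  for (i in seq_along(dtrajs))
    writeLines(as.character(dtrajs[[i]] - 1L), paths[i])
  invisible(paths)
}

#' @rdname write_dtrajs
#' @export
read_dtrajs <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^dtraj_.*\\.txt$",
                           full.names = TRUE))
  lapply(paths, function(p) as.integer(readLines(p)) + 1L)
}
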