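#' Time-lagged independent component analysis
#'
#' Estimates the slow linear subspace of a set of feature trajectories:
#' pooled instantaneous and time-lagged covariances (the lagged covariance
#' symmetrized), then the generalized eigenproblem
#' `C(tau) v = lambda C(0) v`, solved after whitening with a small ridge
#' regularization `eps * I`, `eps = 1e-10 * trace(C0)/k`. Eigenvalues are
#' sorted descending; each component's sign is fixed by making its
#' largest-magnitude loading positive; the cumulative kinetic variance is the
#' running fraction of `sum(lambda_i^2)`.
#'
#' @param trajs list of [feature_traj()] sharing feature names.
#' @param lag lag time in frames (>= 1, shorter than every trajectory).
#' @return object of class `tica_model` with elements `lag`, `mean`,
#'   `instantaneous_cov`, `lagged_cov`, `eigenvalues`, `components`
#'   (columns are loading vectors), `cumulative_kinetic_variance`,
#'   `feature_names`.
#' @export
fit_tica <- function(trajs, lag) {
  if (inherits(trajs, "feature_traj")) trajs <- list(trajs)
  lag <- as.integer(lag)
  if (lag < 1) stop2("lag must be >= 1 frame")
  k <- ncol(trajs[[1]]$values)
  if (k < 2) stop2("TICA needs at least 2 features")
  fn <- trajs[[1]]$feature_names
  for (tr in trajs) {
    if (!identical(tr$feature_names, fn))
      stop2("all trajectories must share the same feature names")
    if (nrow(tr$values) <= lag)
      stop2("lag (", lag, ") must be shorter than every trajectory")
  }
  ## pooled symmetric estimator: each trajectory contributes T - lag pairs;
  ## head and tail windows both enter mean and C(0)
  sw <- 0; s1 <- numeric(k); S0 <- matrix(0, k, k); St <- matrix(0, k, k)
  for (tr in trajs) {
    X <- tr$values
    T <- nrow(X)
    H <- X[1:(T - lag), , drop = FALSE]
    L <- X[(1 + lag):T, , drop = FALSE]
    sw <- sw + (T - lag)
    s1 <- s1 + 0.5 * (colSums(H) + colSums(L))
    S0 <- S0 + 0.5 * (crossprod(H) + crossprod(L))
    St <- St + crossprod(H, L)
  }
  mu <- s1 / sw
  C0 <- S0 / sw - tcrossprod(mu)
  Ct <- St / sw - tcrossprod(mu)
  Ct <- (Ct + t(Ct)) / 2
  eps <- 1e-10 * sum(diag(C0)) / k
  C0r <- C0 + diag(eps, k)

  e0 <- eigen(C0r, symmetric = TRUE)
  pos <- e0$values > max(e0$values) * 1e-12
  if (!any(pos)) stop2("C(0) is numerically zero; features are constant")
  W <- e0$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[pos]), sum(pos))
  K <- crossprod(W, Ct %*% W)
  K <- (K + t(K)) / 2
  ek <- eigen(K, symmetric = TRUE)
  ord <- order(ek$values, decreasing = TRUE)
  lambda <- ek$values[ord]
  V <- W %*% ek$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- fn
  ckv <- cumsum(lambda^2) / sum(lambda^2)
  structure(list(lag = lag, mean = stats::setNames(mu, fn),
                 instantaneous_cov = C0, lagged_cov = Ct,
                 eigenvalues = lambda, components = V,
                 cumulative_kinetic_variance = ckv,
                 feature_names = fn, dt = trajs[[1]]$dt),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat("<tica_model> lag", x$lag, "frames;",
      length(x$eigenvalues), "components; leading eigenvalues:",
      paste(signif(head(x$eigenvalues, 4), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Project a feature trajectory onto the leading TICA components
#'
#' @param model a fitted `tica_model`.
#' @param traj a [feature_traj()] with the model's feature names, or a bare
#'   matrix in the model's feature order.
#' @param n_components number of leading components to keep.
#' @param variance_threshold alternatively, keep the smallest number of
#'   components whose cumulative kinetic variance reaches this fraction.
#' @return numeric matrix (frames x kept components); the number kept is
#'   attached as attribute `n_components`.
#' @export
tica_project <- function(model, traj, n_components = NULL,
                         variance_threshold = NULL) {
  X <- if (inherits(traj, "feature_traj")) {
    if (!identical(traj$feature_names, model$feature_names))
      stop2("feature names of trajectory and model do not match")
    traj$values
  } else as.matrix(traj)
  if (is.null(n_components)) {
    n_components <- if (is.null(variance_threshold))
      ncol(model$components)
    else which(model$cumulative_kinetic_variance >= variance_threshold)[1]
  }
  if (n_components > ncol(model$components))
    stop2("n_components exceeds the available components")
  Y <- sweep(X, 2, model$mean) %*%
    model$components[, seq_len(n_components), drop = FALSE]
  attr(Y, "n_components") <- n_components
  Y
}

#' TICA implied timescales
#'
#' `-lag * dt / log(|lambda_i|)` for each component.
#'
#' @param model a `tica_model`.
#' @return numeric vector, ns.
#' @export
tica_timescales <- function(model) {
  -model$lag * model$dt / log(pmin(1, abs(model$eigenvalues)))
}

#' Serialize / restore a TICA model as JSON
#'
#' @param model a `tica_model`; `path` file path.
#' @return `path`, or the restored model.
#' @export
write_tica_json <- function(model, path) {
  jsonlite::write_json(lapply(unclass(model), function(x)
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x)) else x),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tica_json
#' @export
read_tica_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("instantaneous_cov", "lagged_cov", "components"))
    raw[[f]] <- matrix(raw[[f]]$data, raw[[f]]$dim[1], raw[[f]]$dim[2])
  rownames(raw$components) <- raw$feature_names
  raw$mean <- stats::setNames(as.numeric(raw$mean), raw$feature_names)
  structure(raw, class = "tica_model")
}
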