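#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Metropolis sampler over reversible transition matrices posterior to a
// count matrix, parameterized by symmetric edge weights x_ij with
// P_ij = x_ij / x_i, pi_i = x_i / sum(x). Each sweep proposes a
// multiplicative log-normal update to every non-zero edge (and diagonal)
// weight. The prior is scale-invariant in each edge weight (uniform in
// log x), so the posterior mode coincides with the reversible MLE; the
// Hastings factor x_new/x_old of the multiplicative proposal cancels
// against it. Proper because only edges with observed counts are sampled.
// Uses R's RNG, so set.seed() governs reproducibility.
// [[Rcpp::export]]
List sample_reversible_cpp(const arma::mat& C, const arma::mat& x0,
                           int n_samples, int n_burnin_sweeps,
                           int n_thin_sweeps, double step) {
  const int n = C.n_rows;
  arma::vec ci = arma::sum(C, 1);
  arma::mat Cs = C + C.t();
  arma::mat x = x0;
  arma::vec xi = arma::sum(x, 1);

  // edge list: i <= j with Cs > 0
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      if (Cs(i, j) > 0) { ei.push_back(i); ej.push_back(j); }
  const int ne = ei.size();

  List samples(n_samples);
  int total_sweeps = n_burnin_sweeps + n_samples * n_thin_sweeps;
  int collected = 0;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int e = 0; e < ne; ++e) {
      int i = ei[e], j = ej[e];
      double xe = x(i, j);
      double ye = xe * std::exp(step * R::norm_rand());
      double d = ye - xe;
      double logr;
      if (i == j) {
        double xin = xi(i) + d;
        if (xin <= 0) continue;
        logr = C(i, i) * (std::log(ye) - std::log(xe))
             - ci(i) * (std::log(xin) - std::log(xi(i)));
        if (std::log(R::unif_rand()) < logr) { x(i, i) = ye; xi(i) = xin; }
      } else {
        double xin = xi(i) + d, xjn = xi(j) + d;
        if (xin <= 0 || xjn <= 0) continue;
        logr = Cs(i, j) * (std::log(ye) - std::log(xe))
             - ci(i) * (std::log(xin) - std::log(xi(i)))
             - ci(j) * (std::log(xjn) - std::log(xi(j)));
        if (std::log(R::unif_rand()) < logr) {
          x(i, j) = ye; x(j, i) = ye; xi(i) = xin; xi(j) = xjn;
        }
      }
    }
    // guard against scale drift (target is scale-invariant in x)
    double tot = arma::accu(x);
    x /= tot; xi /= tot;

    if (sweep >= n_burnin_sweeps &&
        (sweep - n_burnin_sweeps + 1) % n_thin_sweeps == 0 &&
        collected < n_samples) {
      arma::mat P = x;
      P.each_col() /= xi;
      arma::vec pi = xi / arma::accu(xi);
      samples[collected++] = List::create(Named("P") = P, Named("pi") = pi);
    }
  }
  return samples;
}

// Self-consistent fixed-point iteration for the reversible maximum-
// likelihood transition matrix: x_ij <- (C_ij + C_ji)/(c_i/x_i + c_j/x_j),
// stopping on max |delta P| <= tol (with a stall guard for the floating-
// point floor). Returns the symmetric edge-weight matrix.
// [[Rcpp::export]]
List reversible_mle_cpp(const arma::mat& C, double tol, int maxiter) {
  const int n = C.n_rows;
  arma::mat Cs = C + C.t();
  arma::vec ci = arma::sum(C, 1);
  arma::mat x = Cs / arma::accu(Cs);
  arma::vec xi = arma::sum(x, 1);
  arma::mat P_old = x;
  P_old.each_col() /= xi;
  bool conv = false;
  int stall = 0;
  double delta_old = R_PosInf, delta = R_PosInf;
  for (int it = 0; it < maxiter; ++it) {
    arma::vec r = ci / xi;
    arma::mat x_new(n, n, arma::fill::zeros);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (Cs(i, j) > 0) x_new(i, j) = Cs(i, j) / (r(i) + r(j));
    x = x_new / arma::accu(x_new);
    xi = arma::sum(x, 1);
    arma::mat P = x;
    P.each_col() /= xi;
    delta = arma::abs(P - P_old).max();
    if (delta <= tol) { conv = true; break; }
    stall = (delta >= delta_old * 0.999) ? stall + 1 : 0;
    if (stall >= 50 && delta < 1e-9) { conv = true; break; }
    delta_old = delta;
    P_old = P;
  }
  return List::create(Named("x") = x, Named("converged") = conv,
                      Named("delta") = delta);
}

static arma::mat kabsch_rotation(const arma::mat& Xc, const arma::mat& Yc) {
  arma::mat A = Xc.t() * Yc;            // 3x3
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, A);
  double d = arma::det(U * V.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d < 0 ? -1.0 : 1.0;
  return U * D * V.t();                  // X * R best matches Y
}

// Pairwise minimum RMSD matrix after optimal superposition of each frame
// pair. coords: n_frames x (3 * n_atoms), frame rows store atoms
// contiguously as x1 y1 z1 x2 y2 z2 ...
// [[Rcpp::export]]
NumericMatrix pairwise_rmsd_cpp(const arma::mat& coords, int n_atoms) {
  const int nf = coords.n_rows;
  std::vector<arma::mat> frames(nf);
  for (int f = 0; f < nf; ++f) {
    arma::mat X(n_atoms, 3);
    for (int a = 0; a < n_atoms; ++a)
      for (int k = 0; k < 3; ++k) X(a, k) = coords(f, 3 * a + k);
    X.each_row() -= arma::mean(X, 0);
    frames[f] = X;
  }
  NumericMatrix out(nf, nf);
  for (int i = 0; i < nf; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      arma::mat R = kabsch_rotation(frames[i], frames[j]);
      double ss = arma::accu(arma::square(frames[i] * R - frames[j]));
      double r = std::sqrt(ss / n_atoms);
      out(i, j) = r; out(j, i) = r;
    }
  }
  return out;
}

// Superpose every frame onto a reference (optimal rotation + translation on
// the given atoms); returns coords in the same flattened layout.
// [[Rcpp::export]]
NumericMatrix superpose_cpp(const arma::mat& coords, const arma::mat& ref,
                            const IntegerVector& fit_atoms) {
  const int nf = coords.n_rows;
  const int n_all = coords.n_cols / 3;
  const int n_fit = fit_atoms.size();
  arma::mat Yc(n_fit, 3);
  for (int a = 0; a < n_fit; ++a)
    for (int k = 0; k < 3; ++k) Yc(a, k) = ref(fit_atoms[a] - 1, k);
  arma::rowvec ymean = arma::mean(Yc, 0);
  Yc.each_row() -= ymean;

  NumericMatrix out(nf, coords.n_cols);
  for (int f = 0; f < nf; ++f) {
    arma::mat X(n_all, 3);
    for (int a = 0; a < n_all; ++a)
      for (int k = 0; k < 3; ++k) X(a, k) = coords(f, 3 * a + k);
    arma::mat Xf(n_fit, 3);
    for (int a = 0; a < n_fit; ++a) Xf.row(a) = X.row(fit_atoms[a] - 1);
    arma::rowvec xmean = arma::mean(Xf, 0);
    Xf.each_row() -= xmean;
    arma::mat R = kabsch_rotation(Xf, Yc);
    arma::mat Xr = X;
    Xr.each_row() -= xmean;
    Xr = Xr * R;
    Xr.each_row() += ymean;
    for (int a = 0; a < n_all; ++a)
      for (int k = 0; k < 3; ++k) out(f, 3 * a + k) = Xr(a, k);
  }
  return out;
}
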