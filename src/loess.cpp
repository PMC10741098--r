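#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Direct local polynomial regression with tricube neighbour weights.
//
// X:  n x p training predictors (p = 1 or 2; columns pre-scaled upstream)
// y:  n responses
// Xe: m x p evaluation points (same scaling as X)
// q:  neighbourhood size (number of nearest neighbours)
// degree: 1 or 2 (full polynomial in p variables)
//
// For every evaluation point the q nearest training points are found
// (absolute difference in 1D, Euclidean distance in 2D; points tied with
// the q-th distance are included with weight 0) and tricube-weighted, and
// a weighted polynomial is fitted by accumulating the normal equations on
// coordinates centred at the evaluation point and scaled by the window
// radius (local coordinates in [-1, 1], so the moment matrix is well
// conditioned); the local prediction is the intercept. Windows whose
// local design is rank deficient (e.g. all predictor values tied) fall
// back to the local weighted mean; the number of fallbacks is returned.
//
// The 1D path sorts the predictor once and finds each window with two
// pointers, so a full fit is O(n log n + n q) with a tight scalar inner
// loop; the 2D path scans all pairwise distances per evaluation point.

namespace {

struct FitResult {
  arma::vec fitted;
  int n_fallback = 0;
};

// solve the npar x npar weighted normal equations; returns false when the
// local design is rank deficient
inline bool solve_local(const arma::mat& A, const arma::vec& b,
                        arma::vec& coef) {
  arma::mat R;
  if (!arma::chol(R, A)) return false;
  const arma::vec d = R.diag();
  if (!(d.min() > 1e-8 * d.max())) return false;
  coef = arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), b));
  return true;
}

FitResult fit_1d(const arma::vec& x, const arma::vec& y,
                 const arma::vec& xe, int q, int degree) {
  const int n = x.n_elem, m = xe.n_elem;
  FitResult res;
  res.fitted.set_size(m);

  const arma::uvec ord = arma::sort_index(x);
  std::vector<double> xs(n), ys(n);
  for (int j = 0; j < n; ++j) {
    xs[j] = x(ord(j));
    ys[j] = y(ord(j));
  }

  const int npar = degree + 1;
  arma::mat A(npar, npar);
  arma::vec b(npar), coef(npar);

  for (int i = 0; i < m; ++i) {
    const double xv = xe(i);
    // grow a window of the q nearest points around the insertion position
    int left = static_cast<int>(std::lower_bound(xs.begin(), xs.end(), xv) -
                                xs.begin()) - 1;
    int right = left + 1;
    for (int k = 0; k < q; ++k) {
      const double dl = (left >= 0) ? xv - xs[left] : -1.0;
      const double dr = (right < n) ? xs[right] - xv : -1.0;
      if (dl >= 0.0 && (dr < 0.0 || dl <= dr)) --left;
      else ++right;
    }
    double dmax = 0.0;
    if (left + 1 <= right - 1) {
      dmax = std::max(xv - xs[left + 1], xs[right - 1] - xv);
    }
    // include boundary ties (weight 0 at d == dmax)
    while (left >= 0 && xv - xs[left] <= dmax) --left;
    while (right < n && xs[right] - xv <= dmax) ++right;

    if (dmax <= 0.0) {
      double s = 0.0;
      int nw = 0;
      for (int j = left + 1; j < right; ++j) { s += ys[j]; ++nw; }
      res.fitted(i) = s / nw;
      ++res.n_fallback;
      continue;
    }

    const double inv = 1.0 / dmax;
    // moments of the tricube-weighted scaled coordinates
    double s0 = 0, s1 = 0, s2 = 0, s3 = 0, s4 = 0;
    double b0 = 0, b1 = 0, b2 = 0;
    for (int j = left + 1; j < right; ++j) {
      const double u = (xs[j] - xv) * inv;       // in [-1, 1]
      const double au = std::abs(u);
      const double tc = 1.0 - au * au * au;
      const double w = tc * tc * tc;
      const double wu = w * u, wu2 = wu * u;
      s0 += w; s1 += wu; s2 += wu2;
      b0 += w * ys[j]; b1 += wu * ys[j];
      if (degree == 2) {
        s3 += wu2 * u; s4 += wu2 * u * u;
        b2 += wu2 * ys[j];
      }
    }
    if (degree == 1) {
      A(0, 0) = s0; A(0, 1) = s1; A(1, 0) = s1; A(1, 1) = s2;
      b(0) = b0; b(1) = b1;
    } else {
      A(0, 0) = s0; A(0, 1) = s1; A(0, 2) = s2;
      A(1, 0) = s1; A(1, 1) = s2; A(1, 2) = s3;
      A(2, 0) = s2; A(2, 1) = s3; A(2, 2) = s4;
      b(0) = b0; b(1) = b1; b(2) = b2;
    }
    if (solve_local(A, b, coef)) {
      res.fitted(i) = coef(0);
    } else {
      res.fitted(i) = (s0 > 0.0) ? b0 / s0 : 0.0;
      ++res.n_fallback;
    }
  }
  return res;
}

FitResult fit_2d(const arma::mat& X, const arma::vec& y,
                 const arma::mat& Xe, int q, int degree) {
  const int n = X.n_rows, m = Xe.n_rows;
  FitResult res;
  res.fitted.set_size(m);

  const int npar = (degree == 1) ? 3 : 6;
  arma::mat A(npar, npar);
  arma::vec b(npar), coef(npar), t(npar);
  std::vector<double> dist(n), dsel(n);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      const double d1 = X(j, 0) - Xe(i, 0);
      const double d2 = X(j, 1) - Xe(i, 1);
      dist[j] = std::sqrt(d1 * d1 + d2 * d2);
    }
    dsel = dist;
    std::nth_element(dsel.begin(), dsel.begin() + (q - 1), dsel.end());
    const double dmax = dsel[q - 1];

    if (dmax <= 0.0) {
      double s = 0.0;
      int nw = 0;
      for (int j = 0; j < n; ++j)
        if (dist[j] <= 0.0) { s += y(j); ++nw; }
      res.fitted(i) = s / nw;
      ++res.n_fallback;
      continue;
    }

    A.zeros();
    b.zeros();
    double sw = 0.0, swy = 0.0;
    const double inv = 1.0 / dmax;
    for (int j = 0; j < n; ++j) {
      if (dist[j] > dmax) continue;
      const double u = dist[j] * inv;
      const double tc = 1.0 - u * u * u;
      const double w = tc * tc * tc;
      const double u1 = (X(j, 0) - Xe(i, 0)) * inv;
      const double u2 = (X(j, 1) - Xe(i, 1)) * inv;
      t(0) = 1.0; t(1) = u1; t(2) = u2;
      if (degree == 2) {
        t(3) = u1 * u1; t(4) = u2 * u2; t(5) = u1 * u2;
      }
      for (int a = 0; a < npar; ++a) {
        const double wt = w * t(a);
        b(a) += wt * y(j);
        for (int c = a; c < npar; ++c) A(a, c) += wt * t(c);
      }
      sw += w;
      swy += w * y(j);
    }
    A = arma::symmatu(A);
    if (solve_local(A, b, coef)) {
      res.fitted(i) = coef(0);
    } else {
      res.fitted(i) = (sw > 0.0) ? swy / sw : arma::mean(y);
      ++res.n_fallback;
    }
  }
  return res;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List loess_eval_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::mat& Xe, int q, int degree) {
  const int n = X.n_rows, p = X.n_cols;
  if (q < 1 || q > n) Rcpp::stop("neighbourhood size out of range");
  if (p < 1 || p > 2) Rcpp::stop("1 or 2 predictor columns supported");
  if (static_cast<int>(Xe.n_cols) != p)
    Rcpp::stop("evaluation points have wrong number of columns");

  FitResult res = (p == 1)
    ? fit_1d(X.col(0), y, Xe.col(0), q, degree)
    : fit_2d(X, y, Xe, q, degree);

  return Rcpp::List::create(Rcpp::Named("fitted") = res.fitted,
                            Rcpp::Named("n_fallback") = res.n_fallback);
}
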