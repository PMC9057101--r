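#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Natural cubic spline through (t, v), evaluated at integer queries
// 1..T (ascending); linear extrapolation beyond the knot range.
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& v,
                                uword T, double* out) {
  const int m = (int) t.size();
  if (m == 1) {
    for (uword q = 0; q < T; ++q) out[q] = v[0];
    return;
  }
  if (m == 2) {
    const double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (uword q = 0; q < T; ++q) out[q] = v[0] + slope * ((q + 1) - t[0]);
    return;
  }
  std::vector<double> h(m - 1), M(m, 0.0), cp(m, 0.0), dp(m, 0.0);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  // Thomas algorithm for interior second derivatives, M[0]=M[m-1]=0
  for (int i = 1; i < m - 1; ++i) {
    const double rhs = 6.0 * ((v[i + 1] - v[i]) / h[i] -
                              (v[i] - v[i - 1]) / h[i - 1]);
    const double diag = 2.0 * (h[i - 1] + h[i]);
    const double lower = (i == 1) ? 0.0 : h[i - 1];
    const double w = diag - lower * cp[i - 1];
    cp[i] = h[i] / w;
    dp[i] = (rhs - lower * dp[i - 1]) / w;
  }
  for (int i = m - 2; i >= 1; --i) M[i] = dp[i] - cp[i] * M[i + 1];
  int seg = 0;
  double inv_hs = 1.0 / h[0], hs2_6 = h[0] * h[0] / 6.0;
  for (uword q = 0; q < T; ++q) {
    const double u = (double)(q + 1);
    while (seg < m - 2 && u > t[seg + 1]) {
      ++seg;
      inv_hs = 1.0 / h[seg];
      hs2_6 = h[seg] * h[seg] / 6.0;
    }
    const double A = (t[seg + 1] - u) * inv_hs;
    const double B = (u - t[seg]) * inv_hs;
    out[q] = A * v[seg] + B * v[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * hs2_6;
  }
}

// Local extrema of p (plateaus collapse to their midpoint); mirrors the
// R reference implementation.
static void local_extrema(const vec& p, std::vector<int>& mx,
                          std::vector<int>& mn) {
  mx.clear(); mn.clear();
  const int n = (int) p.n_elem;
  if (n < 3) return;
  std::vector<int> nz;
  nz.reserve(n);
  for (int i = 0; i + 1 < n; ++i)
    if (p(i + 1) != p(i)) nz.push_back(i);
  if ((int) nz.size() < 2) return;
  for (size_t c = 0; c + 1 < nz.size(); ++c) {
    const double s1 = p(nz[c] + 1) - p(nz[c]);
    const double s2 = p(nz[c + 1] + 1) - p(nz[c + 1]);
    if ((s1 > 0) != (s2 > 0)) {
      const int idx = (nz[c] + 1 + 1 + nz[c + 1] + 1) / 2;  // 1-based mid
      if (s1 > 0) mx.push_back(idx); else mn.push_back(idx);
    }
  }
}

// Mirror-extend (1-based) extrema times about both ends; ext_t sorted.
static void mirror_times(const std::vector<int>& t_ext, int n, int n_mirror,
                         std::vector<double>& tt, std::vector<int>& src) {
  const int m0 = (int) t_ext.size();
  const int m = std::min(n_mirror, m0);
  tt.clear(); src.clear();
  // reflected about t = 1 (ascending: farthest mirror first)
  for (int i = m - 1; i >= 0; --i) {
    tt.push_back(2.0 - (double) t_ext[i]);
    src.push_back(i);
  }
  for (int i = 0; i < m0; ++i) {
    tt.push_back((double) t_ext[i]);
    src.push_back(i);
  }
  // reflected about t = n (ascending: nearest mirror first)
  for (int i = 0; i < m; ++i) {
    tt.push_back(2.0 * n - (double) t_ext[m0 - 1 - i]);
    src.push_back(m0 - 1 - i);
  }
}

// Drop coincident knot times created by mirroring an extremum that
// sits exactly on a boundary.
static void dedup_times(std::vector<double>& tt, std::vector<int>& src) {
  std::vector<double> t2; std::vector<int> s2;
  for (size_t i = 0; i < tt.size(); ++i) {
    if (i > 0 && tt[i] - t2.back() < 1e-9) continue;
    t2.push_back(tt[i]); s2.push_back(src[i]);
  }
  tt.swap(t2); src.swap(s2);
}

// Mean envelope and direction-averaged amplitude for one sifting step.
// x is T x k; dirs is n_dirs x k. Returns the envelope mean (T x k),
// amplitude (T), and the number of usable directions.
// [[Rcpp::export(name = ".cpp_env_mean")]]
Rcpp::List cpp_env_mean(const arma::mat& x, const arma::mat& dirs) {
  const uword T = x.n_rows, k = x.n_cols, nd = dirs.n_rows;
  mat menv(T, k, fill::zeros);
  vec amp(T, fill::zeros);
  int n_ok = 0;
  std::vector<int> mx, mn;
  std::vector<double> tt_u, tt_l;
  std::vector<int> src_u, src_l;
  vec eU(T), eL(T);
  mat sumU(T, k), sumL(T, k);
  for (uword d = 0; d < nd; ++d) {
    vec p = x * dirs.row(d).t();
    local_extrema(p, mx, mn);
    if (mx.size() < 2 || mn.size() < 2) continue;
    mirror_times(mx, (int) T, 2, tt_u, src_u);
    mirror_times(mn, (int) T, 2, tt_l, src_l);
    dedup_times(tt_u, src_u);
    dedup_times(tt_l, src_l);
    std::vector<double> vu(tt_u.size()), vl(tt_l.size());
    for (uword j = 0; j < k; ++j) {
      for (size_t i = 0; i < tt_u.size(); ++i)
        vu[i] = x(mx[src_u[i]] - 1, j);
      for (size_t i = 0; i < tt_l.size(); ++i)
        vl[i] = x(mn[src_l[i]] - 1, j);
      natural_spline_eval(tt_u, vu, T, eU.memptr());
      natural_spline_eval(tt_l, vl, T, eL.memptr());
      sumU.col(j) = eU;
      sumL.col(j) = eL;
    }
    menv += (sumU + sumL) / 2.0;
    amp += sqrt(sum(square(sumU - sumL), 1)) / 2.0;
    ++n_ok;
  }
  if (n_ok > 0) { menv /= (double) n_ok; amp /= (double) n_ok; }
  return Rcpp::List::create(Rcpp::Named("mean") = menv,
                            Rcpp::Named("amp") = amp,
                            Rcpp::Named("n_ok") = n_ok);
}

// Maximum extrema count over all projection directions (decomposition
// stopping rule).
// [[Rcpp::export(name = ".cpp_proj_extrema_max")]]
int cpp_proj_extrema_max(const arma::mat& x, const arma::mat& dirs) {
  std::vector<int> mx, mn;
  int best = 0;
  for (uword d = 0; d < dirs.n_rows; ++d) {
    vec p = x * dirs.row(d).t();
    local_extrema(p, mx, mn);
    const int c = (int)(mx.size() + mn.size());
    if (c > best) best = c;
  }
  return best;
}
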