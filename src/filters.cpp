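#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Direct-form II transposed IIR filter with initial state `z`. The
// 8-state case (4th-order band-pass) is fully unrolled so the
// recurrence stays in registers. `step` = +1 filters forward, -1
// filters the same buffers back to front (time-reversed pass).
static void iir_run(const double* bb, const double* aa, int ns,
                    const double* xp, double* yp, uword n, double* z,
                    int step) {
  const uword start = (step > 0) ? 0 : n - 1;
  if (ns == 8) {
    double z0 = z[0], z1 = z[1], z2 = z[2], z3 = z[3],
           z4 = z[4], z5 = z[5], z6 = z[6], z7 = z[7];
    uword i = start;
    for (uword c = 0; c < n; ++c, i += step) {
      const double xi = xp[i];
      const double yi = bb[0] * xi + z0;
      z0 = bb[1] * xi + z1 - aa[1] * yi;
      z1 = bb[2] * xi + z2 - aa[2] * yi;
      z2 = bb[3] * xi + z3 - aa[3] * yi;
      z3 = bb[4] * xi + z4 - aa[4] * yi;
      z4 = bb[5] * xi + z5 - aa[5] * yi;
      z5 = bb[6] * xi + z6 - aa[6] * yi;
      z6 = bb[7] * xi + z7 - aa[7] * yi;
      z7 = bb[8] * xi - aa[8] * yi;
      yp[i] = yi;
    }
    z[0] = z0; z[1] = z1; z[2] = z2; z[3] = z3;
    z[4] = z4; z[5] = z5; z[6] = z6; z[7] = z7;
  } else {
    uword i = start;
    for (uword c = 0; c < n; ++c, i += step) {
      const double xi = xp[i];
      const double yi = bb[0] * xi + z[0];
      for (int j = 0; j < ns - 1; ++j)
        z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
      z[ns - 1] = bb[ns] * xi - aa[ns] * yi;
      yp[i] = yi;
    }
  }
}

// Normalised coefficients padded to a common length.
static void norm_coefs(const vec& b, const vec& a, std::vector<double>& bb,
                       std::vector<double>& aa, int& nfilt) {
  nfilt = (int) std::max(b.n_elem, a.n_elem);
  bb.assign(nfilt, 0.0);
  aa.assign(nfilt, 0.0);
  for (uword j = 0; j < b.n_elem; ++j) bb[j] = b(j);
  for (uword j = 0; j < a.n_elem; ++j) aa[j] = a(j);
  const double a0 = aa[0];
  for (int j = 0; j < nfilt; ++j) { bb[j] /= a0; aa[j] /= a0; }
}

// Steady-state initial state for a unit step input (lfilter_zi-style):
// chosen so that filtering a constant signal is transient-free.
static std::vector<double> steady_zi(const std::vector<double>& bb,
                                     const std::vector<double>& aa,
                                     int nfilt) {
  const int ns = nfilt - 1;
  mat IminusA = eye(ns, ns);
  vec B(ns);
  for (int j = 0; j < ns; ++j) {
    IminusA(j, 0) += aa[j + 1];
    if (j + 1 < ns) IminusA(j, j + 1) -= 1.0;
    B(j) = bb[j + 1] - bb[0] * aa[j + 1];
  }
  vec zi = solve(IminusA, B);
  return std::vector<double>(zi.begin(), zi.end());
}

// Zero-phase filtering of x into the middle of the scratch buffers.
// xe and buf must have length n + 2*pad with pad = 3*(nfilt-1); on
// return the filtered signal sits in xe[pad .. pad+n-1].
static void filtfilt_scratch(const std::vector<double>& bb,
                             const std::vector<double>& aa, int nfilt,
                             const std::vector<double>& zi,
                             const double* x, uword n,
                             vec& xe, vec& buf) {
  const int ns = nfilt - 1;
  const uword pad = 3 * (uword) ns;
  if (n <= pad + 1) Rcpp::stop("signal too short for zero-phase filtering");
  double* xp = xe.memptr();
  for (uword i = 0; i < pad; ++i) xp[i] = 2.0 * x[0] - x[pad - i];
  std::memcpy(xp + pad, x, n * sizeof(double));
  for (uword i = 0; i < pad; ++i)
    xp[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  const uword ne = n + 2 * pad;
  std::vector<double> z(ns);
  for (int j = 0; j < ns; ++j) z[j] = zi[j] * xp[0];
  iir_run(bb.data(), aa.data(), ns, xp, buf.memptr(), ne, z.data(), +1);
  for (int j = 0; j < ns; ++j) z[j] = zi[j] * buf(ne - 1);
  iir_run(bb.data(), aa.data(), ns, buf.memptr(), xe.memptr(), ne,
          z.data(), -1);
}

//' Zero-phase IIR filtering (forward-backward), with odd reflection
//' padding and steady-state initial conditions; coefficients come from
//' signal::butter on the R side.
// [[Rcpp::export(name = ".cpp_filtfilt")]]
arma::vec cpp_filtfilt(const arma::vec& b, const arma::vec& a,
                       const arma::vec& x) {
  std::vector<double> bb, aa;
  int nfilt;
  norm_coefs(b, a, bb, aa, nfilt);
  std::vector<double> zi = steady_zi(bb, aa, nfilt);
  const uword n = x.n_elem;
  const uword pad = 3 * (uword)(nfilt - 1);
  vec xe(n + 2 * pad), buf(n + 2 * pad);
  filtfilt_scratch(bb, aa, nfilt, zi, x.memptr(), n, xe, buf);
  return xe.subvec(pad, pad + n - 1);
}

// One synthetic channel in a single pass: for each band, zero-phase
// band-pass the shared white carrier source, multiply by the
// exponentiated log-envelope (tabulated at epoch midpoints,
// interpolated linearly in between, flat beyond the ends), and
// accumulate. logenv is nb x nT; epoch_len is samples per epoch.
// [[Rcpp::export(name = ".cpp_channel_signal")]]
arma::vec cpp_channel_signal(const Rcpp::NumericVector& white_,
                             const Rcpp::List& bcoef,
                             const Rcpp::List& acoef,
                             const arma::mat& logenv, double epoch_len) {
  // borrow R's memory: no copy of the (potentially huge) noise vector
  const vec white(const_cast<double*>(white_.begin()),
                  (uword) white_.size(), false, true);
  const uword n = white.n_elem;
  const int nb = (int) logenv.n_rows;
  const uword nT = logenv.n_cols;
  vec acc(n, fill::zeros);
  double* ap = acc.memptr();
  vec xe, buf;
  for (int b = 0; b < nb; ++b) {
    vec bc = Rcpp::as<vec>(bcoef[b]);
    vec ac = Rcpp::as<vec>(acoef[b]);
    std::vector<double> bb, aa;
    int nfilt;
    norm_coefs(bc, ac, bb, aa, nfilt);
    std::vector<double> zi = steady_zi(bb, aa, nfilt);
    const uword pad = 3 * (uword)(nfilt - 1);
    if (xe.n_elem != n + 2 * pad) { xe.set_size(n + 2 * pad); buf.set_size(n + 2 * pad); }
    filtfilt_scratch(bb, aa, nfilt, zi, white.memptr(), n, xe, buf);
    const double* cp = xe.memptr() + pad;
    std::vector<double> env(nT);
    for (uword e = 0; e < nT; ++e) env[e] = std::exp(logenv(b, e));
    if (nT == 1) {
      for (uword s = 0; s < n; ++s) ap[s] += cp[s] * env[0];
      continue;
    }
    const double dpos = 1.0 / epoch_len;
    double pos = dpos - 0.5;  // grid position of the first sample
    for (uword s = 0; s < n; ++s, pos += dpos) {
      double p = pos;
      if (p < 0) p = 0;
      if (p > (double)(nT - 1)) p = (double)(nT - 1);
      uword e0 = (uword) p;
      if (e0 > nT - 2) e0 = nT - 2;
      const double frac = p - (double) e0;
      ap[s] += cp[s] * (env[e0] + frac * (env[e0 + 1] - env[e0]));
    }
  }
  return acc;
}
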