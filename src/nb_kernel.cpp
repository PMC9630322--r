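#include <Rcpp.h>
using namespace Rcpp;

// Negative binomial mixture log-likelihood and gradients for one Monte Carlo
// draw of the variational parameters. All lgamma terms are precomputed in
// `nbconst` (dispersion fixed per gene):
//   ll = nbconst + x log m - (x + r) log(r + m)
//   d ll / d log m = x - m (x + r) / (r + m)
// Per gene the cycling indicator is marginalized as a two-component mixture
// (sinusoid vs flat) with mixing odds `gamodds`; in conditional mode
// (cond_q1) the gene-parameter and phase gradients use the sinusoid branch
// with weight 1. With want_flat = false the flat branch is skipped entirely
// (valid only in conditional mode, where the objective is the sinusoid
// branch and the flat branch only feeds the cycler-probability tracker).
// [[Rcpp::export(name = ".nb_mix_grad")]]
List nb_mix_grad(NumericMatrix x, NumericMatrix xr, NumericMatrix nbconst,
                 NumericVector rj, NumericVector L, NumericVector logL,
                 NumericVector theta, NumericVector mu, NumericVector A,
                 NumericVector phi, NumericVector gamodds,
                 bool cond_q1, bool want_theta_grad, bool want_flat) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector S1(p), S0(p), w1(p), gmu(p), gA(p), gphi(p), gtheta(n);
  NumericVector cth(n), sth(n);
  for (int i = 0; i < n; ++i) { cth[i] = std::cos(theta[i]); sth[i] = std::sin(theta[i]); }
  // per-column stash of d1 * sin(theta - phi) for the phase gradient
  std::vector<double> d1s(want_theta_grad ? (size_t) n * p : 0);
  for (int j = 0; j < p; ++j) {
    const double r = rj[j], muj = mu[j], Aj = A[j];
    const double emuj = std::exp(muj);
    const double cphi = std::cos(phi[j]), sphi = std::sin(phi[j]);
    double s1 = 0.0, s0 = 0.0, c1 = 0.0, c0 = 0.0, cA = 0.0, cphig = 0.0;
    const double* xc = &x(0, j);
    const double* xrc = &xr(0, j);
    const double* nbc = &nbconst(0, j);
    double* d1sc = want_theta_grad ? &d1s[(size_t) n * j] : (double*) 0;
    for (int i = 0; i < n; ++i) {
      const double c = cth[i] * cphi + sth[i] * sphi;      // cos(theta - phi)
      const double s = sth[i] * cphi - cth[i] * sphi;      // sin(theta - phi)
      const double logm1 = logL[i] + muj + Aj * c;
      const double m1 = std::exp(logm1);
      s1 += nbc[i] + xc[i] * logm1 - xrc[i] * std::log(r + m1);
      const double d1 = xc[i] - m1 * xrc[i] / (r + m1);
      c1 += d1; cA += d1 * c; cphig += d1 * s;
      if (want_theta_grad) d1sc[i] = d1 * s;
      if (want_flat) {
        const double m0 = L[i] * emuj;
        s0 += nbc[i] + xc[i] * (logL[i] + muj) - xrc[i] * std::log(r + m0);
        c0 += xc[i] - m0 * xrc[i] / (r + m0);
      }
    }
    S1[j] = s1; S0[j] = s0;
    if (want_flat) {
      const double lo = gamodds[j] + s1 - s0;
      w1[j] = 1.0 / (1.0 + std::exp(-lo));
    } else {
      w1[j] = NA_REAL;
    }
    const double wl1 = cond_q1 ? 1.0 : w1[j];
    const double wl0 = cond_q1 ? 0.0 : 1.0 - w1[j];
    gmu[j] = wl1 * c1 + wl0 * c0;
    gA[j] = wl1 * cA;
    gphi[j] = wl1 * Aj * cphig;
  }
  if (want_theta_grad) {
    for (int j = 0; j < p; ++j) {
      const double w = (cond_q1 ? 1.0 : w1[j]) * A[j];
      const double* d1sc = &d1s[(size_t) n * j];
      for (int i = 0; i < n; ++i) gtheta[i] -= w * d1sc[i];
    }
  }
  // mixture log likelihood (log-sum-exp per gene); conditional mode reports
  // the sinusoid branch
  double LL = 0.0;
  for (int j = 0; j < p; ++j) {
    if (cond_q1) { LL += S1[j]; continue; }
    const double g = 1.0 / (1.0 + std::exp(-gamodds[j]));
    const double a = std::log(g) + S1[j], b = std::log1p(-g) + S0[j];
    const double m = a > b ? a : b;
    LL += m + std::log(std::exp(a - m) + std::exp(b - m));
  }
  return List::create(_["LL"] = LL, _["S1"] = S1, _["S0"] = S0, _["w1"] = w1,
                      _["gmu"] = gmu, _["gA"] = gA, _["gphi"] = gphi,
                      _["gtheta"] = gtheta);
}

// Per-cell log likelihood profile over a grid of candidate phases, for one
// draw of the gene parameters (Q = 1 branch): out[i, g] = sum_j ll_ij(grid_g).
// Used to marginalize each cell's phase by quadrature when computing the
// clock evidence.
// [[Rcpp::export(name = ".nb_theta_profile")]]
NumericMatrix nb_theta_profile(NumericMatrix x, NumericMatrix xr,
                               NumericMatrix nbconst, NumericVector rj,
                               NumericVector logL, NumericVector mu,
                               NumericVector A, NumericVector phi,
                               NumericVector grid) {
  const int n = x.nrow(), p = x.ncol(), G = grid.size();
  NumericMatrix out(n, G);
  for (int g = 0; g < G; ++g) {
    const double tg = grid[g];
    for (int j = 0; j < p; ++j) {
      const double r = rj[j];
      const double ll = mu[j] + A[j] * std::cos(tg - phi[j]);
      const double* xc = &x(0, j);
      const double* xrc = &xr(0, j);
      const double* nbc = &nbconst(0, j);
      double* oc = &out(0, g);
      for (int i = 0; i < n; ++i) {
        const double logm = logL[i] + ll;
        const double m = std::exp(logm);
        oc[i] += nbc[i] + xc[i] * logm - xrc[i] * std::log(r + m);
      }
    }
  }
  return out;
}
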