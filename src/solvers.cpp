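#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Backward propagation of the log-desirability on a (time x position) grid.
//
// log_psi(., k) = -pos_term + log( K %*% psi(., k+1) ), evaluated fully in the
// log domain. K is a banded Gaussian transition kernel (offsets -w..w with
// weights `wts`), truncated at the grid edges and renormalized per row so each
// row is a probability vector: with flat terminal condition and zero running
// cost the recursion then preserves psi == 1 to machine precision.
//
// log_psi_T: terminal slice (length ny)
// pos_term:  position_cost(y) * dt / lambda (length ny)
// wts:       kernel weights, length 2w+1, need not be normalized
// nt:        number of backward steps
// [[Rcpp::export]]
NumericMatrix cpp_psi_backward(NumericVector log_psi_T, NumericVector pos_term,
                               NumericVector wts, int nt) {
  const int ny = log_psi_T.size();
  const int nw = wts.size();
  const int w = (nw - 1) / 2;
  if (pos_term.size() != ny) stop("pos_term length mismatch");

  std::vector<double> logw(nw);
  std::vector<double> prefix(nw + 1, 0.0);
  for (int j = 0; j < nw; ++j) {
    logw[j] = std::log(wts[j]);
    prefix[j + 1] = prefix[j] + wts[j];
  }

  NumericMatrix out(ny, nt + 1);
  std::vector<double> cur(ny), nxt(ny);
  for (int i = 0; i < ny; ++i) {
    nxt[i] = log_psi_T[i];
    out(i, nt) = nxt[i];
  }

  for (int k = nt - 1; k >= 0; --k) {
    for (int i = 0; i < ny; ++i) {
      // valid offset indices j so that 0 <= i + (j - w) < ny
      int jlo = std::max(0, w - i);
      int jhi = std::min(nw - 1, ny - 1 - i + w);
      double m = -INFINITY;
      for (int j = jlo; j <= jhi; ++j) {
        double v = logw[j] + nxt[i + j - w];
        if (v > m) m = v;
      }
      double s = 0.0;
      if (std::isfinite(m)) {
        for (int j = jlo; j <= jhi; ++j) {
          s += std::exp(logw[j] + nxt[i + j - w] - m);
        }
      }
      double wsum = prefix[jhi + 1] - prefix[jlo];
      double lse = std::isfinite(m) ? (m + std::log(s)) : -INFINITY;
      cur[i] = lse - std::log(wsum) - pos_term[i];
      if (std::isnan(cur[i]) || cur[i] == INFINITY) {
        stop("non-finite desirability at time index %d, position index %d",
             k + 1, i + 1);
      }
    }
    for (int i = 0; i < ny; ++i) {
      nxt[i] = cur[i];
      out(i, k) = cur[i];
    }
  }
  return out;
}

// Deterministic (nu = 0) Bellman backward induction on a (time x position)
// grid with a discretized control set and linear interpolation in position.
//
// J(y, k) = min_u [ 0.5*R*u^2*dt + pos_rate(y)*dt + J(y + u*dt, k+1) ]
//
// y landing positions are clamped to the grid range (screen bounds).
// Returns J (ny x nt+1) and the argmin control U (ny x nt+1; final column 0).
// [[Rcpp::export]]
List cpp_det_dp(NumericVector y_grid, NumericVector u_grid,
                NumericVector pos_rate, NumericVector end_cost,
                double dt, double R, int nt) {
  const int ny = y_grid.size();
  const int nu = u_grid.size();
  const double y0 = y_grid[0];
  const double ymax = y_grid[ny - 1];
  const double dy = (ymax - y0) / (ny - 1);

  // landing index and interpolation fraction for every (y, u) pair
  std::vector<int> idx(static_cast<size_t>(ny) * nu);
  std::vector<double> frac(static_cast<size_t>(ny) * nu);
  std::vector<double> ucost(nu);
  for (int l = 0; l < nu; ++l) ucost[l] = 0.5 * R * u_grid[l] * u_grid[l] * dt;
  for (int i = 0; i < ny; ++i) {
    for (int l = 0; l < nu; ++l) {
      double pos = y_grid[i] + u_grid[l] * dt;
      if (pos < y0) pos = y0;
      if (pos > ymax) pos = ymax;
      double g = (pos - y0) / dy;
      int ii = static_cast<int>(std::floor(g));
      if (ii >= ny - 1) ii = ny - 2;
      idx[static_cast<size_t>(i) * nu + l] = ii;
      frac[static_cast<size_t>(i) * nu + l] = g - ii;
    }
  }

  NumericMatrix J(ny, nt + 1), U(ny, nt + 1);
  std::vector<double> nxt(ny);
  for (int i = 0; i < ny; ++i) {
    nxt[i] = end_cost[i];
    J(i, nt) = nxt[i];
    U(i, nt) = 0.0;
  }

  std::vector<double> cur(ny);
  for (int k = nt - 1; k >= 0; --k) {
    for (int i = 0; i < ny; ++i) {
      double best = INFINITY;
      int bestl = 0;
      const size_t base = static_cast<size_t>(i) * nu;
      for (int l = 0; l < nu; ++l) {
        int ii = idx[base + l];
        double f = frac[base + l];
        double val = ucost[l] + nxt[ii] + f * (nxt[ii + 1] - nxt[ii]);
        if (val < best) { best = val; bestl = l; }
      }
      cur[i] = best + pos_rate[i] * dt;
      J(i, k) = cur[i];
      U(i, k) = u_grid[bestl];
    }
    for (int i = 0; i < ny; ++i) nxt[i] = cur[i];
  }
  return List::create(_["J"] = J, _["u"] = U);
}
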