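// Overdamped Langevin sampler with optional in-loop well-tempered
// metadynamics. The bias is accumulated on a uniform grid (value plus
// analytic gradient grids) and evaluated by bilinear interpolation, so the
// force felt by the walker is the exact gradient of the gridded bias.
// Randomness comes from R's RNG (norm_rand), so set.seed() on the R side
// makes every run bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int d;
  double lo[2], hi[2], sp[2];
  int n[2];
  std::vector<double> V, G1, G2;

  void init(const NumericVector& lo_, const NumericVector& hi_,
            const IntegerVector& n_) {
    d = lo_.size();
    size_t tot = 1;
    for (int j = 0; j < d; ++j) {
      lo[j] = lo_[j]; hi[j] = hi_[j]; n[j] = n_[j];
      if (n[j] < 2) stop("grid needs at least 2 nodes per axis");
      sp[j] = (hi[j] - lo[j]) / (n[j] - 1);
      tot *= (size_t)n[j];
    }
    V.assign(tot, 0.0);
    G1.assign(tot, 0.0);
    if (d == 2) G2.assign(tot, 0.0);
  }

  inline size_t idx(int i, int j) const {
    return (size_t)i + (size_t)n[0] * (size_t)j;
  }

  // deposit an axis-aligned Gaussian kernel, truncated at nsig sigmas
  void deposit(const double* c, const double* s, double h, double nsig) {
    int i0 = 0, i1 = n[0] - 1;
    if (R_finite(nsig)) {
      i0 = std::max(0, (int)std::ceil((c[0] - nsig * s[0] - lo[0]) / sp[0]));
      i1 = std::min(n[0] - 1,
                    (int)std::floor((c[0] + nsig * s[0] - lo[0]) / sp[0]));
    }
    if (d == 1) {
      for (int i = i0; i <= i1; ++i) {
        double x = lo[0] + i * sp[0];
        double q = (x - c[0]) / s[0];
        double e = h * std::exp(-0.5 * q * q);
        V[i] += e;
        G1[i] += e * (-q / s[0]);
      }
    } else {
      int j0 = 0, j1 = n[1] - 1;
      if (R_finite(nsig)) {
        j0 = std::max(0, (int)std::ceil((c[1] - nsig * s[1] - lo[1]) / sp[1]));
        j1 = std::min(n[1] - 1,
                      (int)std::floor((c[1] + nsig * s[1] - lo[1]) / sp[1]));
      }
      std::vector<double> ex(i1 - i0 + 1), qx(i1 - i0 + 1);
      for (int i = i0; i <= i1; ++i) {
        double q = (lo[0] + i * sp[0] - c[0]) / s[0];
        qx[i - i0] = q;
        ex[i - i0] = std::exp(-0.5 * q * q);
      }
      for (int j = j0; j <= j1; ++j) {
        double qy = (lo[1] + j * sp[1] - c[1]) / s[1];
        double ey = h * std::exp(-0.5 * qy * qy);
        for (int i = i0; i <= i1; ++i) {
          size_t k = idx(i, j);
          double e = ey * ex[i - i0];
          V[k] += e;
          G1[k] += e * (-qx[i - i0] / s[0]);
          G2[k] += e * (-qy / s[1]);
        }
      }
    }
  }

  // bilinear interpolation of a stored field
  double interp(const std::vector<double>& fld, const double* z) const {
    double t[2]; int ii[2];
    for (int j = 0; j < d; ++j) {
      double x = (z[j] - lo[j]) / sp[j];
      if (x < 0) x = 0;
      if (x > n[j] - 1) x = n[j] - 1;
      int i = (int)std::floor(x);
      if (i > n[j] - 2) i = n[j] - 2;
      ii[j] = i;
      t[j] = x - i;
    }
    if (d == 1) {
      return fld[ii[0]] * (1 - t[0]) + fld[ii[0] + 1] * t[0];
    }
    double f00 = fld[idx(ii[0], ii[1])], f10 = fld[idx(ii[0] + 1, ii[1])];
    double f01 = fld[idx(ii[0], ii[1] + 1)], f11 = fld[idx(ii[0] + 1, ii[1] + 1)];
    return f00 * (1 - t[0]) * (1 - t[1]) + f10 * t[0] * (1 - t[1]) +
           f01 * (1 - t[0]) * t[1] + f11 * t[0] * t[1];
  }

  // c(t) = (1/beta) [ lse(g/(g-1) beta V) - lse(1/(g-1) beta V) ],
  // trapezoid quadrature on the grid (edge nodes at half weight)
  double c_of_t(double beta, double gamma) const {
    double a = gamma / (gamma - 1.0) * beta;
    double b = 1.0 / (gamma - 1.0) * beta;
    double vmax = 0.0;
    for (size_t k = 0; k < V.size(); ++k) if (V[k] > vmax) vmax = V[k];
    double sa = 0.0, sb = 0.0;
    for (size_t k = 0; k < V.size(); ++k) {
      int i = (int)(k % (size_t)n[0]);
      double w = (i == 0 || i == n[0] - 1) ? 0.5 : 1.0;
      if (d == 2) {
        int j = (int)(k / (size_t)n[0]);
        w *= (j == 0 || j == n[1] - 1) ? 0.5 : 1.0;
      }
      sa += w * std::exp(a * (V[k] - vmax));
      sb += w * std::exp(b * (V[k] - vmax));
    }
    return (std::log(sa) - std::log(sb)) / beta + (a - b) * vmax / beta;
  }
};

struct Surface {
  int d, m;
  const double *h, *c, *s, *u, *tilt, *hk, *hc;

  void grad(const double* z, double* g) const {
    for (int j = 0; j < d; ++j)
      g[j] = tilt[j] + hk[j] * (z[j] - hc[j]);
    for (int k = 0; k < m; ++k) {
      double q = -c[k];
      for (int j = 0; j < d; ++j) q += u[k + (size_t)m * j] * z[j];
      double e = h[k] * std::exp(-q * q / (2.0 * s[k] * s[k]));
      double pref = e * (-q / (s[k] * s[k]));
      for (int j = 0; j < d; ++j) g[j] += pref * u[k + (size_t)m * j];
    }
  }
};

inline void reflect(double& z, double zmax) {
  while (z > zmax || z < -zmax) {
    if (z > zmax) z = 2 * zmax - z;
    if (z < -zmax) z = -2 * zmax - z;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_run_langevin(int d,
                      NumericVector term_h, NumericMatrix term_u,
                      NumericVector term_c, NumericVector term_s,
                      NumericVector tilt, NumericVector harm_k,
                      NumericVector harm_c,
                      int D_form, double D_bulk, double D_core, double D_width,
                      double beta, double dt, double n_steps_d,
                      int out_stride, NumericVector z_init, double z_max,
                      double max_jump,
                      bool metad, double w0, NumericVector ksigma,
                      int pace_steps, double gamma,
                      NumericVector grid_lo, NumericVector grid_hi,
                      IntegerVector grid_n, double trunc_nsig) {
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  Surface sf;
  sf.d = d; sf.m = term_h.size();
  sf.h = REAL(term_h); sf.c = REAL(term_c); sf.s = REAL(term_s);
  sf.u = REAL(term_u); sf.tilt = REAL(tilt);
  sf.hk = REAL(harm_k); sf.hc = REAL(harm_c);

  Grid grid;
  if (metad) {
    if (gamma <= 1.0) stop("bias factor gamma must be > 1");
    grid.init(grid_lo, grid_hi, grid_n);
  }
  double kT = 1.0 / beta;

  double z[2], g[2], dz[2];
  for (int j = 0; j < d; ++j) z[j] = z_init[j];

  const R_xlen_t n_out = n_steps / out_stride + 1;
  NumericMatrix frames(n_out, d);
  NumericVector ftimes(n_out), fbias(n_out);
  R_xlen_t iout = 0;
  for (int j = 0; j < d; ++j) frames(0, j) = z[j];
  ftimes[0] = 0.0; fbias[0] = 0.0;
  iout = 1;

  std::vector<double> h_time, h_h;
  std::vector<double> h_c(0), h_s(0);
  std::vector<double> ct;
  int nker = 0;

  const double dw2 = 2.0 * D_width * D_width;

  for (R_xlen_t step = 1; step <= n_steps; ++step) {
    sf.grad(z, g);
    if (metad && nker > 0) {
      g[0] += grid.interp(grid.G1, z);
      if (d == 2) g[1] += grid.interp(grid.G2, z);
    }
    for (int j = 0; j < d; ++j) {
      double D = D_bulk, dD = 0.0;
      if (D_form == 1) {
        double e = std::exp(-z[j] * z[j] / dw2);
        D = D_bulk + (D_core - D_bulk) * e;
        dD = (D_core - D_bulk) * e * (-2.0 * z[j] / dw2);
      }
      dz[j] = (-beta * D * g[j] + dD) * dt +
              std::sqrt(2.0 * D * dt) * norm_rand();
      if (std::fabs(dz[j]) > max_jump) {
        stop("integration diverged at step %td (|dz| = %g A); reduce dt",
             (ptrdiff_t)step, std::fabs(dz[j]));
      }
      z[j] += dz[j];
      reflect(z[j], z_max);
    }

    if (metad && (step % pace_steps == 0)) {
      double Vs = (nker > 0) ? grid.interp(grid.V, z) : 0.0;
      double w = w0 * std::exp(-Vs / ((gamma - 1.0) * kT));
      grid.deposit(z, REAL(ksigma), w, trunc_nsig);
      h_time.push_back(step * dt);
      h_h.push_back(w);
      for (int j = 0; j < d; ++j) h_c.push_back(z[j]);
      ++nker;
      ct.push_back(grid.c_of_t(beta, gamma));
    }

    if (step % out_stride == 0) {
      for (int j = 0; j < d; ++j) frames(iout, j) = z[j];
      ftimes[iout] = step * dt;
      fbias[iout] = (metad && nker > 0) ? grid.interp(grid.V, z) : 0.0;
      ++iout;
    }
    if (step % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["times"] = ftimes, _["values"] = frames, _["frame_bias"] = fbias);
  if (metad) {
    NumericMatrix centers(nker, d);
    for (int k = 0; k < nker; ++k)
      for (int j = 0; j < d; ++j) centers(k, j) = h_c[(size_t)k * d + j];
    out["hill_times"] = NumericVector(h_time.begin(), h_time.end());
    out["hill_centers"] = centers;
    out["hill_heights"] = NumericVector(h_h.begin(), h_h.end());
    out["c_of_t"] = NumericVector(ct.begin(), ct.end());
    out["bias_values"] = NumericVector(grid.V.begin(), grid.V.end());
  }
  return out;
}

// Sum axis-aligned Gaussian kernels on a grid. trunc_nsig = Inf gives the
// exact untruncated sum.
// [[Rcpp::export]]
NumericVector cpp_kernels_on_grid(NumericMatrix centers, NumericMatrix sigmas,
                                  NumericVector heights,
                                  NumericVector grid_lo, NumericVector grid_hi,
                                  IntegerVector grid_n, double trunc_nsig) {
  Grid grid;
  grid.init(grid_lo, grid_hi, grid_n);
  double c[2], s[2];
  for (int k = 0; k < centers.nrow(); ++k) {
    for (int j = 0; j < grid.d; ++j) { c[j] = centers(k, j); s[j] = sigmas(k, j); }
    grid.deposit(c, s, heights[k], trunc_nsig);
  }
  return NumericVector(grid.V.begin(), grid.V.end());
}

// Bias V(s_i, t_i) at time-ordered frames, replayed on the deposition grid:
// kernels are added in time order and each frame reads the grid state at its
// own time by bilinear interpolation.
// [[Rcpp::export]]
NumericVector cpp_bias_at_frames(NumericMatrix fpts, NumericVector ftimes,
                                 NumericVector ktimes, NumericMatrix kcenters,
                                 NumericMatrix ksigmas, NumericVector kheights,
                                 NumericVector grid_lo, NumericVector grid_hi,
                                 IntegerVector grid_n, double trunc_nsig) {
  Grid grid;
  grid.init(grid_lo, grid_hi, grid_n);
  const R_xlen_t n = fpts.nrow();
  const int m = kcenters.nrow();
  NumericVector out(n);
  double z[2], c[2], s[2];
  int k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    while (k < m && ktimes[k] <= ftimes[i]) {
      for (int j = 0; j < grid.d; ++j) { c[j] = kcenters(k, j); s[j] = ksigmas(k, j); }
      grid.deposit(c, s, kheights[k], trunc_nsig);
      ++k;
    }
    if (k == 0) { out[i] = 0.0; continue; }
    for (int j = 0; j < grid.d; ++j) z[j] = fpts(i, j);
    out[i] = grid.interp(grid.V, z);
  }
  return out;
}
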