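// Adaptive Dormand-Prince RK45 integration of the resource-competition
// dynamics. The derivative is inlined here because explicit integration of
// near-equilibrium chemostats takes ~1e5 steps and an R-level callback
// dominates runtime.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int ns, nr;
  const double *mu_max, *Ks, *q;  // ns x nr, column-major
  const double *D, *S, *fixedR;
  const int *dyn;                 // 0/1 per resource
  double m;
  int ndyn;

  // y = [B_1..B_ns, R_dyn...]; dy written in place
  void deriv(const double *y, double *dy, double *R, double *mu) const {
    int di = 0;
    for (int j = 0; j < nr; ++j)
      R[j] = dyn[j] ? std::max(y[ns + di++], 0.0) : fixedR[j];
    for (int i = 0; i < ns; ++i) {
      double mmin = R_PosInf;
      for (int j = 0; j < nr; ++j) {
        double v = mu_max[i + ns * j] * R[j] / (Ks[i + ns * j] + R[j]);
        if (v < mmin) mmin = v;
      }
      mu[i] = mmin;
      dy[i] = y[i] * (mmin - m);
    }
    di = 0;
    for (int j = 0; j < nr; ++j) {
      if (!dyn[j]) continue;
      double uptake = 0.0;
      for (int i = 0; i < ns; ++i) uptake += q[i + ns * j] * mu[i] * y[i];
      dy[ns + di++] = D[j] * (S[j] - R[j]) - uptake;
    }
  }
};

const double A2[] = {1.0 / 5};
const double A3[] = {3.0 / 40, 9.0 / 40};
const double A4[] = {44.0 / 45, -56.0 / 15, 32.0 / 9};
const double A5[] = {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561,
                     -212.0 / 729};
const double A6[] = {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176,
                     -5103.0 / 18656};
const double A7[] = {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192,
                     -2187.0 / 6784, 11.0 / 84};
const double *AA[] = {A2, A3, A4, A5, A6, A7};
const double B5[] = {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192,
                     -2187.0 / 6784, 11.0 / 84, 0};
const double B4[] = {5179.0 / 57600, 0, 7571.0 / 16695, 393.0 / 640,
                     -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};
const double CS[] = {0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1, 1};

} // namespace

// [[Rcpp::export(name = ".rk45_cpp")]]
List rk45_cpp(NumericVector y0, NumericVector times, NumericMatrix mu_max,
              NumericMatrix Ks, NumericMatrix q, NumericVector D,
              NumericVector S, NumericVector fixedR, IntegerVector dyn,
              double m, double rtol, double atol, double h0) {
  const int ny = y0.size(), nt = times.size();
  const int ns = mu_max.nrow(), nr = mu_max.ncol();
  Model mod{ns, nr, REAL(mu_max), REAL(Ks), REAL(q), REAL(D), REAL(S),
            REAL(fixedR), INTEGER(dyn), m, ny - ns};
  NumericMatrix out(nt, ny);
  std::vector<double> y(y0.begin(), y0.end()), ys(ny), y5(ny), y4(ny);
  std::vector<double> Rbuf(nr), mubuf(ns);
  std::vector< std::vector<double> > k(7, std::vector<double>(ny));
  for (int c = 0; c < ny; ++c) out(0, c) = y[c];
  double t = times[0];
  double h = h0 > 0 ? h0 : std::min(0.1, (times[nt - 1] - times[0]) / 100);
  mod.deriv(y.data(), k[0].data(), Rbuf.data(), mubuf.data());
  bool have_k1 = true;
  for (int ti = 1; ti < nt; ++ti) {
    double target = times[ti];
    long guard = 0;
    while (t < target - 1e-12) {
      if (++guard > 100000000L)
        stop("rk45: step limit exceeded at t = %g", t);
      if (h > target - t) h = target - t;
      if (!have_k1) {
        mod.deriv(y.data(), k[0].data(), Rbuf.data(), mubuf.data());
        have_k1 = true;
      }
      for (int s = 1; s < 7; ++s) {
        for (int c = 0; c < ny; ++c) {
          double acc = 0;
          for (int p = 0; p < s; ++p) acc += AA[s - 1][p] * k[p][c];
          ys[c] = y[c] + h * acc;
        }
        mod.deriv(ys.data(), k[s].data(), Rbuf.data(), mubuf.data());
        (void)CS; // stage times unused: the system is autonomous
      }
      double err = 0;
      for (int c = 0; c < ny; ++c) {
        double a5 = 0, a4 = 0;
        for (int s = 0; s < 7; ++s) {
          a5 += B5[s] * k[s][c];
          a4 += B4[s] * k[s][c];
        }
        y5[c] = y[c] + h * a5;
        y4[c] = y[c] + h * a4;
        double sc = atol + rtol * std::max(std::fabs(y[c]), std::fabs(y5[c]));
        double e = (y5[c] - y4[c]) / sc;
        err += e * e;
      }
      err = std::sqrt(err / ny);
      if (!std::isfinite(err)) stop("rk45: non-finite state at t = %g", t);
      if (err <= 1) {
        t += h;
        bool clipped = false;
        for (int c = 0; c < ny; ++c) {
          if (y5[c] < 0) { y5[c] = 0; clipped = true; }
          y[c] = y5[c];
        }
        if (clipped) {
          have_k1 = false;   // FSAL invalid after clipping
        } else {
          k[0] = k[6];
        }
      }
      double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5) fac = 5;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    for (int c = 0; c < ny; ++c) out(ti, c) = y[c];
  }
  return List::create(_["y"] = out, _["h"] = h);
}
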