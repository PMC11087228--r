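// Adaptive Dormand-Prince 5(4) integrator for the pathway ODE.
//
// The reaction network is passed as a flat table so that user-supplied
// parameter sets (and toy models in the tests) reuse the same kernel:
//   r_type: 0 = Michaelis-Menten, 1 = mass action,
//           2 = competitive MM,   3 = bisubstrate competitive MM
//   r_enz:  0-based enzyme index into enzyme_conc
//   r_sub1, r_sub2: 0-based substrate species indices (-1 = unused)
//   pool_*: concatenated competitor pools, offsets in pool_start (length nr+1)
//   stoich: n_species x n_reactions net stoichiometry matrix
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Network {
  int ns, nr;
  const int *type, *enz, *sub1, *sub2;
  const double *k, *km1, *km2;
  const int *pool_start, *pool_sp;
  const double *pool_km;
  const double *stoich;  // column-major ns x nr
  const double *econc;   // per-enzyme concentration
};

inline double reaction_rate(const Network &net, int r, const double *y) {
  const double E = net.econc[net.enz[r]];
  if (E <= 0.0) return 0.0;
  double s1 = net.sub1[r] >= 0 ? y[net.sub1[r]] : 0.0;
  if (s1 < 0.0) s1 = 0.0;
  switch (net.type[r]) {
  case 0:  // Michaelis-Menten
    return net.k[r] * E * s1 / (net.km1[r] + s1);
  case 1:  // mass action (enzyme-proportional)
    return net.k[r] * E * s1;
  case 2: case 3: {
    double denom = 1.0;
    for (int j = net.pool_start[r]; j < net.pool_start[r + 1]; ++j) {
      double c = y[net.pool_sp[j]];
      if (c < 0.0) c = 0.0;
      denom += c / net.pool_km[j];
    }
    if (net.type[r] == 2) return net.k[r] * E * (s1 / net.km1[r]) / denom;
    double s2 = net.sub2[r] >= 0 ? y[net.sub2[r]] : 0.0;
    if (s2 < 0.0) s2 = 0.0;
    return net.k[r] * E * (s1 / net.km1[r]) * (s2 / net.km2[r]) / (denom * denom);
  }
  }
  return 0.0;
}

inline void rhs(const Network &net, const double *y, double *dy) {
  for (int i = 0; i < net.ns; ++i) dy[i] = 0.0;
  for (int r = 0; r < net.nr; ++r) {
    const double v = reaction_rate(net, r, y);
    if (v == 0.0) continue;
    const double *col = net.stoich + (size_t)r * net.ns;
    for (int i = 0; i < net.ns; ++i) dy[i] += col[i] * v;
  }
}

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

}  // namespace

// [[Rcpp::export]]
NumericVector pathway_rhs_cpp(NumericVector y,
                              IntegerVector r_type, IntegerVector r_enz,
                              IntegerVector r_sub1, IntegerVector r_sub2,
                              NumericVector r_k, NumericVector r_km1,
                              NumericVector r_km2,
                              IntegerVector pool_start, IntegerVector pool_sp,
                              NumericVector pool_km, NumericMatrix stoich,
                              NumericVector enzyme_conc) {
  Network net{(int)y.size(), (int)r_type.size(),
              r_type.begin(), r_enz.begin(), r_sub1.begin(), r_sub2.begin(),
              r_k.begin(), r_km1.begin(), r_km2.begin(),
              pool_start.begin(), pool_sp.begin(), pool_km.begin(),
              stoich.begin(), enzyme_conc.begin()};
  NumericVector dy(y.size());
  rhs(net, y.begin(), dy.begin());
  return dy;
}

// [[Rcpp::export]]
List pathway_ode_cpp(NumericVector y0, NumericVector times,
                     IntegerVector r_type, IntegerVector r_enz,
                     IntegerVector r_sub1, IntegerVector r_sub2,
                     NumericVector r_k, NumericVector r_km1,
                     NumericVector r_km2,
                     IntegerVector pool_start, IntegerVector pool_sp,
                     NumericVector pool_km, NumericMatrix stoich,
                     NumericVector enzyme_conc,
                     double rtol, double atol, double max_steps) {
  const int ns = y0.size(), nt = times.size();
  Network net{ns, (int)r_type.size(),
              r_type.begin(), r_enz.begin(), r_sub1.begin(), r_sub2.begin(),
              r_k.begin(), r_km1.begin(), r_km2.begin(),
              pool_start.begin(), pool_sp.begin(), pool_km.begin(),
              stoich.begin(), enzyme_conc.begin()};

  NumericMatrix out(nt, ns);
  std::vector<double> y(y0.begin(), y0.end()), ynew(ns), yerr(ns),
      k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns), ytmp(ns);

  double t = times[0];
  for (int i = 0; i < ns; ++i) out(0, i) = y[i];

  rhs(net, y.data(), k1.data());
  double h = (times[nt - 1] - t) / 100.0;
  if (h <= 0) h = 1e-3;
  long steps = 0;
  int next_report = 1;

  while (next_report < nt) {
    if (++steps > (long)max_steps)
      stop("ODE integration exceeded max_steps = %g at t = %g (h = %g)",
           max_steps, t, h);
    const double t_target = times[next_report];
    bool hit = false;
    if (t + h >= t_target) { h = t_target - t; hit = true; }

    for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(net, ytmp.data(), k2.data());
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(net, ytmp.data(), k3.data());
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(net, ytmp.data(), k4.data());
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(net, ytmp.data(), k5.data());
    for (int i = 0; i < ns; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(net, ytmp.data(), k6.data());
    for (int i = 0; i < ns; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(net, ynew.data(), k7.data());
    for (int i = 0; i < ns; ++i)
      yerr[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                     e6 * k6[i] + e7 * k7[i]);

    double errnorm = 0.0;
    for (int i = 0; i < ns; ++i) {
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double e = yerr[i] / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / ns);

    if (errnorm <= 1.0) {  // accept
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      if (hit) {
        for (int i = 0; i < ns; ++i) out(next_report, i) = y[i];
        ++next_report;
      }
    }
    double fac = errnorm > 0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14) stop("ODE step size underflow at t = %g", t);
  }

  return List::create(_["y"] = out, _["steps"] = (double)steps);
}
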