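#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mass-action right-hand side: dy = S %*% (k * prod_i y_i^orders[i, j]).
// `stoich` and `orders` are n_species x n_reactions; orders are small
// non-negative integers, so powers are unrolled as products.
static inline void mass_action_rhs(const std::vector<double>& y,
                                   const NumericMatrix& stoich,
                                   const IntegerMatrix& orders,
                                   const NumericVector& k,
                                   std::vector<double>& dy) {
  const int ns = stoich.nrow(), nr = stoich.ncol();
  std::fill(dy.begin(), dy.end(), 0.0);
  for (int j = 0; j < nr; ++j) {
    double rate = k[j];
    if (rate == 0.0) continue;
    for (int i = 0; i < ns; ++i) {
      const int o = orders(i, j);
      for (int p = 0; p < o; ++p) rate *= y[i];
    }
    if (rate == 0.0) continue;
    for (int i = 0; i < ns; ++i) {
      const double s = stoich(i, j);
      if (s != 0.0) dy[i] += s * rate;
    }
  }
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients.
static const double CK_A[6] = {0.0, 1.0/5, 3.0/10, 3.0/5, 1.0, 7.0/8};
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0/5, 0, 0, 0, 0},
  {3.0/40, 9.0/40, 0, 0, 0},
  {3.0/10, -9.0/10, 6.0/5, 0, 0},
  {-11.0/54, 5.0/2, -70.0/27, 35.0/27, 0},
  {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}};
static const double CK_C5[6]  = {37.0/378, 0, 250.0/621, 125.0/594, 0, 512.0/1771};
static const double CK_C4[6]  = {2825.0/27648, 0, 18575.0/48384, 13525.0/55296,
                                 277.0/14336, 1.0/4};

// Clamp tiny negative excursions (round-off on species near zero); anything
// materially negative signals an integration failure.
static inline void clamp_nonneg(std::vector<double>& y, double floor_tol) {
  for (size_t i = 0; i < y.size(); ++i) {
    if (y[i] < 0.0) {
      if (y[i] < -floor_tol)
        stop("integrator produced a materially negative concentration (%g)", y[i]);
      y[i] = 0.0;
    }
  }
}

// [[Rcpp::export(name = ".cpp_integrate_adaptive")]]
NumericMatrix cpp_integrate_adaptive(NumericVector y0, NumericMatrix stoich,
                                     IntegerMatrix orders, NumericVector k,
                                     NumericVector t_grid, double rtol,
                                     double atol, double max_steps) {
  const int ns = y0.size(), nt = t_grid.size();
  NumericMatrix out(nt, ns);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> ytmp(ns), yerr(ns), y5(ns), dy(ns);
  std::vector< std::vector<double> > ks(6, std::vector<double>(ns));

  double t = t_grid[0];
  for (int i = 0; i < ns; ++i) out(0, i) = y[i];

  double h = (t_grid[nt - 1] - t) * 1e-6;
  if (h <= 0) stop("time grid must span a positive interval");
  double steps = 0;
  int next = 1;

  while (next < nt) {
    const double t_target = t_grid[nt - 1];
    if (t + h > t_grid[next]) h = t_grid[next] - t;
    if (h < (t_target - t_grid[0]) * 1e-14)
      stop("adaptive integrator failed: step size underflow at t = %g", t);

    // six stages
    mass_action_rhs(y, stoich, orders, k, ks[0]);
    for (int s = 1; s < 6; ++s) {
      for (int i = 0; i < ns; ++i) {
        double acc = y[i];
        for (int q = 0; q < s; ++q) acc += h * CK_B[s][q] * ks[q][i];
        ytmp[i] = acc;
      }
      mass_action_rhs(ytmp, stoich, orders, k, ks[s]);
    }
    double errmax = 0.0;
    for (int i = 0; i < ns; ++i) {
      double s5 = y[i], s4 = y[i];
      for (int q = 0; q < 6; ++q) {
        s5 += h * CK_C5[q] * ks[q][i];
        s4 += h * CK_C4[q] * ks[q][i];
      }
      y5[i] = s5;
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(s5));
      errmax = std::max(errmax, std::fabs(s5 - s4) / sc);
    }
    if (!std::isfinite(errmax))
      stop("adaptive integrator failed: non-finite state at t = %g", t);

    if (errmax <= 1.0) { // accept
      t += h;
      y = y5;
      clamp_nonneg(y, atol * 1e3 + 1e-18);
      while (next < nt && t >= t_grid[next] - 1e-12 * std::fabs(t_grid[next])) {
        for (int i = 0; i < ns; ++i) out(next, i) = y[i];
        ++next;
      }
      h *= std::min(5.0, 0.9 * std::pow(std::max(errmax, 1e-10), -0.2));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errmax, -0.25));
    }
    if (++steps > max_steps)
      stop("adaptive integrator failed: exceeded %g steps", max_steps);
  }
  return out;
}

// Fixed-step classic RK4; serves as the independent explicit-stepper oracle.
// [[Rcpp::export(name = ".cpp_integrate_rk4")]]
NumericMatrix cpp_integrate_rk4(NumericVector y0, NumericMatrix stoich,
                                IntegerMatrix orders, NumericVector k,
                                NumericVector t_grid, double dt) {
  const int ns = y0.size(), nt = t_grid.size();
  NumericMatrix out(nt, ns);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), ytmp(ns);
  for (int i = 0; i < ns; ++i) out(0, i) = y[i];

  double t = t_grid[0];
  for (int next = 1; next < nt; ++next) {
    while (t < t_grid[next] - 1e-12) {
      const double h = std::min(dt, t_grid[next] - t);
      mass_action_rhs(y, stoich, orders, k, k1);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
      mass_action_rhs(ytmp, stoich, orders, k, k2);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * h * k2[i];
      mass_action_rhs(ytmp, stoich, orders, k, k3);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * k3[i];
      mass_action_rhs(ytmp, stoich, orders, k, k4);
      for (int i = 0; i < ns; ++i) {
        y[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
        if (y[i] < 0.0) {
          if (y[i] < -1e-12) stop("rk4 produced a materially negative concentration");
          y[i] = 0.0;
        }
      }
      if (!std::isfinite(y[0]))
        stop("rk4 integrator failed: non-finite state at t = %g", t);
      t += h;
    }
    for (int i = 0; i < ns; ++i) out(next, i) = y[i];
  }
  return out;
}
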