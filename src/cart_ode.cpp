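#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout (8): dose, dosex, t_m, t_e1, t_e2, t_x, b, b_a
// Parameter layout (27), canonical order shared with R/parameters.R:
//  0 b50    1 mu_b   2 k_kill 3 f_loss 4 tk50  5 kt    6 k_b1
//  7 k_b2   8 mu_m   9 km    10 f_max 11 ke   12 mu_e 13 n_doub
// 14 k_ex  15 d_m   16 d_e1  17 d_e2  18 d_x  19 b_max
// 20 kx    21 kr    22 r_m   23 f_tm  24 f_te1 25 f_te2 26 f_tx

static inline double hill_up(double x, double half, double k) {
  if (x <= 0.0) return 0.0;
  double r = std::pow(x / half, k);
  return r / (1.0 + r);
}

static void rhs(const double *y, const double *p, double *dy) {
  const double dose = y[0], dosex = y[1], tm = y[2], te1 = y[3],
               te2 = y[4], tx = y[5], b = y[6], ba = y[7];
  const double b50 = p[0], mu_b = p[1], k_kill = p[2], f_loss = p[3],
               tk50 = p[4], kt = p[5], k_b1 = p[6], k_b2 = p[7],
               mu_m = p[8], km = p[9], f_max = p[10], ke = p[11],
               mu_e = p[12], n_doub = p[13], k_ex = p[14], d_m = p[15],
               d_e1 = p[16], d_e2 = p[17], d_x = p[18], b_max = p[19],
               kx = p[20], kr = p[21], r_m = p[22], f_tm = p[23],
               f_te1 = p[24], f_te2 = p[25], f_tx = p[26];

  const double hm = hill_up(ba, b50, km);   // memory self-renewal switch (up)
  const double hr = hill_up(ba, b50, kr);   // memory regeneration switch (up)
  const double he = hill_up(ba, b50, ke);   // effector proliferation switch
  const double hx = hill_up(ba, b50, kx);   // exhaustion switch
  const double ht = hill_up(te2, tk50, kt); // tumor-killing saturation
  const double frac_sum = f_tm + f_te1 + f_te2 + f_tx;

  dy[0] = -(1.0 + f_loss) * dose;
  dy[1] = dose - frac_sum * dosex;
  dy[2] = mu_m * (2.0 * f_max * (1.0 - hm) - 1.0) * tm +
          r_m * (1.0 - hr) * te2 - d_m * tm + f_tm * dosex;
  dy[3] = 2.0 * mu_m * (1.0 - f_max * (1.0 - hm)) * tm -
          mu_e * he * te1 - d_e1 * te1 + f_te1 * dosex;
  dy[4] = mu_e * std::pow(2.0, n_doub) * he * te1 - k_ex * hx * te2 -
          r_m * (1.0 - hr) * te2 - d_e2 * te2 + f_te2 * dosex;
  dy[5] = k_ex * hx * te2 - d_x * tx + f_tx * dosex;
  dy[6] = mu_b * (1.0 - b / b_max) * b - k_kill * ht * b;
  dy[7] = k_b1 * b - k_b2 * ba;
}

// [[Rcpp::export(name = ".cart_rhs_cpp")]]
NumericVector cart_rhs_cpp(NumericVector state, NumericVector params) {
  if (state.size() != 8) stop("state must have length 8");
  if (params.size() != 27) stop("params must have length 27");
  NumericVector out(8);
  rhs(REAL(state), REAL(params), REAL(out));
  return out;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                    c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate one interval [t0, t1] with adaptive DP45. y is modified in place.
// Returns false on step-size underflow.
static bool integrate_interval(double t0, double t1, double *y,
                               const double *p, double rtol, double atol,
                               double *h_io, long *nsteps, long max_steps) {
  const int n = 8;
  double t = t0, h = *h_io;
  double k1[8], k2[8], k3[8], k4[8], k5[8], k6[8], k7[8], yt[8], ynew[8];
  rhs(y, p, k1);
  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    if (h < 1e-13) return false;
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(yt, p, k2);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(yt, p, k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(yt, p, k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    rhs(yt, p, k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(yt, p, k6);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(ynew, p, k7);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) {
      h *= 0.25;
      rhs(y, p, k1);
      continue;
    }
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i]; // FSAL
      }
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (++(*nsteps) > max_steps) return false;
  }
  *h_io = h;
  return true;
}

// [[Rcpp::export(name = ".cart_integrate_cpp")]]
NumericMatrix cart_integrate_cpp(NumericVector y0, NumericVector params,
                                 NumericVector times, double extinction,
                                 double rtol, double atol) {
  if (y0.size() != 8) stop("y0 must have length 8");
  if (params.size() != 27) stop("params must have length 27");
  const int nt = times.size();
  NumericMatrix out(nt, 8);
  double y[8];
  for (int i = 0; i < 8; ++i) y[i] = y0[i];
  // clamp applies to cell-count compartments (not antigen)
  auto clamp = [&](double *v) {
    for (int i = 0; i < 7; ++i)
      if (v[i] < extinction) v[i] = 0.0;
    if (v[7] < 0.0) v[7] = 0.0;
  };
  clamp(y);
  for (int i = 0; i < 8; ++i) out(0, i) = y[i];
  double h = (nt > 1) ? (times[1] - times[0]) / 20.0 : 1e-3;
  long nsteps = 0;
  const long max_steps = 20000000L;
  for (int j = 1; j < nt; ++j) {
    if (!integrate_interval(times[j - 1], times[j], y, REAL(params), rtol,
                            atol, &h, &nsteps, max_steps))
      stop("ODE integration failed near t=%g (step underflow or step cap)",
           times[j - 1]);
    clamp(y);
    for (int i = 0; i < 8; ++i) out(j, i) = y[i];
  }
  return out;
}
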