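#include <Rcpp.h>
using namespace Rcpp;

// Five-stage mosquito system right-hand side.  r points at the 11 rates of
// one day: d_E d_L d_P m_E m_L m_P m_A o_v z1 z2 K.
static inline void deriv(const double *s, const double *r, double *ds) {
  const double E = s[0], Edia = s[1], L = s[2], P = s[3], A = s[4];
  const double dE = r[0], dL = r[1], dP = r[2], mE = r[3], mL = r[4],
               mP = r[5], mA = r[6], ov = r[7], z1 = r[8], z2 = r[9],
               K = r[10];
  ds[0] = (1.0 - z1) * ov * A - (mE + dE) * E + z2 * Edia;
  ds[1] = z1 * ov * A - z2 * Edia;
  ds[2] = dE * E - (mL + dL + L / K) * L;
  ds[3] = dL * L - (mP + dP) * P;
  ds[4] = dP * P - mA * A;
}

// Daily RK4 integration of the five-stage system.  `rates` has one row per
// day (11 columns); the day's rates are held constant across the day's
// sub-steps.  Each day is integrated with at least `substeps` equal RK4
// sub-steps; a stability guard subdivides further whenever the fastest
// per-capita rate (including the state-dependent larval crowding term
// L / K, which can spike when the overwintered egg bank is released) would
// otherwise exceed 0.1 per sub-step, keeping the explicit scheme well
// inside its accuracy region.  States are clamped at zero after each
// sub-step.  Returns the end-of-day state for every day.
// [[Rcpp::export]]
NumericMatrix rk4_core(NumericVector init, NumericMatrix rates, int substeps) {
  const int n = rates.nrow();
  if (rates.ncol() != 11) stop("rates must have 11 columns");
  if (substeps < 1) stop("substeps must be >= 1");
  NumericMatrix out(n, 5);
  double s[5], k1[5], k2[5], k3[5], k4[5], tmp[5], r[11];
  for (int j = 0; j < 5; ++j) s[j] = init[j];
  const double target = 0.1;   // max per-capita rate per sub-step
  const int max_sub = 4000;

  for (int day = 0; day < n; ++day) {
    for (int c = 0; c < 11; ++c) r[c] = rates(day, c);
    if (r[10] <= 0.0) stop("carrying capacity <= 0 on day %d", day + 1);

    // fastest per-capita loss rate this day, using a one-day-inflow bound
    // on the larval pool for the crowding term
    double l_bound = s[2] + r[0] * s[0];
    double fast = r[3] + r[0];                      // eggs
    double v = r[9]; if (v > fast) fast = v;        // diapause release
    v = r[4] + r[1] + l_bound / r[10];              // larvae + crowding
    if (v > fast) fast = v;
    v = r[5] + r[2]; if (v > fast) fast = v;        // pupae
    if (r[6] > fast) fast = r[6];                   // adults
    int nsub = (int)std::ceil(fast / target);
    if (nsub < substeps) nsub = substeps;
    if (nsub > max_sub) nsub = max_sub;
    const double h = 1.0 / nsub;

    for (int sub = 0; sub < nsub; ++sub) {
      deriv(s, r, k1);
      for (int j = 0; j < 5; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
      deriv(tmp, r, k2);
      for (int j = 0; j < 5; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
      deriv(tmp, r, k3);
      for (int j = 0; j < 5; ++j) tmp[j] = s[j] + h * k3[j];
      deriv(tmp, r, k4);
      for (int j = 0; j < 5; ++j) {
        s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (s[j] < 0.0) s[j] = 0.0;
      }
    }
    for (int j = 0; j < 5; ++j) {
      if (!R_finite(s[j]))
        stop("numerical instability: non-finite state on day %d", day + 1);
      out(day, j) = s[j];
    }
  }
  return out;
}
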