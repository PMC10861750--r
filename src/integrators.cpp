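#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrators for the two generative stages. Forcing and
// inputs are sampled by zero-order hold: the value at sample i is held
// constant over the step from t_i to t_{i+1}.

// [[Rcpp::export(name = ".vdp_rk4")]]
NumericVector vdp_rk4(double lam, double p, double gain,
                      NumericVector init, int n, double dt,
                      NumericVector forcing, double bound) {
  NumericVector out(n);
  double y = init[0], v = init[1];
  const bool has_f = forcing.size() > 0;
  const double p2 = p * p;
  out[0] = y;
  for (int i = 1; i < n; i++) {
    const double f = has_f ? gain * forcing[i - 1] : 0.0;
    const double k1y = v;
    const double k1v = (lam - y * y) * v - p2 * y + f;
    const double ya = y + 0.5 * dt * k1y, va = v + 0.5 * dt * k1v;
    const double k2y = va;
    const double k2v = (lam - ya * ya) * va - p2 * ya + f;
    const double yb = y + 0.5 * dt * k2y, vb = v + 0.5 * dt * k2v;
    const double k3y = vb;
    const double k3v = (lam - yb * yb) * vb - p2 * yb + f;
    const double yc = y + dt * k3y, vc = v + dt * k3v;
    const double k4y = vc;
    const double k4v = (lam - yc * yc) * vc - p2 * yc + f;
    y += dt / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
    v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    if (!std::isfinite(y) || !std::isfinite(v) || std::fabs(y) > bound)
      stop("oscillator trajectory exceeded magnitude bound %g at step %d (dt = %g); "
           "reduce dt or the forcing gain", bound, i, dt);
    out[i] = y;
  }
  return out;
}

static inline double sigz(double v, double e0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(-r * v)) - e0;
}

// Parameter vector layout (fixed order, see nmm_param_vector() on the R side):
// 0:C12 1:C21 2:C13 3:C31 4:C14 5:C41 6:C43 7:C44
// 8:G2 9:G3 10:G4 11:w2 12:w3 13:w4 14:e0 15:r
static inline void nmm_deriv(const double *s, const double *P,
                             double u1, double u4, double *ds) {
  const double C12 = P[0], C21 = P[1], C13 = P[2], C31 = P[3];
  const double C14 = P[4], C41 = P[5], C43 = P[6], C44 = P[7];
  const double G2 = P[8], G3 = P[9], G4 = P[10];
  const double w2 = P[11], w3 = P[12], w4 = P[13];
  const double e0 = P[14], r = P[15];

  const double v1 = C12 * s[2] - C13 * s[4] - C14 * s[6];
  const double v2 = C21 * s[0];
  const double v3 = C31 * s[0];
  const double v4 = C41 * s[0] - C43 * s[4] - C44 * s[6] + s[8];

  const double z1 = sigz(v1, e0, r);
  const double z2 = sigz(v2, e0, r);
  const double z3 = sigz(v3, e0, r);
  const double z4 = sigz(v4, e0, r);

  ds[0] = s[1];
  ds[1] = G2 * w2 * z1 - 2.0 * w2 * s[1] - w2 * w2 * s[0];
  // the R surface rejects C12 = 0 with nonzero u1; with u1 = 0 the
  // external drive vanishes rather than producing 0/0
  const double drive = (C12 != 0.0) ? u1 / C12 : 0.0;
  ds[2] = s[3];
  ds[3] = G2 * w2 * (z2 + drive) - 2.0 * w2 * s[3] - w2 * w2 * s[2];
  ds[4] = s[5];
  ds[5] = G3 * w3 * z3 - 2.0 * w3 * s[5] - w3 * w3 * s[4];
  ds[6] = s[7];
  ds[7] = G4 * w4 * z4 - 2.0 * w4 * s[7] - w4 * w4 * s[6];
  ds[8] = s[9];
  ds[9] = G2 * w2 * u4 - 2.0 * w2 * s[9] - w2 * w2 * s[8];
}

// Integrates the ten-state neural mass model. `par2`/`switch_step` allow an
// evoked change of connectivity: steps with index >= switch_step use par2.
// Returns an n x 11 matrix: columns 1..10 are the state, column 11 is v1.
// [[Rcpp::export(name = ".nmm_rk4")]]
NumericMatrix nmm_rk4(NumericVector par, NumericVector par2, int switch_step,
                      NumericVector init, NumericVector u1, NumericVector u4,
                      double dt, double bound) {
  const int n = u1.size();
  NumericMatrix out(n, 11);
  double s[10], k1[10], k2[10], k3[10], k4[10], tmp[10];
  for (int j = 0; j < 10; j++) s[j] = init[j];

  const double *P0 = REAL(par);
  const double *P1 = REAL(par2);

  for (int i = 0; i < n; i++) {
    const double *P = (i >= switch_step) ? P1 : P0;
    for (int j = 0; j < 10; j++) out(i, j) = s[j];
    out(i, 10) = P[0] * s[2] - P[2] * s[4] - P[4] * s[6];
    if (i == n - 1) break;

    const double a = u1[i], b = u4[i];
    nmm_deriv(s, P, a, b, k1);
    for (int j = 0; j < 10; j++) tmp[j] = s[j] + 0.5 * dt * k1[j];
    nmm_deriv(tmp, P, a, b, k2);
    for (int j = 0; j < 10; j++) tmp[j] = s[j] + 0.5 * dt * k2[j];
    nmm_deriv(tmp, P, a, b, k3);
    for (int j = 0; j < 10; j++) tmp[j] = s[j] + dt * k3[j];
    nmm_deriv(tmp, P, a, b, k4);
    for (int j = 0; j < 10; j++) {
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(s[j]) || std::fabs(s[j]) > bound)
        stop("neural mass state exceeded magnitude bound %g at step %d (dt = %g)",
             bound, i + 1, dt);
    }
  }
  return out;
}
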