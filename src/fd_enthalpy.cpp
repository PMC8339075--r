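#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-dimensional explicit conservative enthalpy-method march for the
// two-phase freezing problem on a uniform grid. Latent heat is smeared over
// a mushy band of half-width `delta` around the transition temperature `Tm`
// (apparent-heat-capacity formulation expressed through a piecewise-linear
// enthalpy-temperature relation, which makes the scheme exactly
// conservative). Node 0 is held at the surface temperature, node n-1 at the
// far-field (body) temperature.
//
// Enthalpy datum: H = 0 at T = Tm - delta (fully frozen edge of the band).
//
// The sweep is fused (face flux and node update in one pass over old-time
// values) and restricted to the active region behind the thermal
// disturbance front, which grows by at most one cell per step in an
// explicit scheme.

static inline double enth_from_T(double T, double T1, double T2,
                                 double c1, double c2, double cm, double Hm) {
  if (T < T1) return c1 * (T - T1);
  if (T <= T2) return cm * (T - T1);
  return Hm + c2 * (T - T2);
}

static inline double T_from_enth(double H, double T1, double T2,
                                 double c1, double c2, double cm, double Hm) {
  if (H < 0.0) return T1 + H / c1;
  if (H <= Hm) return T1 + H / cm;
  return T2 + (H - Hm) / c2;
}

static inline double cond_of_T(double T, double T1, double T2,
                               double k1, double k2) {
  if (T < T1) return k1;
  if (T > T2) return k2;
  return k1 + (k2 - k1) * (T - T1) / (T2 - T1);
}

// [[Rcpp::export(name = ".fd_enthalpy_march")]]
List fd_enthalpy_march(int n, double dx, double dt, int nsteps,
                       IntegerVector out_steps,
                       double Ts, double Ti,
                       double k1, double k2, double c1, double c2,
                       double rho, double L, double Tm, double delta) {
  const double T1 = Tm - delta, T2 = Tm + delta;
  const double cm = 0.5 * (c1 + c2) + L / (2.0 * delta);
  const double Hm = cm * (T2 - T1);
  const double invdx = 1.0 / dx;
  const double wupd = dt / (rho * dx);

  std::vector<double> T(n), H(n), kc(n);
  for (int i = 0; i < n; ++i) T[i] = Ti;
  T[0] = Ts;
  for (int i = 0; i < n; ++i) H[i] = enth_from_T(T[i], T1, T2, c1, c2, cm, Hm);
  for (int i = 0; i < n; ++i) kc[i] = cond_of_T(T[i], T1, T2, k1, k2);

  double U0 = 0.0;
  for (int i = 1; i < n - 1; ++i) U0 += H[i];
  U0 *= rho * dx;

  int nout = out_steps.size();
  NumericMatrix Tout(nout, n);
  NumericVector tout(nout), flux0_out(nout);
  double Ebound = 0.0;   // cumulative net boundary energy into interior, J/m^2
  int oi = 0;
  while (oi < nout && out_steps[oi] == 0) {
    for (int i = 0; i < n; ++i) Tout(oi, i) = T[i];
    tout[oi] = 0.0;
    flux0_out[oi] = 0.0;
    ++oi;
  }

  int iact = 2;                       // last interior node swept
  const double tiny = 1e-12 * (std::fabs(Ti - Ts) + 1.0);

  for (int s = 1; s <= nsteps; ++s) {
    double F0 = 0.5 * (kc[0] + kc[1]) * (T[1] - T[0]) * invdx;
    double Fprev = F0;                // face between i-1 and i, old values
    double Tip = T[1];                // old T[i] (not yet overwritten)
    double kip = kc[1];
    for (int i = 1; i <= iact; ++i) {
      double Tnext = T[i + 1];
      double knext = kc[i + 1];
      double Fi = 0.5 * (kip + knext) * (Tnext - Tip) * invdx;
      H[i] += wupd * (Fi - Fprev);
      double Tn = T_from_enth(H[i], T1, T2, c1, c2, cm, Hm);
      T[i] = Tn;
      kc[i] = cond_of_T(Tn, T1, T2, k1, k2);
      Fprev = Fi;
      Tip = Tnext;
      kip = knext;
    }
    // the enthalpy updates telescope to the flux through the last swept
    // face minus the surface flux
    Ebound += dt * (Fprev - F0);
    if (iact < n - 2 && std::fabs(T[iact] - Ti) > tiny) ++iact;

    while (oi < nout && out_steps[oi] == s) {
      for (int i = 0; i < n; ++i) Tout(oi, i) = T[i];
      tout[oi] = s * dt;
      flux0_out[oi] = 0.5 * (kc[0] + kc[1]) * (T[1] - T[0]) * invdx;
      ++oi;
    }
  }

  double U1 = 0.0;
  for (int i = 1; i < n - 1; ++i) U1 += H[i];
  U1 *= rho * dx;

  return List::create(
    _["temperature"] = Tout,
    _["times"] = tout,
    _["flux_surface"] = flux0_out,
    _["boundary_energy"] = Ebound,
    _["enthalpy_change"] = U1 - U0);
}
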