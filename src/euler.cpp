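#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step explicit integration of the compartmental convection-diffusion
// network.
//
// State: tracer mole fraction chi per airway unit.  Continuous form:
//   V_i dchi_i/dt = conv_in - conv_out + diff - chi_i dV_i/dt
// with upwind convective fluxes switched by the breathing phase (inspiration
// during the first half of each period), Fick fluxes G_i (chi_parent - chi_i)
// on every parent link, and linear within-phase volume ramps
// V_i(t) = V_base_i + Q_alv_i * ramp(t) for alveolated units.
//
// Schemes: order 1 = explicit Euler, order 2 = Heun (explicit trapezoidal).
// The half-period must be an integer number of steps so the rectangular-flow
// reversals land exactly on step boundaries; every step is then integrated
// entirely inside one smooth phase segment (the second Heun stage evaluates
// the same phase's fluxes at the segment end, where the volume ramp is still
// continuous), which preserves the scheme's order across flow reversals.
//
// parent is 0-based with -1 for the root (first TU compartment), whose
// parent link is the model inlet held at u_insp / u_exp.
//
// Returns the mouth trace (root chi at every step), the total tracer volume
// and the cumulative boundary influx on the same grid (their difference is
// the discrete mass-balance residual), and full chi/V snapshots at the
// requested times (rounded to the nearest step).

namespace {

struct Net {
  int n;
  const int *parent;
  const double *G, *Qin, *Qalv, *Vbase;
};

// flux balance: rhs_i = conv_in - conv_out + diff for state chi;
// returns the boundary (inlet) influx rate
inline double fluxes(const Net &net, const std::vector<double> &chi,
                     bool insp, double u, std::vector<double> &rhs) {
  std::fill(rhs.begin(), rhs.end(), 0.0);
  double brate = net.G[0] * (u - chi[0]);
  rhs[0] += brate;
  if (insp) {
    const double c = net.Qin[0] * u;
    rhs[0] += c;
    brate += c;
  } else {
    const double c = net.Qin[0] * chi[0];
    rhs[0] -= c;
    brate -= c;
  }
  for (int i = 1; i < net.n; ++i) {
    const int p = net.parent[i];
    const double f = net.G[i] * (chi[p] - chi[i]);
    rhs[i] += f;
    rhs[p] -= f;
    if (insp) {
      const double c = net.Qin[i] * chi[p];
      rhs[i] += c;
      rhs[p] -= c;
    } else {
      const double c = net.Qin[i] * chi[i];
      rhs[i] -= c;
      rhs[p] += c;
    }
  }
  return brate;
}

}  // namespace

// [[Rcpp::export(name = "euler_washout", rng = false)]]
List euler_washout(IntegerVector parent, NumericVector G,
                   NumericVector Qin, NumericVector Qalv,
                   NumericVector Vbase, double T,
                   double u_insp, double u_exp,
                   double duration, double dt,
                   NumericVector chi0, NumericVector snap_times,
                   double tol, int order) {
  const int n = parent.size();
  const long nsteps = (long)std::llround(duration / dt);
  const long sph = (long)std::llround(T / 2.0 / dt);
  if (sph < 1 || std::fabs(sph * dt - T / 2.0) > 1e-9 * T)
    stop("half-period is not an integer number of steps");
  if (order != 1 && order != 2) stop("order must be 1 or 2");

  std::vector<double> chi(chi0.begin(), chi0.end());
  std::vector<double> rhs(n), rhs2(n), pred(n), vcur(n), vnext(n);
  Net net{n, INTEGER(parent), REAL(G), REAL(Qin), REAL(Qalv), REAL(Vbase)};

  const int nsnap = snap_times.size();
  std::vector<long> snap_step(nsnap);
  for (int s = 0; s < nsnap; ++s) {
    long k = (long)std::llround(snap_times[s] / dt);
    if (k < 0) k = 0;
    if (k > nsteps) k = nsteps;
    snap_step[s] = k;
  }
  NumericMatrix snap_chi(nsnap, n), snap_V(nsnap, n);

  NumericVector time(nsteps + 1), mouth(nsteps + 1), mass(nsteps + 1),
      boundary(nsteps + 1);
  double cumb = 0.0;

  for (long k = 0; k <= nsteps; ++k) {
    const long half = k / sph;
    const long j = k % sph;
    const bool insp = (half % 2 == 0);
    double ramp;
    if (k == nsteps && j == 0 && half > 0) {
      // final instant on a phase boundary: volumes are continuous, take the
      // left limit of the phase that just ended
      ramp = ((half - 1) % 2 == 0) ? T / 2.0 : 0.0;
    } else {
      ramp = insp ? j * dt : (T / 2.0 - j * dt);
    }
    for (int i = 0; i < n; ++i) vcur[i] = Vbase[i] + Qalv[i] * ramp;

    // record state at t_k
    time[k] = k * dt;
    mouth[k] = chi[0];
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += vcur[i] * chi[i];
    mass[k] = m;
    boundary[k] = cumb;
    for (int s = 0; s < nsnap; ++s)
      if (snap_step[s] == k)
        for (int i = 0; i < n; ++i) {
          snap_chi(s, i) = chi[i];
          snap_V(s, i) = vcur[i];
        }
    if (k == nsteps) break;

    // advance over [t_k, t_k + dt], entirely inside the current phase
    const double u = insp ? u_insp : u_exp;
    const double sgn = insp ? 1.0 : -1.0;
    const double ramp2 = insp ? (j + 1) * dt : (T / 2.0 - (j + 1) * dt);
    for (int i = 0; i < n; ++i) vnext[i] = Vbase[i] + Qalv[i] * ramp2;

    double brate = fluxes(net, chi, insp, u, rhs);
    if (order == 1) {
      for (int i = 0; i < n; ++i)
        chi[i] += dt * (rhs[i] - chi[i] * sgn * Qalv[i]) / vcur[i];
      cumb += dt * brate;
    } else {
      for (int i = 0; i < n; ++i)
        pred[i] = chi[i] + dt * (rhs[i] - chi[i] * sgn * Qalv[i]) / vcur[i];
      const double brate2 = fluxes(net, pred, insp, u, rhs2);
      for (int i = 0; i < n; ++i)
        chi[i] += 0.5 * dt *
                  ((rhs[i] - chi[i] * sgn * Qalv[i]) / vcur[i] +
                   (rhs2[i] - pred[i] * sgn * Qalv[i]) / vnext[i]);
      cumb += 0.5 * dt * (brate + brate2);
    }
    for (int i = 0; i < n; ++i)
      if (chi[i] < -tol || chi[i] > 1.0 + tol)
        stop("unstable step: chi = %f at unit %d, t = %f s "
             "(reduce dt)", chi[i], i + 1, (k + 1) * dt);
  }

  return List::create(_["time"] = time, _["mouth"] = mouth,
                      _["mass"] = mass, _["boundary"] = boundary,
                      _["chi"] = snap_chi, _["V"] = snap_V);
}
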