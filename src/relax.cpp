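#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// MacKintosh-style WLC force for total extension x = delta_r + delta_r0 (m).
// Positive return = tension. Exact on (-Lc^2/(3Lp), Lc^2/(6Lp)); beyond
// (1 - margin) of either root the integrator uses a C1 linear continuation,
// so a filament transiently pushed past its extension limit produces a
// large finite restoring force instead of a domain failure. Equilibria
// whose filament tensions stay below the (very large) threshold force are
// identical under the exact and regularized laws; beyond it the length
// error is bounded at the nanometre scale, negligible against the
// micrometre-scale deformations the network readout uses.
struct WlcLaw {
  double kBT, Lp, Lc, x_hi, x_lo, f_hi, k_hi, f_lo, k_lo;
  WlcLaw(double kBT_, double Lp_, double Lc_, double margin)
      : kBT(kBT_), Lp(Lp_), Lc(Lc_) {
    double xmax = Lc * Lc / (6.0 * Lp);
    double xmin = -Lc * Lc / (3.0 * Lp);
    x_hi = (1.0 - margin) * xmax;
    x_lo = (1.0 - margin) * xmin;
    f_hi = exact(x_hi); k_hi = stiff(x_hi);
    f_lo = exact(x_lo); k_lo = stiff(x_lo);
  }
  double exact(double x) const {
    double Lc2 = Lc * Lc;
    double d1 = Lc2 - 6.0 * Lp * x;
    double d2 = Lc2 + 3.0 * Lp * x;
    return 81.0 * kBT * Lp * Lp * Lc2 * x / (d1 * d1 * d2);
  }
  double stiff(double x) const {  // d f / d x, centered difference
    double h = 1e-7 * Lc * Lc / (6.0 * Lp);
    return (exact(x + h) - exact(x - h)) / (2.0 * h);
  }
  inline double force(double x) const {
    if (x > x_hi) return f_hi + k_hi * (x - x_hi);
    if (x < x_lo) return f_lo + k_lo * (x - x_lo);
    return exact(x);
  }
};

// Flat scratch state for the integrator (positions/forces as x,y,z arrays).
struct NetState {
  int n, m_fil, m_abp;
  std::vector<int> fa, fb, aa, ab;
  std::vector<double> fil_rest, abp_rest, ext;
  WlcLaw wlc;
  double dr0, kc;
  NetState(const NumericMatrix& pos0, const IntegerMatrix& fil,
           const NumericVector& fil_rest_, const IntegerMatrix& abp,
           const NumericVector& abp_rest_, const NumericMatrix& ext_,
           double kBT, double Lp, double Lc, double dr0_, double kc_,
           double margin)
      : n(pos0.nrow()), m_fil(fil.nrow()), m_abp(abp.nrow()),
        wlc(kBT, Lp, Lc, margin), dr0(dr0_), kc(kc_) {
    fa.resize(m_fil); fb.resize(m_fil);
    for (int e = 0; e < m_fil; ++e) { fa[e] = fil(e, 0); fb[e] = fil(e, 1); }
    aa.resize(m_abp); ab.resize(m_abp);
    for (int e = 0; e < m_abp; ++e) { aa[e] = abp(e, 0); ab[e] = abp(e, 1); }
    fil_rest.assign(fil_rest_.begin(), fil_rest_.end());
    abp_rest.assign(abp_rest_.begin(), abp_rest_.end());
    ext.resize(3 * n);
    for (int i = 0; i < n; ++i) {
      ext[3 * i] = ext_(i, 0); ext[3 * i + 1] = ext_(i, 1);
      ext[3 * i + 2] = ext_(i, 2);
    }
  }
  // returns max vertex force
  double forces(const double* p, double* F) const {
    for (int i = 0; i < 3 * n; ++i) F[i] = ext[i];
    for (int e = 0; e < m_fil; ++e) {
      int a = 3 * fa[e], b = 3 * fb[e];
      double dx = p[b] - p[a], dy = p[b + 1] - p[a + 1],
             dz = p[b + 2] - p[a + 2];
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len < 1e-300) continue;
      double f = wlc.force(len - fil_rest[e] + dr0) / len;
      F[a] += f * dx; F[a + 1] += f * dy; F[a + 2] += f * dz;
      F[b] -= f * dx; F[b + 1] -= f * dy; F[b + 2] -= f * dz;
    }
    for (int e = 0; e < m_abp; ++e) {
      int a = 3 * aa[e], b = 3 * ab[e];
      double dx = p[b] - p[a], dy = p[b + 1] - p[a + 1],
             dz = p[b + 2] - p[a + 2];
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len < 1e-300) continue;
      double f = kc * (len - abp_rest[e]) / len;
      F[a] += f * dx; F[a + 1] += f * dy; F[a + 2] += f * dz;
      F[b] -= f * dx; F[b + 1] -= f * dy; F[b + 2] -= f * dz;
    }
    double fmax2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double m2 = F[3 * i] * F[3 * i] + F[3 * i + 1] * F[3 * i + 1] +
                  F[3 * i + 2] * F[3 * i + 2];
      if (m2 > fmax2) fmax2 = m2;
    }
    return std::sqrt(fmax2);
  }
};

// [[Rcpp::export]]
List network_forces_cpp(NumericMatrix pos,
                        IntegerMatrix fil, NumericVector fil_rest,
                        IntegerMatrix abp, NumericVector abp_rest,
                        NumericMatrix ext,
                        double kBT, double Lp, double Lc, double dr0,
                        double kc, double margin) {
  NetState st(pos, fil, fil_rest, abp, abp_rest, ext, kBT, Lp, Lc, dr0, kc,
              margin);
  int n = pos.nrow();
  std::vector<double> p(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i) {
    p[3 * i] = pos(i, 0); p[3 * i + 1] = pos(i, 1); p[3 * i + 2] = pos(i, 2);
  }
  bool in_domain = true;
  for (int e = 0; e < st.m_fil; ++e) {
    int a = 3 * st.fa[e], b = 3 * st.fb[e];
    double dx = p[b] - p[a], dy = p[b + 1] - p[a + 1], dz = p[b + 2] - p[a + 2];
    double x = std::sqrt(dx * dx + dy * dy + dz * dz) - st.fil_rest[e] + dr0;
    if (x >= Lc * Lc / (6.0 * Lp) || x <= -Lc * Lc / (3.0 * Lp))
      in_domain = false;
  }
  double fmax = st.forces(p.data(), F.data());
  NumericMatrix Fout(n, 3);
  for (int i = 0; i < n; ++i) {
    Fout(i, 0) = F[3 * i]; Fout(i, 1) = F[3 * i + 1]; Fout(i, 2) = F[3 * i + 2];
  }
  return List::create(_["forces"] = Fout, _["fmax"] = fmax,
                      _["in_domain"] = in_domain);
}

// Relax the network to mechanical equilibrium.
// method 0: overdamped explicit Euler (eta rdot = F) with adaptive step
//           halving on force blow-up.
// method 1: damped inertial dynamics (m rddot = F with FIRE velocity
//           mixing/zeroing playing the role of the viscous term); same
//           equilibria, far fewer iterations on stiff networks.
// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos0,
               IntegerMatrix fil, NumericVector fil_rest,
               IntegerMatrix abp, NumericVector abp_rest,
               NumericMatrix ext,
               double kBT, double Lp, double Lc, double dr0, double kc,
               double gamma, double dt0, double dt_max,
               int max_iter, double ftol, int method, NumericVector mass,
               double margin) {
  NetState st(pos0, fil, fil_rest, abp, abp_rest, ext, kBT, Lp, Lc, dr0, kc,
              margin);
  int n = pos0.nrow();
  // per-vertex fictitious mass (diagonal preconditioning)
  std::vector<double> mv(mass.begin(), mass.end());
  if ((int)mv.size() == 1) mv.assign(n, mv[0]);
  std::vector<double> pos(3 * n), trial(3 * n), F(3 * n), Ft(3 * n),
      vel(3 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    pos[3 * i] = pos0(i, 0); pos[3 * i + 1] = pos0(i, 1);
    pos[3 * i + 2] = pos0(i, 2);
  }
  double fmax = st.forces(pos.data(), F.data()), fmax_t = 0.0;

  double dt = dt0;
  int it = 0;
  bool converged = fmax < ftol;

  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, f_alpha = 0.99;
  const int n_min = 5;
  double alpha = alpha0;
  int n_pos = 0;

  for (it = 0; it < max_iter && !converged; ++it) {
    if (method == 0) {
      int halvings = 0;
      while (true) {
        double s = dt / gamma;
        for (int i = 0; i < 3 * n; ++i) trial[i] = pos[i] + s * F[i];
        fmax_t = st.forces(trial.data(), Ft.data());
        if (R_finite(fmax_t) && fmax_t <= 3.0 * fmax) break;
        dt *= 0.5;
        if (++halvings > 60)
          stop("Relaxation step size underflow (dt = %g s) at iteration %d.",
               dt, it);
      }
      pos.swap(trial);
      F.swap(Ft);
      fmax = fmax_t;
      dt = std::min(dt * 1.1, dt_max);
    } else {
      double P = 0.0;
      for (int i = 0; i < 3 * n; ++i) P += F[i] * vel[i];
      if (P > 0.0) {
        double vnorm = 0.0, fnorm = 0.0;
        for (int i = 0; i < 3 * n; ++i) {
          vnorm += vel[i] * vel[i];
          fnorm += F[i] * F[i];
        }
        vnorm = std::sqrt(vnorm); fnorm = std::sqrt(fnorm);
        double mix = (fnorm > 0) ? alpha * vnorm / fnorm : 0.0;
        for (int i = 0; i < 3 * n; ++i)
          vel[i] = (1 - alpha) * vel[i] + mix * F[i];
        if (++n_pos > n_min) { dt = std::min(dt * f_inc, dt_max); alpha *= f_alpha; }
      } else {
        std::fill(vel.begin(), vel.end(), 0.0);
        dt *= f_dec;
        alpha = alpha0;
        n_pos = 0;
      }
      int halvings = 0;
      while (true) {
        for (int i = 0; i < 3 * n; ++i)
          trial[i] = pos[i] + dt * (vel[i] + dt / mv[i / 3] * F[i]);
        fmax_t = st.forces(trial.data(), Ft.data());
        if (R_finite(fmax_t)) break;
        dt *= 0.5;
        std::fill(vel.begin(), vel.end(), 0.0);
        n_pos = 0;
        if (++halvings > 60)
          stop("Relaxation step size underflow (dt = %g s) at iteration %d.",
               dt, it);
      }
      for (int i = 0; i < 3 * n; ++i) vel[i] += dt / mv[i / 3] * F[i];
      pos.swap(trial);
      F.swap(Ft);
      fmax = fmax_t;
    }
    converged = fmax < ftol;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = pos[3 * i]; out(i, 1) = pos[3 * i + 1];
    out(i, 2) = pos[3 * i + 2];
  }
  return List::create(_["pos"] = out, _["converged"] = converged,
                      _["iterations"] = it, _["fmax"] = fmax,
                      _["dt_final"] = dt);
}
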