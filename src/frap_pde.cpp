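// Deterministic expected strip-FRAP curve for the three-state model.
//
// The strip readout depends on the x coordinate only, so the expected
// curve is computed on the x marginal of the ellipsoidal nucleus: the
// cross-section area A(x) = 1 - (x/a)^2 weights a 1D reaction-diffusion
// system for the bright line densities of the free, promoter-bound and
// elongating pools,
//
//   du_f/dt = D d/dx [ A d/dx (u_f / A) ] - (konp + kone) u_f
//             + koffp u_p + koffe u_e
//   du_p/dt = konp u_f - koffp u_p
//   du_e/dt = kone u_f - koffe u_e
//
// with zero-flux ends (A vanishes at the poles, so the flux form encodes
// the boundary automatically).  Diffusion advances by Crank-Nicolson on
// the acquisition substep, reactions explicitly (rates x dt << 1).  The
// bleach multiplies every pool by 1 - depth inside the strip, with exact
// cell-overlap weights.  The curve is normalized like the simulator's:
// pre-bleach level = 100.
//
// This expectation is the control-variate companion of the particle
// engine: grid fits use it for the *difference* between candidate models,
// anchored at Monte Carlo reference simulations, so its residual closure
// error (the x marginal of a 3D reflected diffusion is not exactly
// Markov) enters only at second order.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".pde_frap_cpp")]]
NumericVector pde_frap_cpp(double f_free, double f_prom, double f_elong,
                           double t_prom, double t_elong, double D,
                           double a, double strip_width,
                           double frame_interval, int n_prebleach,
                           int n_recovery, double bleach_depth, double dt,
                           int n_sub, int K) {
  // Non-uniform grid whose cell boundaries coincide with the strip edges,
  // so every cell is entirely inside or outside the strip: bleach and
  // readout are then exact, with no partial-cell smearing at the bleach
  // frame.
  const double half_w = strip_width / 2.0;
  const double dx_target = 2.0 * a / K;
  const int m_out = std::max(2, (int)std::ceil((a - half_w) / dx_target));
  const int m_in = std::max(2, (int)std::ceil(strip_width / dx_target));
  const int Kn = 2 * m_out + m_in;
  std::vector<double> xb(Kn + 1);
  const double dxo = (a - half_w) / m_out, dxi = strip_width / m_in;
  xb[0] = -a;
  for (int i = 1; i <= m_out; ++i) xb[i] = -a + i * dxo;
  for (int i = 1; i <= m_in; ++i) xb[m_out + i] = -half_w + i * dxi;
  for (int i = 1; i <= m_out; ++i) xb[m_out + m_in + i] = half_w + i * dxo;
  xb[Kn] = a;

  std::vector<double> xc(Kn), dxc(Kn), A(Kn), Ah(Kn + 1), wgt(Kn);
  for (int i = 0; i < Kn; ++i) {
    xc[i] = 0.5 * (xb[i] + xb[i + 1]);
    dxc[i] = xb[i + 1] - xb[i];
    A[i] = 1.0 - (xc[i] / a) * (xc[i] / a);
    wgt[i] = (xc[i] > -half_w && xc[i] < half_w) ? 1.0 : 0.0;
  }
  for (int i = 0; i <= Kn; ++i)
    Ah[i] = std::max(0.0, 1.0 - (xb[i] / a) * (xb[i] / a));

  // Tridiagonal operator L for the flux form on the non-uniform grid.
  const int Kc = Kn;
  std::vector<double> lo_(Kc), di_(Kc), up_(Kc);
  for (int i = 0; i < Kc; ++i) {
    const double hm = i > 0 ? 0.5 * (dxc[i - 1] + dxc[i]) : 1.0;
    const double hp = i < Kc - 1 ? 0.5 * (dxc[i] + dxc[i + 1]) : 1.0;
    const double am = i > 0 ? D * Ah[i] / (hm * dxc[i] * A[i - 1]) : 0.0;
    const double ap = i < Kc - 1 ? D * Ah[i + 1] / (hp * dxc[i] * A[i + 1])
                                 : 0.0;
    const double ad = (i > 0 ? D * Ah[i] / (hm * dxc[i]) : 0.0) +
                      (i < Kc - 1 ? D * Ah[i + 1] / (hp * dxc[i]) : 0.0);
    lo_[i] = am;             // coefficient of u_{i-1}
    up_[i] = ap;             // coefficient of u_{i+1}
    di_[i] = -ad / A[i];     // coefficient of u_i
  }

  // Crank-Nicolson matrices: (I - dt/2 L) u+ = (I + dt/2 L) u.
  std::vector<double> Al(Kc), Ad(Kc), Au(Kc);
  for (int i = 0; i < Kc; ++i) {
    Al[i] = -0.5 * dt * lo_[i];
    Ad[i] = 1.0 - 0.5 * dt * di_[i];
    Au[i] = -0.5 * dt * up_[i];
  }

  double konp = 0.0, kone = 0.0;
  if (f_free > 0.0) {
    if (f_prom > 0.0) konp = f_prom / (f_free * t_prom);
    if (f_elong > 0.0) kone = f_elong / (f_free * t_elong);
  }
  const double koffp = 1.0 / t_prom, koffe = 1.0 / t_elong;

  std::vector<double> uf(Kc), up(Kc), ue(Kc), rhs(Kc), cp(Kc), dp(Kc);
  for (int i = 0; i < Kc; ++i) {
    uf[i] = f_free * A[i];
    up[i] = f_prom * A[i];
    ue[i] = f_elong * A[i];
  }

  auto thomas = [&](std::vector<double>& u) {
    // Solve (Al, Ad, Au) x = rhs in place into u.
    cp[0] = Au[0] / Ad[0];
    dp[0] = rhs[0] / Ad[0];
    for (int i = 1; i < Kc; ++i) {
      const double m = Ad[i] - Al[i] * cp[i - 1];
      cp[i] = Au[i] / m;
      dp[i] = (rhs[i] - Al[i] * dp[i - 1]) / m;
    }
    u[Kc - 1] = dp[Kc - 1];
    for (int i = Kc - 2; i >= 0; --i) u[i] = dp[i] - cp[i] * u[i + 1];
  };

  auto substep = [&]() {
    // Diffusion of the free pool (Crank-Nicolson).
    for (int i = 0; i < Kc; ++i) {
      double v = uf[i] * (1.0 + 0.5 * dt * di_[i]);
      if (i > 0) v += 0.5 * dt * lo_[i] * uf[i - 1];
      if (i < Kc - 1) v += 0.5 * dt * up_[i] * uf[i + 1];
      rhs[i] = v;
    }
    thomas(uf);
    // Exchange (explicit; rate * dt is tiny at all sane parameters).
    for (int i = 0; i < Kc; ++i) {
      const double f = uf[i], p = up[i], e = ue[i];
      uf[i] += dt * (-(konp + kone) * f + koffp * p + koffe * e);
      up[i] += dt * (konp * f - koffp * p);
      ue[i] += dt * (kone * f - koffe * e);
    }
  };

  double strip0 = 0.0;
  for (int i = 0; i < Kc; ++i) strip0 += wgt[i] * A[i] * dxc[i];

  const int n_frames = n_prebleach + 1 + n_recovery;
  NumericVector rfi(n_frames);
  auto readout = [&](int frame) {
    double s = 0.0;
    for (int i = 0; i < Kc; ++i) s += wgt[i] * (uf[i] + up[i] + ue[i]) * dxc[i];
    rfi[frame] = 100.0 * s / strip0;
  };

  int frame = 0;
  readout(frame++);
  for (int f = 1; f < n_prebleach; ++f) {
    for (int s = 0; s < n_sub; ++s) substep();
    readout(frame++);
  }
  for (int s = 0; s < n_sub; ++s) substep();
  for (int i = 0; i < Kc; ++i) {
    const double keep = 1.0 - bleach_depth * wgt[i];
    uf[i] *= keep; up[i] *= keep; ue[i] *= keep;
  }
  readout(frame++);
  for (int f = 0; f < n_recovery; ++f) {
    for (int s = 0; s < n_sub; ++s) substep();
    readout(frame++);
  }
  return rfi;
}
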