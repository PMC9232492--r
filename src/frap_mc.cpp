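// Particle-based Monte Carlo engine for nuclear strip-FRAP.
//
// Particles live inside a 3D ellipsoidal nucleus.  A particle is either
// freely diffusing (state 0), promoter-bound (state 1) or elongating
// (state 2).  Bound particles are immobile; free particles take isotropic
// Gaussian steps reflected at the nuclear envelope by rejection resampling.
// State transitions are evaluated on the substep lattice with per-substep
// probability 1 - exp(-rate * dt); binding is pseudo-first-order with rates
// chosen so the configured fractions are the exact steady state.  The
// waiting time to the next transition is drawn as a geometric number of
// substeps, which is distributionally identical to testing every substep
// but avoids one uniform draw per particle per substep.
//
// Random-number layout (common random numbers).  A grid search compares
// kinetic models by simulating each on the same seed, so the engine is
// built to keep simulations that differ only in kinetic parameters as
// tightly coupled as possible:
//
//   * diffusion displacements are a pure counter-based function of
//     (seed, particle, substep index) — a particle that is free at substep
//     s takes the identical step in every simulation sharing the seed, no
//     matter how its binding history differs;
//   * each particle's sequential stream is reserved for kinetic decisions
//     (waiting times, binding-branch choices), whose draw sequence is
//     invariant across parameter values, and inverse-CDF sampling maps the
//     same uniforms to monotonically shifted waits;
//   * initial positions and the bleach lottery are pure per-particle
//     functions that consume no stream state.
//
// Initialization and bleach are additionally stratified: state counts are
// deterministic (blockwise, so a particle's state is stable under small
// fraction changes), x positions within each state block follow the
// stratified inverse marginal CDF, and the bleach darkens an unbiased
// integer count of the in-strip fluorophores.  Per-particle marginals all
// equal their nominal distributions; stratification only suppresses the
// slow, whole-curve components of the counting noise, which would
// otherwise sit as a quasi-static RFI offset over the entire recovery —
// indistinguishable from a residence-time change at feasible particle
// numbers.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <vector>

using namespace Rcpp;

namespace {

constexpr std::int64_t NEVER = std::numeric_limits<std::int64_t>::max() / 2;
constexpr std::uint64_t TAG_INIT = 0x9FB21C651E98DF25ULL;
constexpr std::uint64_t TAG_STEP = 0xD1B54A32D192ED03ULL;
constexpr std::uint64_t TAG_BLEACH = 0x8BB84B93962EACC9ULL;
constexpr std::uint64_t TAG_DWELL = 0xA0761D6478BD642FULL;

inline std::uint64_t splitmix64(std::uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline std::uint64_t mix_key(std::uint64_t a, std::uint64_t b) {
  std::uint64_t x = a ^ (b * 0x2545F4914F6CDD1DULL + 0x6A09E667F3BCC909ULL);
  return splitmix64(x);
}

inline double to_unit(std::uint64_t v) {
  // Uniform in (0, 1): never exactly 0, so log(u) is safe.
  return (v >> 11) * 0x1.0p-53 + 0x1.0p-54;
}

// Counter-based stream: cheap to construct at an arbitrary (key, tag)
// point, sequential draws via splitmix64.
struct CtrRng {
  std::uint64_t x;
  CtrRng(std::uint64_t key, std::uint64_t tag) : x(key ^ tag) {}
  double u() { return to_unit(splitmix64(x)); }
  // Two standard normals per Marsaglia polar round.
  void polar(double& n1, double& n2) {
    double a, b, r2;
    do {
      a = 2.0 * u() - 1.0;
      b = 2.0 * u() - 1.0;
      r2 = a * a + b * b;
    } while (r2 >= 1.0 || r2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(r2) / r2);
    n1 = a * f;
    n2 = b * f;
  }
};

// Precomputed table of standard-normal triples for the diffusion steps:
// built once from a fixed internal seed, each column centred and scaled to
// exact zero mean and unit variance.  A diffusion step indexes the table
// with a counter hash and applies hash-derived sign flips, which keeps the
// step an exact function of (seed, particle, substep, attempt) at a
// fraction of the cost of generating three fresh normals.
struct NormTable {
  static constexpr int SIZE = 1 << 16;
  std::vector<double> v;  // SIZE x 3, row-major
  NormTable() : v(3 * SIZE) {
    std::uint64_t x = 0x0DDC0FFEEBADF00DULL;
    CtrRng gen(splitmix64(x), 0);
    for (int j = 0; j < 3; ++j) {
      double mean = 0.0;
      for (int i = 0; i < SIZE; ++i) {
        double a, b;
        gen.polar(a, b);
        v[3 * i + j] = a;
        mean += a;
      }
      mean /= SIZE;
      double ss = 0.0;
      for (int i = 0; i < SIZE; ++i) {
        v[3 * i + j] -= mean;
        ss += v[3 * i + j] * v[3 * i + j];
      }
      const double sc = 1.0 / std::sqrt(ss / SIZE);
      for (int i = 0; i < SIZE; ++i) v[3 * i + j] *= sc;
    }
  }
};

const NormTable& norm_table() {
  static const NormTable t;
  return t;
}

// xoshiro256++: the per-particle sequential stream for kinetic decisions.
struct Rng {
  std::uint64_t s[4];
  void seed(std::uint64_t key) {
    std::uint64_t x = key;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static std::uint64_t rotl(std::uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double u() { return to_unit(next()); }
  // Number of Bernoulli(p) substeps up to and including the first success.
  std::int64_t geometric(double p) { return geometric_from_u(u(), p); }
  static std::int64_t geometric_from_u(double uv, double p) {
    if (p <= 0.0) return NEVER;
    if (p >= 1.0) return 1;
    const double g = std::floor(std::log(uv) / std::log1p(-p));
    return g >= static_cast<double>(NEVER) ? NEVER
                                           : static_cast<std::int64_t>(g) + 1;
  }
};

struct Geom {
  double a, b, c;    // ellipsoid semi-axes (um)
  double half_w;     // strip half-width along x (um)
  double ia2, ib2, ic2;
  Geom(double a_, double b_, double c_, double w)
      : a(a_), b(b_), c(c_), half_w(w / 2.0),
        ia2(1.0 / (a_ * a_)), ib2(1.0 / (b_ * b_)), ic2(1.0 / (c_ * c_)) {}
  bool inside(double x, double y, double z) const {
    return x * x * ia2 + y * y * ib2 + z * z * ic2 <= 1.0;
  }
  bool in_strip(double x) const { return std::fabs(x) <= half_w; }
};

struct Kinetics {
  double bind_scale_p;  // substeps per unit exponential deviate, promoter
  double bind_scale_e;  // substeps per unit exponential deviate, elongating
  double p_off_p;    // P(promoter-bound -> free) per substep
  double p_off_e;    // P(elongating -> free) per substep (exponential dwell)
  bool fixed_elong;  // deterministic elongating dwell of t_elong
  std::int64_t elong_steps;  // dwell in substeps when fixed
};

Kinetics make_kinetics(double f_free, double f_prom, double f_elong,
                       double t_prom, double t_elong, double dt,
                       bool fixed_elong) {
  // Pseudo-first-order binding: k_on,p = f_prom / (f_free * t_prom), etc.
  // With unbinding rates 1/t these make (f_free, f_prom, f_elong) the
  // exact stationary distribution.  f_free == 0 means no exchange.  The
  // two binding channels compete as independent per-substep Bernoulli
  // processes, so a parameter change in one channel leaves the other
  // channel's draws untouched (common-random-number coupling).
  double kon_p = 0.0, kon_e = 0.0;
  if (f_free > 0.0) {
    if (f_prom > 0.0) kon_p = f_prom / (f_free * t_prom);
    if (f_elong > 0.0) kon_e = f_elong / (f_free * t_elong);
  }
  Kinetics k;
  // Binding waits are drawn as continuous competing exponentials (in
  // substep units) and discretized with ceil(): the marginal substep
  // probability is exactly 1 - exp(-kon * dt), and the branch choice is
  // the exact rate ratio (no simultaneous-fire tie bias).
  k.bind_scale_p = kon_p > 0.0 ? 1.0 / (kon_p * dt) : 0.0;
  k.bind_scale_e = kon_e > 0.0 ? 1.0 / (kon_e * dt) : 0.0;
  k.p_off_p = -std::expm1(-dt / t_prom);
  k.p_off_e = -std::expm1(-dt / t_elong);
  k.fixed_elong = fixed_elong;
  k.elong_steps = static_cast<std::int64_t>(std::ceil(t_elong / dt));
  if (k.elong_steps < 1) k.elong_steps = 1;
  return k;
}

struct Ensemble {
  std::vector<double> X, Y, Z;
  std::vector<int> state;
  std::vector<std::int64_t> next_event;  // substeps until the next transition
  std::vector<char> bind_to;             // pending target state when free
  std::vector<char> fluor;
  std::vector<std::uint64_t> key;        // per-particle RNG key
  std::vector<Rng> kin;                  // kinetic-decision stream
};

// Draw the waiting time for particle i entering `state`; for a free
// particle both binding channels are drawn (fixed draw count, so the
// kinetic stream stays aligned across parameter values) and the earlier
// one wins, ties going to the promoter channel.
void enter_state(Ensemble& e, std::size_t i, const Kinetics& k, int state) {
  e.state[i] = state;
  Rng& r = e.kin[i];
  switch (state) {
    case 0: {
      const double inf = std::numeric_limits<double>::infinity();
      const double wp = k.bind_scale_p > 0.0
                            ? -std::log(r.u()) * k.bind_scale_p : inf;
      const double we = k.bind_scale_e > 0.0
                            ? -std::log(r.u()) * k.bind_scale_e : inf;
      const double w = wp <= we ? wp : we;
      e.bind_to[i] = wp <= we ? 1 : 2;
      e.next_event[i] = w >= static_cast<double>(NEVER)
                            ? NEVER
                            : static_cast<std::int64_t>(std::ceil(w));
      if (e.next_event[i] < 1) e.next_event[i] = 1;
      break;
    }
    case 1:
      e.next_event[i] = r.geometric(k.p_off_p);
      break;
    default:
      e.next_event[i] = k.fixed_elong ? k.elong_steps
                                      : r.geometric(k.p_off_e);
      break;
  }
}

// Invert the marginal CDF of the x coordinate of a uniform point in the
// ellipsoid: F(t) = 1/2 + (3 t - t^3) / 4 on t = x/a in [-1, 1].
double inverse_x_cdf(double p) {
  double lo = -1.0, hi = 1.0, t = 2.0 * p - 1.0;
  for (int it = 0; it < 60; ++it) {
    const double f = 0.5 + (3.0 * t - t * t * t) / 4.0 - p;
    if (f > 0) hi = t; else lo = t;
    const double fp = 0.75 * (1.0 - t * t);
    double step = fp > 1e-12 ? t - f / fp : 0.5 * (lo + hi);
    if (step <= lo || step >= hi) step = 0.5 * (lo + hi);
    if (std::fabs(step - t) < 1e-12) { t = step; break; }
    t = step;
  }
  return t;
}

void init_ensemble(double seed, const Geom& g, const Kinetics& k, int n,
                   double f_free, double f_prom, Ensemble& e) {
  e.X.resize(n); e.Y.resize(n); e.Z.resize(n);
  e.state.resize(n);
  e.next_event.resize(n);
  e.bind_to.assign(n, 1);
  e.fluor.assign(n, 1);
  e.key.resize(n);
  e.kin.resize(n);

  // Deterministic state counts, assigned blockwise: free block first, then
  // promoter-bound, then elongating.  Under a small change of one fraction
  // only the particles at a block boundary change state, which keeps
  // common-random-number coupling tight across grid points.
  int n_free = static_cast<int>(std::floor(f_free * n + 0.5));
  int n_prom = static_cast<int>(std::floor(f_prom * n + 0.5));
  if (n_free > n) n_free = n;
  if (n_free + n_prom > n) n_prom = n - n_free;
  const int start_prom = n_free, start_elong = n_free + n_prom;

  const std::uint64_t sim_key =
      static_cast<std::uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL;

  // Latin-hypercube stratification of the initial residual dwells of the
  // bound blocks: each particle's dwell draw is confined to one stratum of
  // the dwell distribution, with a seeded permutation so that dwell strata
  // are independent of the position strata.  This pins the number of
  // initially-bound particles that release within any horizon to its
  // expectation (+/- O(1)); the Poisson noise of those release counts is
  // otherwise the dominant slow error of the simulated curve, degenerate
  // in shape with a residence-time change.
  const int n_elong = n - start_elong;
  std::vector<int> perm_p(n_prom), perm_e(n_elong);
  auto make_perm = [&](std::vector<int>& perm, std::uint64_t tag) {
    const int m = static_cast<int>(perm.size());
    for (int j = 0; j < m; ++j) perm[j] = j;
    Rng pr;
    pr.seed(mix_key(sim_key, tag));
    for (int j = m - 1; j > 0; --j) {
      const int l = static_cast<int>(pr.u() * (j + 1));
      std::swap(perm[j], perm[l <= j ? l : j]);
    }
  };
  make_perm(perm_p, TAG_DWELL + 1);
  make_perm(perm_e, TAG_DWELL + 2);

  for (int i = 0; i < n; ++i) {
    e.key[i] = mix_key(sim_key, static_cast<std::uint64_t>(i));
    e.kin[i].seed(e.key[i]);
    // Stratified x within the particle's state block: particle `rank` of a
    // block of m occupies stratum [rank/m, (rank+1)/m) of the x marginal.
    int block_start, block_size;
    if (i < start_prom) { block_start = 0; block_size = n_free; }
    else if (i < start_elong) { block_start = start_prom; block_size = n_prom; }
    else { block_start = start_elong; block_size = n - start_elong; }
    CtrRng pr(e.key[i], TAG_INIT);
    const double p = (i - block_start + pr.u()) / block_size;
    const double t = inverse_x_cdf(p);
    const double s = std::sqrt(std::max(0.0, 1.0 - t * t));
    // y, z uniform in the elliptical cross-section at x.
    double v, w;
    do {
      v = 2.0 * pr.u() - 1.0;
      w = 2.0 * pr.u() - 1.0;
    } while (v * v + w * w > 1.0);
    e.X[i] = t * g.a; e.Y[i] = g.b * s * v; e.Z[i] = g.c * s * w;
    const int st = i < start_prom ? 0 : (i < start_elong ? 1 : 2);
    if (st == 0) {
      // Free particles: plain stationary draw (their relaxation is fast).
      enter_state(e, i, k, 0);
      continue;
    }
    // Bound particles: stratified residual dwell.  Exponential dwells are
    // memoryless, so a fresh draw is the stationary residual; for a fixed
    // dwell the stationary residual is uniform on (0, T).  One kinetic-
    // stream draw is consumed either way, keeping the stream aligned.
    const int r = st == 1 ? i - start_prom : i - start_elong;
    const std::vector<int>& perm = st == 1 ? perm_p : perm_e;
    const int m = st == 1 ? n_prom : n_elong;
    const double su = (perm[r] + e.kin[i].u()) / m;
    e.state[i] = st;
    if (st == 2 && k.fixed_elong) {
      e.next_event[i] =
          static_cast<std::int64_t>(std::ceil(su * k.elong_steps));
      if (e.next_event[i] < 1) e.next_event[i] = 1;
    } else {
      e.next_event[i] = Rng::geometric_from_u(
          su, st == 1 ? k.p_off_p : k.p_off_e);
    }
  }
}

// One kinetic + diffusion substep over all particles.  `substep_index` is
// the global substep counter that keys the counter-based diffusion draws.
void substep(const Geom& g, const Kinetics& k, double sd, Ensemble& e,
             std::uint64_t substep_index) {
  const std::size_t n = e.X.size();
  const std::uint64_t step_tag = TAG_STEP + substep_index * 0xB5026F5AA96619E9ULL;
  const NormTable& nt = norm_table();
  const double ssd = sd * 0.7071067811865476;  // table triples are summed in pairs
  for (std::size_t i = 0; i < n; ++i) {
    if (e.state[i] == 0) {
      // Reflecting boundary by rejection: redraw the whole step until the
      // endpoint lies inside the nucleus.
      std::uint64_t h = e.key[i] ^ step_tag;
      for (int attempt = 0; attempt < 100; ++attempt) {
        const std::uint64_t r = splitmix64(h);
        // Sum of two independently indexed, independently sign-flipped
        // triples: particles colliding on one index still take distinct
        // steps, so ensemble fluctuations stay at their nominal level.
        const double* a = &nt.v[3 * (r & (NormTable::SIZE - 1))];
        const double* b = &nt.v[3 * ((r >> 20) & (NormTable::SIZE - 1))];
        const double d1 = ((r & (1ULL << 40)) ? a[0] : -a[0]) +
                          ((r & (1ULL << 43)) ? b[0] : -b[0]);
        const double d2 = ((r & (1ULL << 41)) ? a[1] : -a[1]) +
                          ((r & (1ULL << 44)) ? b[1] : -b[1]);
        const double d3 = ((r & (1ULL << 42)) ? a[2] : -a[2]) +
                          ((r & (1ULL << 45)) ? b[2] : -b[2]);
        const double nx = e.X[i] + ssd * d1;
        const double ny = e.Y[i] + ssd * d2;
        const double nz = e.Z[i] + ssd * d3;
        if (g.inside(nx, ny, nz)) {
          e.X[i] = nx; e.Y[i] = ny; e.Z[i] = nz;
          break;
        }
      }
      if (--e.next_event[i] <= 0)
        enter_state(e, i, k, e.bind_to[i]);
    } else if (--e.next_event[i] <= 0) {
      // A bound particle rebinds where it unbound: position is unchanged.
      enter_state(e, i, k, 0);
    }
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_init_cpp")]]
List mc_init_cpp(int n_particles, double f_free, double f_prom,
                 double f_elong, double a, double b, double c,
                 double strip_width, double seed) {
  Geom g(a, b, c, strip_width);
  Kinetics k = make_kinetics(f_free, f_prom, f_elong, 1.0, 1.0, 1.0, false);
  Ensemble e;
  init_ensemble(seed, g, k, n_particles, f_free, f_prom, e);
  NumericMatrix pos(n_particles, 3);
  IntegerVector st(n_particles);
  for (int i = 0; i < n_particles; ++i) {
    pos(i, 0) = e.X[i]; pos(i, 1) = e.Y[i]; pos(i, 2) = e.Z[i];
    st[i] = e.state[i];
  }
  (void)f_elong;
  return List::create(_["positions"] = pos, _["state"] = st);
}

//' @noRd
// [[Rcpp::export(name = ".mc_step_cpp")]]
List mc_step_cpp(NumericMatrix positions, IntegerVector state_in,
                 double f_free, double f_prom, double f_elong, double t_prom,
                 double t_elong, double D, double a, double b, double c,
                 double strip_width, double dt, int n_steps, double seed) {
  const int n = positions.nrow();
  Geom g(a, b, c, strip_width);
  Kinetics k = make_kinetics(f_free, f_prom, f_elong, t_prom, t_elong, dt,
                             false);
  const double sd = std::sqrt(2.0 * D * dt);
  Ensemble e;
  e.X.resize(n); e.Y.resize(n); e.Z.resize(n);
  e.state.resize(n);
  e.next_event.resize(n);
  e.bind_to.assign(n, 1);
  e.fluor.assign(n, 1);
  e.key.resize(n);
  e.kin.resize(n);
  const std::uint64_t sim_key =
      static_cast<std::uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL;
  for (int i = 0; i < n; ++i) {
    e.X[i] = positions(i, 0); e.Y[i] = positions(i, 1);
    e.Z[i] = positions(i, 2);
    e.key[i] = mix_key(sim_key, static_cast<std::uint64_t>(i));
    e.kin[i].seed(e.key[i]);
    enter_state(e, i, k, state_in[i]);
  }
  for (int s = 0; s < n_steps; ++s)
    substep(g, k, sd, e, static_cast<std::uint64_t>(s));
  NumericMatrix pos(n, 3);
  IntegerVector st(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = e.X[i]; pos(i, 1) = e.Y[i]; pos(i, 2) = e.Z[i];
    st[i] = e.state[i];
  }
  return List::create(_["positions"] = pos, _["state"] = st);
}

//' @noRd
// [[Rcpp::export(name = ".mc_frap_cpp")]]
List mc_frap_cpp(int n_particles, double f_free, double f_prom,
                 double f_elong, double t_prom, double t_elong, double D,
                 double a, double b, double c, double strip_width,
                 double frame_interval, int n_prebleach, int n_recovery,
                 double bleach_depth, double dt, int n_sub, bool fixed_elong,
                 double seed) {
  Geom g(a, b, c, strip_width);
  Kinetics k = make_kinetics(f_free, f_prom, f_elong, t_prom, t_elong, dt,
                             fixed_elong);
  const double sd = std::sqrt(2.0 * D * dt);

  Ensemble e;
  init_ensemble(seed, g, k, n_particles, f_free, f_prom, e);

  const int n_frames = n_prebleach + 1 + n_recovery;
  NumericVector counts(n_frames);
  NumericVector total_fluor(n_frames);

  // Per-particle fluorescence weight: the expectation of the particle's
  // brightness over the Bernoulli bleach lottery, given its trajectory.
  // Summing weights instead of drawing the lottery (Rao-Blackwellization)
  // removes every trace of bleach-assignment noise from the curve — in
  // particular the slow error from which mobile particles happen to go
  // dark and where they subsequently carry their darkness.  The expected
  // readout is identical to the lottery's; only its variance is smaller.
  std::vector<double> w(n_particles, 1.0);

  auto readout = [&](int frame) {
    double cnt = 0.0, tot = 0.0;
    for (int i = 0; i < n_particles; ++i) {
      tot += w[i];
      if (g.in_strip(e.X[i])) cnt += w[i];
    }
    counts[frame] = cnt;
    total_fluor[frame] = tot;
  };

  std::uint64_t substep_index = 0;
  auto advance_frame = [&]() {
    for (int s = 0; s < n_sub; ++s) substep(g, k, sd, e, substep_index++);
  };

  int frame = 0;
  readout(frame++);
  for (int f = 1; f < n_prebleach; ++f) {
    advance_frame();
    readout(frame++);
  }

  // Bleach frame: advance one interval, then attenuate the weight of every
  // particle inside the strip by the bleach depth.
  advance_frame();
  double n_bleached = 0.0;
  for (int i = 0; i < n_particles; ++i) {
    if (g.in_strip(e.X[i])) {
      n_bleached += w[i] * bleach_depth;
      w[i] *= 1.0 - bleach_depth;
    }
  }
  readout(frame++);

  for (int f = 0; f < n_recovery; ++f) {
    advance_frame();
    readout(frame++);
  }

  return List::create(_["counts"] = counts,
                      _["total_fluorescent"] = total_fluor,
                      _["n_bleached"] = n_bleached);
}
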