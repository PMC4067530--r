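// Compiled inner loop of the 2-D Brownian-dynamics engine.
//
// The engine advances one ParB/parS partition complex and n_ParA ParA-ATP
// dimers inside a reflective rectangular cell [0, l0] x [-w0/2, w0/2].
// Three model variants share the loop:
//   1 "diffusion"          complex diffuses; no dimers simulated
//   2 "diffusion_binding"  immobile DNA-bound dimers; binding is bookkeeping
//   3 "dna_relay"          dimers fluctuate in harmonic wells and, while
//                          attached, pull the complex toward their tether
//                          equilibrium points
//
// Each particle coordinate is updated per axis with the second-order scheme
//   x(t+dt) = x(t) + R0 + (D/kT) F dt + (D^2/2(kT)^2) F F' dt^2 + (D/kT) F' R1
// where (R0, R1) is a correlated Gaussian pair with
//   Var(R0) = 2 D dt, Var(R1) = (2/3) D dt^3, Cov(R0, R1) = D dt^2.
// Forces only enter through F/kT, so springs are parameterised as
// k_sp/kT = 1/sigma^2 per axis.
//
// Determinism: a self-contained xoshiro256++ generator seeded via splitmix64
// makes a run a pure function of (config, seed).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm();
  inline double rexp(double mean) { return -mean * std::log(unif()); }
};

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers).
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    const double vn = 9.91256303526217e-3;
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const ZigTables zig;

inline double Xoshiro::norm() {
  for (;;) {
    const int32_t hz = static_cast<int32_t>(static_cast<uint32_t>(next() >> 32));
    const uint32_t iz = static_cast<uint32_t>(hz) & 127u;
    const uint32_t a =
        hz < 0 ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
               : static_cast<uint32_t>(hz);
    if (a < zig.kn[iz]) return hz * zig.wn[iz];
    // edge/tail handling
    double x = hz * zig.wn[iz];
    if (iz == 0) {  // Gaussian tail beyond r
      const double r = 3.442619855899;
      double y;
      do {
        x = -std::log(unif()) / r;
        y = -std::log(unif());
      } while (y + y < x * x);
      return hz > 0 ? r + x : -(r + x);
    }
    if (zig.fn[iz] + unif() * (zig.fn[iz - 1] - zig.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

inline double reflect1(double x, double lo, double hi) {
  if (x >= lo && x <= hi) return x;
  const double w = hi - lo;
  const double p = 2.0 * w;
  const double u = x - lo;
  double z = u - std::floor(u / p) * p;  // u mod p, in [0, p)
  return lo + (z <= w ? z : p - z);
}

struct Pair {
  double r0, r1;
};

// Correlated pair via the conditional decomposition
// R1 | R0 ~ N((dt/2) R0, D dt^3 / 6).
inline Pair corr_pair(Xoshiro& rng, double D, double dt) {
  const double z1 = rng.norm(), z2 = rng.norm();
  Pair p;
  p.r0 = std::sqrt(2.0 * D * dt) * z1;
  p.r1 = 0.5 * dt * p.r0 + std::sqrt(D * dt * dt * dt / 6.0) * z2;
  return p;
}

const double INF = std::numeric_limits<double>::infinity();

enum DimerState { FREE = 0, DNA_BOUND = 1, PC_BOUND = 2 };

}  // namespace

// Stationary samples of a single harmonically tethered particle (deviations
// from its equilibrium point), recorded every `record_every` steps. Used by
// the locus-fluctuation generator and the Boltzmann-limit checks.
// [[Rcpp::export(name = ".tether_traj_cpp")]]
NumericMatrix tether_traj_cpp(int n_records, int record_every, double dt,
                              double D, double sigma_x, double sigma_y,
                              double x0, double y0, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double bx = D * dt / (sigma_x * sigma_x);
  const double by = D * dt / (sigma_y * sigma_y);
  const double c1x = 1.0 - bx + 0.5 * bx * bx;
  const double c1y = 1.0 - by + 0.5 * by * by;
  const double c2x = -D / (sigma_x * sigma_x);
  const double c2y = -D / (sigma_y * sigma_y);
  NumericMatrix out(n_records, 2);
  double x = x0, y = y0;
  for (int r = 0; r < n_records; ++r) {
    for (int i = 0; i < record_every; ++i) {
      const Pair px = corr_pair(rng, D, dt);
      const Pair py = corr_pair(rng, D, dt);
      x = c1x * x + px.r0 + c2x * px.r1;
      y = c1y * y + py.r0 + c2y * py.r1;
    }
    out(r, 0) = x;
    out(r, 1) = y;
  }
  return out;
}

// [[Rcpp::export(name = ".bd_run_cpp")]]
List bd_run_cpp(List cfg, double seed) {
  const double dt = as<double>(cfg["dt"]);
  const double t_fin = as<double>(cfg["t_fin"]);
  const double l0 = as<double>(cfg["l0"]);
  const double w0 = as<double>(cfg["w0"]);
  const double x0 = as<double>(cfg["x0"]);
  const double y0 = as<double>(cfg["y0"]);
  const double x_finish = as<double>(cfg["x_finish"]);
  const double R_PC = as<double>(cfg["R_PC"]);
  const double R_ParA = as<double>(cfg["R_ParA"]);
  const int n_ParA = as<int>(cfg["n_ParA"]);
  const double k_cat = as<double>(cfg["k_cat"]);
  const double tau_db = as<double>(cfg["tau_db"]);
  const double D_PC = as<double>(cfg["D_PC"]);
  const double D_A = as<double>(cfg["D_A"]);
  const double sx = as<double>(cfg["sigma_long"]);
  const double sy = as<double>(cfg["sigma_short"]);
  const int model = as<int>(cfg["model_code"]);  // 1, 2, 3
  const int record_every = as<int>(cfg["record_every"]);

  Xoshiro rng(static_cast<uint64_t>(seed));

  const double ylo = -0.5 * w0, yhi = 0.5 * w0;
  const double capt2 = (R_PC + R_ParA) * (R_PC + R_ParA);
  const double inv_sx2 = 1.0 / (sx * sx), inv_sy2 = 1.0 / (sy * sy);
  const double bx = D_A * dt * inv_sx2, by = D_A * dt * inv_sy2;
  const double c1x = 1.0 - bx + 0.5 * bx * bx;
  const double c1y = 1.0 - by + 0.5 * by * by;
  const double c2x = -D_A * inv_sx2, c2y = -D_A * inv_sy2;
  const bool has_dimers = model >= 2;
  const bool dimers_move = model == 3;

  // dimer state
  std::vector<double> px(n_ParA), py(n_ParA), ex(n_ParA), ey(n_ParA),
      nev(n_ParA, INF);
  std::vector<int> st(n_ParA, DNA_BOUND);
  if (has_dimers) {
    for (int j = 0; j < n_ParA; ++j) {
      // linearly increasing density between x0 and the new pole (inverse CDF)
      px[j] = x0 + (l0 - x0) * std::sqrt(rng.unif());
      py[j] = ylo + w0 * rng.unif();
      ex[j] = px[j];
      ey[j] = py[j];
    }
  }

  double xpc = x0, ypc = y0;
  const long n_steps = static_cast<long>(std::ceil(t_fin / dt - 1e-9));
  const long n_rec_max = n_steps / record_every + 2;

  std::vector<double> rt, rx, ry;
  std::vector<int> rnb, rnd, rnf;
  rt.reserve(n_rec_max);
  rx.reserve(n_rec_max);
  ry.reserve(n_rec_max);
  rnb.reserve(n_rec_max);
  rnd.reserve(n_rec_max);
  rnf.reserve(n_rec_max);

  int n_pc = 0, n_dna = has_dimers ? n_ParA : 0, n_free = 0;
  auto record = [&](double t) {
    rt.push_back(t);
    rx.push_back(xpc);
    ry.push_back(ypc);
    rnb.push_back(n_pc);
    rnd.push_back(n_dna);
    rnf.push_back(n_free);
  };
  record(0.0);

  bool crossed = false;
  double crossing_time = NA_REAL;

  for (long i = 1; i <= n_steps; ++i) {
    const double t = i * dt;

    // force on the complex from attached tethers (restoring, per axis)
    double Gx = 0.0, Gy = 0.0, Hx = 0.0, Hy = 0.0;
    if (dimers_move && n_pc > 0) {
      for (int j = 0; j < n_ParA; ++j) {
        if (st[j] == PC_BOUND) {
          Gx += (ex[j] - px[j]) * inv_sx2;
          Gy += (ey[j] - py[j]) * inv_sy2;
        }
      }
      Hx = -n_pc * inv_sx2;
      Hy = -n_pc * inv_sy2;
    }

    // advance the complex; in the diffusion-binding model an attachment to
    // an immobile DNA-bound dimer stalls the complex until hydrolysis
    const bool stalled = (model == 2 && n_pc > 0);
    double xn, yn;
    if (stalled) {
      xn = xpc;
      yn = ypc;
    } else if (Hx != 0.0) {
      const Pair nx = corr_pair(rng, D_PC, dt);
      const Pair ny = corr_pair(rng, D_PC, dt);
      xn = xpc + nx.r0 + D_PC * Gx * dt +
           0.5 * D_PC * D_PC * Gx * Hx * dt * dt + D_PC * Hx * nx.r1;
      yn = ypc + ny.r0 + D_PC * Gy * dt +
           0.5 * D_PC * D_PC * Gy * Hy * dt * dt + D_PC * Hy * ny.r1;
    } else {
      xn = xpc + std::sqrt(2.0 * D_PC * dt) * rng.norm();
      yn = ypc + std::sqrt(2.0 * D_PC * dt) * rng.norm();
    }

    if (xn >= x_finish) {  // absorbed at the translocation end point
      crossed = true;
      crossing_time = t;
      xpc = x_finish;
      ypc = reflect1(yn, ylo, yhi);
      record(t);
      break;
    }
    xn = reflect1(xn, 0.0, l0);
    yn = reflect1(yn, ylo, yhi);
    const double dx = xn - xpc, dy = yn - ypc;
    xpc = xn;
    ypc = yn;

    if (has_dimers) {
      for (int j = 0; j < n_ParA; ++j) {
        switch (st[j]) {
          case PC_BOUND:
            if (dimers_move) {  // attached dimers track the complex exactly
              px[j] += dx;
              py[j] += dy;
            }
            if (nev[j] <= t) {  // hydrolysis releases the dimer
              st[j] = FREE;
              nev[j] = t + rng.rexp(tau_db);
              --n_pc;
              ++n_free;
            }
            break;
          case DNA_BOUND: {
            if (dimers_move) {  // harmonic fluctuation about the tether point
              const Pair nx2 = corr_pair(rng, D_A, dt);
              const Pair ny2 = corr_pair(rng, D_A, dt);
              px[j] = ex[j] + c1x * (px[j] - ex[j]) + nx2.r0 + c2x * nx2.r1;
              py[j] = ey[j] + c1y * (py[j] - ey[j]) + ny2.r0 + c2y * ny2.r1;
              px[j] = reflect1(px[j], 0.0, l0);
              py[j] = reflect1(py[j], ylo, yhi);
            }
            const double ddx = px[j] - xpc, ddy = py[j] - ypc;
            if (ddx * ddx + ddy * ddy <= capt2) {  // capture on disk overlap
              st[j] = PC_BOUND;
              nev[j] = k_cat > 0 ? t + rng.rexp(1.0 / k_cat) : INF;
              --n_dna;
              ++n_pc;
            }
            break;
          }
          case FREE:
            if (nev[j] <= t) {  // rebind ahead of the complex
              st[j] = DNA_BOUND;
              px[j] = xpc + (l0 - xpc) * std::sqrt(rng.unif());
              py[j] = ylo + w0 * rng.unif();
              ex[j] = px[j];
              ey[j] = py[j];
              nev[j] = INF;
            }
            break;
        }
      }
    }

    if (i % record_every == 0) record(t);
  }
  if (!crossed && (n_steps % record_every != 0)) record(n_steps * dt);

  DataFrame dimers = DataFrame::create(
      _["x"] = NumericVector(px.begin(), px.end()),
      _["y"] = NumericVector(py.begin(), py.end()),
      _["eq_x"] = NumericVector(ex.begin(), ex.end()),
      _["eq_y"] = NumericVector(ey.begin(), ey.end()),
      _["state"] = IntegerVector(st.begin(), st.end()));

  return List::create(
      _["t"] = NumericVector(rt.begin(), rt.end()),
      _["x"] = NumericVector(rx.begin(), rx.end()),
      _["y"] = NumericVector(ry.begin(), ry.end()),
      _["n_bound"] = IntegerVector(rnb.begin(), rnb.end()),
      _["n_dna"] = IntegerVector(rnd.begin(), rnd.end()),
      _["n_free"] = IntegerVector(rnf.begin(), rnf.end()),
      _["crossed"] = crossed, _["crossing_time"] = crossing_time,
      _["dimers"] = dimers);
}
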