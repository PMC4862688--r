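// Compiled core for the one-bead structure-based model:
// energy/force evaluation, underdamped (BAOAB) Langevin dynamics with an
// optional harmonic bias on a logistic contact coordinate Q, and fast
// evaluation of Q over contact sets.
//
// Units: length nm, energy kcal/mol, time ps, temperature K, mass amu.
// 1 kcal/mol = 4.184 amu nm^2 ps^-2 (MECH below).
//
// Numerical safeguards: angle terms are harmonic in cos(theta) (no
// singularity at colinear triples), nonbonded interactions are truncated
// (natives at 3 r0, repulsives at 2.5 sigma), overlapping beads are softened
// below 0.1 nm, and per-component forces are capped.  A Verlet neighbor
// list (skin 0.4 nm) is rebuilt every NLIST_EVERY steps during dynamics.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0019872;   // kcal/mol/K
static const double MECH = 4.184;     // kcal/mol -> amu nm^2/ps^2
static const double FCAP = 2000.0;    // kcal/mol/nm per component
static const double SKIN = 0.4;       // neighbor-list skin, nm
static const int NLIST_EVERY = 20;

// ---- deterministic RNG (xoshiro256++, seeded via splitmix64) ----
static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  bool has_g;
  double g2;
  explicit Xoshiro(uint64_t seed) : has_g(false), g2(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  uint64_t next() {
    const uint64_t r = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;   s[3] = rotl64(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {
    if (has_g) { has_g = false; return g2; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    const double u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 2.0 * M_PI * u2;
    g2 = r * std::sin(a);
    has_g = true;
    return r * std::cos(a);
  }
};

struct BondT { int i, j; double r0, k; };
struct AngleT { int i, j, k; double c0, kc; };   // harmonic in cos(theta)
struct DihT { int i, j, k, l; double cphi0, sphi0, k1, k3; };
struct PairT { int i, j; int type; double a, b, cut2; };
// type 0: repulsive, a = rep_eps, b = sigma^2;  type 1: native, a = |eps|,
// b = r0^2

struct Core {
  int n;
  std::vector<BondT> bonds;
  std::vector<AngleT> angles;
  std::vector<DihT> dihs;
  std::vector<PairT> pairs;

  explicit Core(const List& m) {
    n = as<int>(m["n"]);
    IntegerMatrix b = m["bonds"];
    NumericVector br0 = m["bond_r0"], bk = m["bond_k"];
    for (int t = 0; t < b.nrow(); ++t) {
      bonds.push_back({b(t, 0) - 1, b(t, 1) - 1, br0[t], bk[t]});
    }
    IntegerMatrix a = m["angles"];
    NumericVector th0 = m["theta0"], ak = m["angle_k"];
    for (int t = 0; t < a.nrow(); ++t) {
      // match the harmonic-in-theta curvature at theta0
      double s2 = std::sin(th0[t]); s2 *= s2;
      if (s2 < 0.1) s2 = 0.1;
      angles.push_back({a(t, 0) - 1, a(t, 1) - 1, a(t, 2) - 1,
                        std::cos(th0[t]), ak[t] / s2});
    }
    IntegerMatrix d = m["dihedrals"];
    NumericVector p0 = m["phi0"], k1 = m["dih_k1"], k3 = m["dih_k3"];
    for (int t = 0; t < d.nrow(); ++t) {
      dihs.push_back({d(t, 0) - 1, d(t, 1) - 1, d(t, 2) - 1, d(t, 3) - 1,
                      std::cos(p0[t]), std::sin(p0[t]), k1[t], k3[t]});
    }
    IntegerMatrix code = m["pair_code"];
    NumericMatrix peps = m["pair_eps"], pr0 = m["pair_r0"];
    NumericVector sigma = m["sigma"];
    double rep_eps = as<double>(m["rep_eps"]);
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const int c = code(i, j);
        if (c < 0) continue;
        if (c == 0) {
          const double s = 0.5 * (sigma[i] + sigma[j]);
          pairs.push_back({i, j, 0, rep_eps, s * s, 6.25 * s * s});
        } else {
          const double r0 = pr0(i, j);
          pairs.push_back({i, j, 1, peps(i, j), r0 * r0, 9.0 * r0 * r0});
        }
      }
    }
  }
};

struct Bias {
  bool active;
  std::vector<int> bi, bj;
  std::vector<double> br0;
  double k, q0, beta, lam;
};

struct EnergyTerms {
  double bond, angle, dihedral, native, repulsive, bias;
  double total() const {
    return bond + angle + dihedral + native + repulsive + bias;
  }
};

// Energy and (optionally) forces over a candidate pair index list.
static EnergyTerms eval_model(const Core& c, const double* x,
                              double* F, const Bias* bias,
                              const std::vector<int>* active) {
  EnergyTerms E = {0, 0, 0, 0, 0, 0};
  const int n = c.n;
  if (F) std::fill(F, F + 3 * n, 0.0);

  for (const BondT& b : c.bonds) {
    const double dx = x[3 * b.i] - x[3 * b.j];
    const double dy = x[3 * b.i + 1] - x[3 * b.j + 1];
    const double dz = x[3 * b.i + 2] - x[3 * b.j + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double d = r - b.r0;
    E.bond += b.k * d * d;
    if (F && r > 1e-9) {
      const double fs = -2.0 * b.k * d / r;
      F[3 * b.i] += fs * dx; F[3 * b.i + 1] += fs * dy; F[3 * b.i + 2] += fs * dz;
      F[3 * b.j] -= fs * dx; F[3 * b.j + 1] -= fs * dy; F[3 * b.j + 2] -= fs * dz;
    }
  }

  for (const AngleT& a : c.angles) {
    const double ux = x[3 * a.i] - x[3 * a.j];
    const double uy = x[3 * a.i + 1] - x[3 * a.j + 1];
    const double uz = x[3 * a.i + 2] - x[3 * a.j + 2];
    const double vx = x[3 * a.k] - x[3 * a.j];
    const double vy = x[3 * a.k + 1] - x[3 * a.j + 1];
    const double vz = x[3 * a.k + 2] - x[3 * a.j + 2];
    const double nu2 = ux * ux + uy * uy + uz * uz;
    const double nv2 = vx * vx + vy * vy + vz * vz;
    if (nu2 < 1e-12 || nv2 < 1e-12) continue;
    const double nu = std::sqrt(nu2), nv = std::sqrt(nv2);
    const double cth = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    const double d = cth - a.c0;
    E.angle += a.kc * d * d;
    if (F) {
      const double pref = -2.0 * a.kc * d;  // = -dV/dcos
      const double inv = 1.0 / (nu * nv);
      const double cu = cth / nu2, cv = cth / nv2;
      const double gix = vx * inv - cu * ux, giy = vy * inv - cu * uy,
                   giz = vz * inv - cu * uz;
      const double gkx = ux * inv - cv * vx, gky = uy * inv - cv * vy,
                   gkz = uz * inv - cv * vz;
      F[3 * a.i] += pref * gix; F[3 * a.i + 1] += pref * giy; F[3 * a.i + 2] += pref * giz;
      F[3 * a.k] += pref * gkx; F[3 * a.k + 1] += pref * gky; F[3 * a.k + 2] += pref * gkz;
      F[3 * a.j] -= pref * (gix + gkx);
      F[3 * a.j + 1] -= pref * (giy + gky);
      F[3 * a.j + 2] -= pref * (giz + gkz);
    }
  }

  // dihedrals: V = k1 (1 - cos(phi - phi0)) + k3 (1 - cos(3(phi - phi0))),
  // evaluated trig-free from cos/sin of phi
  for (const DihT& dh : c.dihs) {
    const double b1x = x[3 * dh.j] - x[3 * dh.i];
    const double b1y = x[3 * dh.j + 1] - x[3 * dh.i + 1];
    const double b1z = x[3 * dh.j + 2] - x[3 * dh.i + 2];
    const double b2x = x[3 * dh.k] - x[3 * dh.j];
    const double b2y = x[3 * dh.k + 1] - x[3 * dh.j + 1];
    const double b2z = x[3 * dh.k + 2] - x[3 * dh.j + 2];
    const double b3x = x[3 * dh.l] - x[3 * dh.k];
    const double b3y = x[3 * dh.l + 1] - x[3 * dh.k + 1];
    const double b3z = x[3 * dh.l + 2] - x[3 * dh.k + 2];
    const double mx = b1y * b2z - b1z * b2y;
    const double my = b1z * b2x - b1x * b2z;
    const double mz = b1x * b2y - b1y * b2x;
    const double nx = b2y * b3z - b2z * b3y;
    const double ny = b2z * b3x - b2x * b3z;
    const double nz = b2x * b3y - b2y * b3x;
    const double msq = mx * mx + my * my + mz * mz;
    const double nsq = nx * nx + ny * ny + nz * nz;
    const double b2sq = b2x * b2x + b2y * b2y + b2z * b2z;
    if (msq < 1e-12 || nsq < 1e-12 || b2sq < 1e-12) continue;
    const double b2n = std::sqrt(b2sq);
    const double mn = std::sqrt(msq * nsq);
    const double cphi = (mx * nx + my * ny + mz * nz) / mn;
    // sin(phi) = (m x n) . b2hat / (|m||n|) = (m . b3) |b2| / (|m||n|)
    const double sphi = (mx * b3x + my * b3y + mz * b3z) * b2n / mn;
    const double cd = cphi * dh.cphi0 + sphi * dh.sphi0;   // cos(dphi)
    const double sd = sphi * dh.cphi0 - cphi * dh.sphi0;   // sin(dphi)
    E.dihedral += dh.k1 * (1.0 - cd) + dh.k3 * (1.0 - (4.0 * cd * cd * cd - 3.0 * cd));
    if (F) {
      // dV/dphi = k1 sin(dphi) + 3 k3 sin(3 dphi)
      const double s3 = 3.0 * sd - 4.0 * sd * sd * sd;
      const double dVdphi = dh.k1 * sd + 3.0 * dh.k3 * s3;
      const double ci = -b2n / msq, cl = b2n / nsq;
      const double dpix = ci * mx, dpiy = ci * my, dpiz = ci * mz;
      const double dplx = cl * nx, dply = cl * ny, dplz = cl * nz;
      const double p = (b1x * b2x + b1y * b2y + b1z * b2z) / b2sq;
      const double q = (b3x * b2x + b3y * b2y + b3z * b2z) / b2sq;
      const double djx = -(1.0 + p) * dpix + q * dplx;
      const double djy = -(1.0 + p) * dpiy + q * dply;
      const double djz = -(1.0 + p) * dpiz + q * dplz;
      const double dkx = p * dpix - (1.0 + q) * dplx;
      const double dky = p * dpiy - (1.0 + q) * dply;
      const double dkz = p * dpiz - (1.0 + q) * dplz;
      F[3 * dh.i] -= dVdphi * dpix; F[3 * dh.i + 1] -= dVdphi * dpiy; F[3 * dh.i + 2] -= dVdphi * dpiz;
      F[3 * dh.j] -= dVdphi * djx;  F[3 * dh.j + 1] -= dVdphi * djy;  F[3 * dh.j + 2] -= dVdphi * djz;
      F[3 * dh.k] -= dVdphi * dkx;  F[3 * dh.k + 1] -= dVdphi * dky;  F[3 * dh.k + 2] -= dVdphi * dkz;
      F[3 * dh.l] -= dVdphi * dplx; F[3 * dh.l + 1] -= dVdphi * dply; F[3 * dh.l + 2] -= dVdphi * dplz;
    }
  }

  // nonbonded pairs (over the active neighbor list when given)
  const size_t np = active ? active->size() : c.pairs.size();
  for (size_t t = 0; t < np; ++t) {
    const PairT& pr = c.pairs[active ? (*active)[t] : (int)t];
    const double dx = x[3 * pr.i] - x[3 * pr.j];
    const double dy = x[3 * pr.i + 1] - x[3 * pr.j + 1];
    const double dz = x[3 * pr.i + 2] - x[3 * pr.j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > pr.cut2) continue;
    bool flat = false;
    if (r2 < 0.01) { r2 = 0.01; flat = true; }  // flat core below 0.1 nm
    double fs;
    // truncation shifts: potentials vanish continuously at the cutoffs
    static const double SH_REP = std::pow(1.0 / 6.25, 6);      // (sigma/cut)^12
    static const double SH_NAT = 13.0 * std::pow(1.0 / 9.0, 6) -
                                 18.0 * std::pow(1.0 / 9.0, 5) +
                                 4.0 * std::pow(1.0 / 9.0, 3); // at 3 r0
    if (pr.type == 0) {
      const double y2 = pr.b / r2;
      const double y6 = y2 * y2 * y2;
      const double V = pr.a * y6 * y6;
      E.repulsive += V - pr.a * SH_REP;
      fs = 12.0 * V / r2;
    } else {
      // 12-10-6 native well with a desolvation barrier (well depth -a at r0)
      const double x2 = pr.b / r2;
      const double x4 = x2 * x2;
      const double x6 = x4 * x2;
      const double x10 = x4 * x4 * x2;
      const double x12 = x10 * x2;
      E.native += pr.a * (13.0 * x12 - 18.0 * x10 + 4.0 * x6 - SH_NAT);
      fs = pr.a * (156.0 * x12 - 180.0 * x10 + 24.0 * x6) / r2;
    }
    if (flat) fs = 0.0;
    if (F) {
      F[3 * pr.i] += fs * dx; F[3 * pr.i + 1] += fs * dy; F[3 * pr.i + 2] += fs * dz;
      F[3 * pr.j] -= fs * dx; F[3 * pr.j + 1] -= fs * dy; F[3 * pr.j + 2] -= fs * dz;
    }
  }

  // harmonic bias on Q over a contact set
  if (bias && bias->active) {
    const int ns = (int)bias->bi.size();
    std::vector<double> ex(ns);
    double Q = 0.0;
    for (int t = 0; t < ns; ++t) {
      const int i = bias->bi[t], j = bias->bj[t];
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double arg = bias->beta * (r - bias->lam * bias->br0[t]);
      const double e = (arg > 40.0) ? std::exp(40.0) : std::exp(arg);
      ex[t] = e;
      Q += 1.0 / (1.0 + e);
    }
    Q /= ns;
    const double dev = Q - bias->q0;
    E.bias += 0.5 * bias->k * dev * dev;
    if (F) {
      const double dVdQ = bias->k * dev;
      for (int t = 0; t < ns; ++t) {
        const int i = bias->bi[t], j = bias->bj[t];
        const double dx = x[3 * i] - x[3 * j];
        const double dy = x[3 * i + 1] - x[3 * j + 1];
        const double dz = x[3 * i + 2] - x[3 * j + 2];
        const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-9) continue;
        const double op = 1.0 + ex[t];
        const double dQdr = -bias->beta * ex[t] / (op * op) / ns;
        const double fscal = -dVdQ * dQdr / r;
        F[3 * i] += fscal * dx; F[3 * i + 1] += fscal * dy; F[3 * i + 2] += fscal * dz;
        F[3 * j] -= fscal * dx; F[3 * j + 1] -= fscal * dy; F[3 * j + 2] -= fscal * dz;
      }
    }
  }
  if (F) {
    for (int i = 0; i < 3 * n; ++i) {
      if (F[i] > FCAP) F[i] = FCAP;
      else if (F[i] < -FCAP) F[i] = -FCAP;
    }
  }
  return E;
}

static void rebuild_nlist(const Core& c, const double* x,
                          std::vector<int>& active) {
  active.clear();
  const double skin2pad = SKIN;
  for (size_t t = 0; t < c.pairs.size(); ++t) {
    const PairT& pr = c.pairs[t];
    const double dx = x[3 * pr.i] - x[3 * pr.j];
    const double dy = x[3 * pr.i + 1] - x[3 * pr.j + 1];
    const double dz = x[3 * pr.i + 2] - x[3 * pr.j + 2];
    const double r2 = dx * dx + dy * dy + dz * dz;
    const double cut = std::sqrt(pr.cut2) + skin2pad;
    if (r2 < cut * cut) active.push_back((int)t);
  }
}

static std::vector<double> flatten(const NumericMatrix& m) {
  const int n = m.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = m(i, 0); x[3 * i + 1] = m(i, 1); x[3 * i + 2] = m(i, 2);
  }
  return x;
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix coords, List model) {
  Core c(model);
  std::vector<double> x = flatten(coords);
  EnergyTerms E = eval_model(c, x.data(), nullptr, nullptr, nullptr);
  return List::create(_["bond"] = E.bond, _["angle"] = E.angle,
                      _["dihedral"] = E.dihedral, _["native"] = E.native,
                      _["repulsive"] = E.repulsive, _["total"] = E.total());
}

// [[Rcpp::export]]
NumericMatrix cg_forces_cpp(NumericMatrix coords, List model) {
  Core c(model);
  std::vector<double> x = flatten(coords);
  std::vector<double> F(x.size());
  eval_model(c, x.data(), F.data(), nullptr, nullptr);
  NumericMatrix out(c.n, 3);
  for (int i = 0; i < c.n; ++i) {
    out(i, 0) = F[3 * i]; out(i, 1) = F[3 * i + 1]; out(i, 2) = F[3 * i + 2];
  }
  return out;
}

// Logistic fraction-of-contacts over one set (columns i, j, r0).
static double qset_eval(const double* x, const NumericMatrix& set,
                        double beta, double lam) {
  const int ns = set.nrow();
  double Q = 0.0;
  for (int t = 0; t < ns; ++t) {
    const int i = (int)set(t, 0) - 1, j = (int)set(t, 1) - 1;
    const double dx = x[3 * i] - x[3 * j];
    const double dy = x[3 * i + 1] - x[3 * j + 1];
    const double dz = x[3 * i + 2] - x[3 * j + 2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double arg = beta * (r - lam * set(t, 2));
    Q += (arg > 40.0) ? 0.0 : 1.0 / (1.0 + std::exp(arg));
  }
  return Q / ns;
}

// [[Rcpp::export]]
double q_logistic_cpp(NumericMatrix coords, NumericMatrix set, double beta,
                      double lam) {
  std::vector<double> x = flatten(coords);
  return qset_eval(x.data(), set, beta, lam);
}

// BAOAB Langevin integrator.
// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix coords0, List model, List opts) {
  Core c(model);
  const double n_steps_d = as<double>(opts["n_steps"]);
  const long n_steps = (long)n_steps_d;
  const double dt = as<double>(opts["dt"]);
  const double gamma = as<double>(opts["friction"]);
  const double T = as<double>(opts["temperature"]);
  const double mass = as<double>(opts["mass"]);
  const uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  const int save_every = as<int>(opts["save_every"]);
  const int check_every = as<int>(opts["check_every"]);
  const double beta = as<double>(opts["beta"]);
  const double lam = as<double>(opts["lam"]);
  const double stop_threshold = as<double>(opts["stop_threshold"]);
  List qsets = as<List>(opts["qsets"]);
  IntegerMatrix stop_groups = as<IntegerMatrix>(opts["stop_groups"]);
  const int nset = qsets.size();

  Bias bias; bias.active = false;
  if (opts.containsElementNamed("bias") && !Rf_isNull(opts["bias"])) {
    List bl = as<List>(opts["bias"]);
    NumericMatrix bset = as<NumericMatrix>(bl["set"]);
    bias.active = true;
    for (int t = 0; t < bset.nrow(); ++t) {
      bias.bi.push_back((int)bset(t, 0) - 1);
      bias.bj.push_back((int)bset(t, 1) - 1);
      bias.br0.push_back(bset(t, 2));
    }
    bias.k = as<double>(bl["k"]);
    bias.q0 = as<double>(bl["q0"]);
    bias.beta = beta; bias.lam = lam;
  }

  std::vector<double> x = flatten(coords0);
  const int n = c.n;
  std::vector<double> v(3 * n), F(3 * n);
  Xoshiro rng(seed);
  const double vsd = std::sqrt(KB * T * MECH / mass);
  for (int i = 0; i < 3 * n; ++i) v[i] = (T > 0) ? vsd * rng.gauss() : 0.0;

  const double c1 = std::exp(-gamma * dt);
  const double c2 = (T > 0) ? std::sqrt(1.0 - c1 * c1) * vsd : 0.0;
  const double acc = MECH * dt * 0.5 / mass;  // kick prefactor

  const long n_checks = (check_every > 0) ? n_steps / check_every : 0;
  NumericMatrix qhist(std::max(n_checks, 1L), std::max(nset, 1));
  std::fill(qhist.begin(), qhist.end(), NA_REAL);
  NumericVector echeck(std::max(n_checks, 1L), NA_REAL);
  IntegerVector check_step(std::max(n_checks, 1L), NA_INTEGER);

  const long n_frames = (save_every > 0) ? n_steps / save_every : 0;
  NumericVector frames((n_frames > 0) ? (R_xlen_t)n_frames * 3 * n : 0);

  std::vector<int> active;
  rebuild_nlist(c, x.data(), active);
  EnergyTerms E = eval_model(c, x.data(), F.data(),
                             bias.active ? &bias : nullptr, &active);
  bool blown = false;
  int stop_group = 0;
  long step = 0;
  long icheck = 0, iframe = 0;

  for (step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * n; ++i) v[i] += acc * F[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (T > 0) {
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * rng.gauss();
    } else {
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (step % NLIST_EVERY == 0) rebuild_nlist(c, x.data(), active);
    E = eval_model(c, x.data(), F.data(), bias.active ? &bias : nullptr,
                   &active);
    for (int i = 0; i < 3 * n; ++i) v[i] += acc * F[i];

    if (save_every > 0 && step % save_every == 0 && iframe < n_frames) {
      for (int i = 0; i < n; ++i) {
        frames[(R_xlen_t)iframe * 3 * n + i] = x[3 * i];
        frames[(R_xlen_t)iframe * 3 * n + n + i] = x[3 * i + 1];
        frames[(R_xlen_t)iframe * 3 * n + 2 * n + i] = x[3 * i + 2];
      }
      ++iframe;
    }

    if (check_every > 0 && step % check_every == 0) {
      const double etot = E.total();
      if (!std::isfinite(etot) || std::fabs(etot) > 1e9) { blown = true; break; }
      if (icheck < n_checks) {
        echeck[icheck] = etot;
        check_step[icheck] = (int)step;
        for (int s = 0; s < nset; ++s) {
          qhist(icheck, s) =
              qset_eval(x.data(), as<NumericMatrix>(qsets[s]), beta, lam);
        }
        if (stop_threshold > 0 && stop_groups.nrow() > 0) {
          for (int g = 0; g < stop_groups.nrow(); ++g) {
            const double qi = qhist(icheck, stop_groups(g, 0) - 1);
            const double qo = qhist(icheck, stop_groups(g, 1) - 1);
            if (qi >= stop_threshold && qo >= stop_threshold) {
              stop_group = g + 1;
              break;
            }
          }
        }
        ++icheck;
        if (stop_group > 0) break;
      }
    }
  }

  NumericMatrix xout(n, 3);
  for (int i = 0; i < n; ++i) {
    xout(i, 0) = x[3 * i]; xout(i, 1) = x[3 * i + 1]; xout(i, 2) = x[3 * i + 2];
  }
  List out = List::create(
      _["coords"] = xout, _["steps_done"] = (double)std::min(step, n_steps),
      _["qhist"] = qhist, _["check_step"] = check_step,
      _["energy"] = echeck, _["n_checks"] = (double)icheck,
      _["stop_group"] = stop_group, _["blown"] = blown);
  if (n_frames > 0) {
    frames.attr("dim") = IntegerVector::create(n, 3, (int)n_frames);
    out["frames"] = frames;
    out["n_frames"] = (double)iframe;
  }
  return out;
}
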