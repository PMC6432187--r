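// Monte Carlo kernel for coarse-grained semiflexible polymers.
//
// Layout contract (enforced on the R side): beads are stored contiguously,
// M chains of N beads each, chain c owning indices [c*N, (c+1)*N).
// Energies: shifted-truncated LJ over non-bonded pairs, worm-like-chain
// bending kappa*(1-cos theta), FENE bonds (bead-spring only).  The bending
// sum is tracked unmultiplied so p(ELJ, EBend) histograms need no re-run.
// Minimal image applies to inter-chain pair distances only; chains are
// stored unwrapped.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const double E_INF = std::numeric_limits<double>::infinity();

struct Model {
  bool spring;
  double eps, sigma, rc2, kappa, rb, K, Rf, r0, shift;
};

Model parse_model(const List& m) {
  Model mod;
  std::string kind = as<std::string>(m["kind"]);
  mod.spring = (kind == "bead_spring");
  mod.eps = as<double>(m["epsilon"]);
  mod.sigma = as<double>(m["sigma"]);
  double rc = as<double>(m["rc"]);
  mod.rc2 = rc * rc;
  mod.kappa = as<double>(m["kappa"]);
  mod.rb = mod.spring ? 1.0 : as<double>(m["rb"]);
  mod.K = mod.spring ? as<double>(m["K"]) : 0.0;
  mod.Rf = mod.spring ? as<double>(m["R"]) : 0.0;
  mod.r0 = mod.spring ? as<double>(m["r0"]) : 0.0;
  double s6 = std::pow(mod.sigma * mod.sigma / mod.rc2, 3.0);
  mod.shift = 4.0 * mod.eps * (s6 * s6 - s6);
  return mod;
}

inline double lj_r2(const Model& m, double r2) {
  if (r2 >= m.rc2) return 0.0;
  double s2 = m.sigma * m.sigma / r2;
  double s6 = s2 * s2 * s2;
  return 4.0 * m.eps * (s6 * s6 - s6) - m.shift;
}

inline double fene_r(const Model& m, double r) {
  double x = (r - m.r0) / m.Rf;
  double arg = 1.0 - x * x;
  if (arg <= 0.0) return E_INF;
  return -0.5 * m.K * m.Rf * m.Rf * std::log(arg);
}

// xoshiro-free deterministic RNG: mt19937_64 + hand-rolled mappings so the
// stream does not depend on the standard library's distribution internals.
struct RNG {
  std::mt19937_64 eng;
  explicit RNG(uint64_t s) : eng(s) {}
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  int randint(int n) {  // 0..n-1
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
  void rand_axis(double* u) {  // uniform on the unit sphere (Marsaglia)
    double x1, x2, s;
    do {
      x1 = 2.0 * unif() - 1.0;
      x2 = 2.0 * unif() - 1.0;
      s = x1 * x1 + x2 * x2;
    } while (s >= 1.0 || s == 0.0);
    double f = 2.0 * std::sqrt(1.0 - s);
    u[0] = x1 * f;
    u[1] = x2 * f;
    u[2] = 1.0 - 2.0 * s;
  }
};

struct Sys {
  int n, M, N;
  double L;  // box edge, <= 0 means no box
  std::vector<double> x, y, z;
  Model mod;

  int chain_of(int i) const { return i / N; }
  bool bonded(int i, int j) const {
    return chain_of(i) == chain_of(j) && std::abs(i - j) == 1;
  }
  inline double mi(double d) const { return d - L * std::floor(d / L + 0.5); }
  double dist2(int i, int j) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    if (L > 0.0 && chain_of(i) != chain_of(j)) {
      dx = mi(dx); dy = mi(dy); dz = mi(dz);
    }
    return dx * dx + dy * dy + dz * dz;
  }
};

// bending term (1 - cos theta) at interior vertex v (global index)
inline double bend_at(const Sys& s, int v) {
  double b1x = s.x[v] - s.x[v - 1], b1y = s.y[v] - s.y[v - 1], b1z = s.z[v] - s.z[v - 1];
  double b2x = s.x[v + 1] - s.x[v], b2y = s.y[v + 1] - s.y[v], b2z = s.z[v + 1] - s.z[v];
  double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
  double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
  double ct = (b1x * b2x + b1y * b2y + b1z * b2z) / (n1 * n2);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return 1.0 - ct;
}

// is v an interior vertex of its chain?
inline bool interior_vertex(const Sys& s, int v) {
  if (v < 0 || v >= s.n) return false;
  int p = v % s.N;
  return p > 0 && p < s.N - 1;
}

void full_energy(const Sys& s, double& elj, double& eb, double& ef, bool& bad) {
  elj = 0.0; eb = 0.0; ef = 0.0; bad = false;
  for (int i = 0; i < s.n; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      if (s.bonded(i, j)) continue;
      double r2 = s.dist2(i, j);
      if (r2 < 1e-16) { bad = true; return; }
      elj += lj_r2(s.mod, r2);
    }
  }
  for (int v = 0; v < s.n; ++v)
    if (interior_vertex(s, v)) eb += bend_at(s, v);
  if (s.mod.spring) {
    for (int i = 0; i < s.n - 1; ++i) {
      if (!s.bonded(i, i + 1)) continue;
      double r = std::sqrt(s.dist2(i, i + 1));
      double e = fene_r(s.mod, r);
      if (!std::isfinite(e)) { bad = true; return; }
      ef += e;
    }
  }
}

// LJ between moved range [lo,hi] and the rest, bonded pairs excluded
double range_lj(const Sys& s, int lo, int hi, bool& bad) {
  double e = 0.0;
  for (int i = lo; i <= hi; ++i) {
    for (int j = 0; j < s.n; ++j) {
      if (j >= lo && j <= hi) continue;
      if (s.bonded(i, j)) continue;
      double r2 = s.dist2(i, j);
      if (r2 < 1e-16) { bad = true; return 0.0; }
      e += lj_r2(s.mod, r2);
    }
  }
  return e;
}

double range_bend(const Sys& s, int lo, int hi) {
  int cand[4] = {lo - 1, lo, hi, hi + 1};
  double e = 0.0;
  int seen[4]; int ns = 0;
  for (int k = 0; k < 4; ++k) {
    int v = cand[k];
    bool dup = false;
    for (int q = 0; q < ns; ++q) if (seen[q] == v) dup = true;
    if (dup) continue;
    seen[ns++] = v;
    if (interior_vertex(s, v)) e += bend_at(s, v);
  }
  return e;
}

double range_fene(const Sys& s, int lo, int hi) {
  if (!s.mod.spring) return 0.0;
  double e = 0.0;
  if (lo - 1 >= 0 && s.bonded(lo - 1, lo))
    e += fene_r(s.mod, std::sqrt(s.dist2(lo - 1, lo)));
  if (hi + 1 < s.n && s.bonded(hi, hi + 1))
    e += fene_r(s.mod, std::sqrt(s.dist2(hi, hi + 1)));
  return e;
}

inline void rotate_about(double& px, double& py, double& pz,
                         const double* c, const double* u, double ca, double sa) {
  double vx = px - c[0], vy = py - c[1], vz = pz - c[2];
  double dot = vx * u[0] + vy * u[1] + vz * u[2];
  double cx = u[1] * vz - u[2] * vy;
  double cy = u[2] * vx - u[0] * vz;
  double cz = u[0] * vy - u[1] * vx;
  px = c[0] + vx * ca + cx * sa + u[0] * dot * (1.0 - ca);
  py = c[1] + vy * ca + cy * sa + u[1] * dot * (1.0 - ca);
  pz = c[2] + vz * ca + cz * sa + u[2] * dot * (1.0 - ca);
}

// Move kinds: 0 local displacement, 1 crankshaft (end beads: rotation about
// the single neighbor), 2 pivot, 3 chain translation (new COM uniform in box).
// All proposals are symmetric (Hastings ratio 1).
struct Prop {
  int lo, hi;
  std::vector<double> nx, ny, nz;
  bool ok;
};

void gen_proposal(const Sys& s, int kind, double amp, RNG& rng, Prop& pr) {
  pr.ok = true;
  if (kind == 0) {  // local displacement
    int i = rng.randint(s.n);
    pr.lo = pr.hi = i;
    pr.nx.assign(1, s.x[i] + rng.unif(-amp, amp));
    pr.ny.assign(1, s.y[i] + rng.unif(-amp, amp));
    pr.nz.assign(1, s.z[i] + rng.unif(-amp, amp));
  } else if (kind == 1) {  // crankshaft / end rotation
    int i = rng.randint(s.n);
    int p = i % s.N;
    double c[3], u[3];
    if (p > 0 && p < s.N - 1) {
      u[0] = s.x[i + 1] - s.x[i - 1];
      u[1] = s.y[i + 1] - s.y[i - 1];
      u[2] = s.z[i + 1] - s.z[i - 1];
      double nn = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      if (nn < 1e-12) { rng.rand_axis(u); } else { u[0] /= nn; u[1] /= nn; u[2] /= nn; }
      c[0] = s.x[i - 1]; c[1] = s.y[i - 1]; c[2] = s.z[i - 1];
    } else {
      int j = (p == 0) ? i + 1 : i - 1;
      rng.rand_axis(u);
      c[0] = s.x[j]; c[1] = s.y[j]; c[2] = s.z[j];
    }
    double a = rng.unif(-amp, amp);
    double px = s.x[i], py = s.y[i], pz = s.z[i];
    rotate_about(px, py, pz, c, u, std::cos(a), std::sin(a));
    pr.lo = pr.hi = i;
    pr.nx.assign(1, px); pr.ny.assign(1, py); pr.nz.assign(1, pz);
  } else if (kind == 2) {  // pivot: rotate one side about an interior vertex
    if (s.N < 3) { pr.ok = false; return; }
    int c0 = rng.randint(s.M);
    int p = 1 + rng.randint(s.N - 2);
    int piv = c0 * s.N + p;
    int side = rng.randint(2);
    double u[3], c[3] = {s.x[piv], s.y[piv], s.z[piv]};
    rng.rand_axis(u);
    double a = rng.unif(-amp, amp);
    double ca = std::cos(a), sa = std::sin(a);
    if (side == 0) { pr.lo = piv + 1; pr.hi = c0 * s.N + s.N - 1; }
    else           { pr.lo = c0 * s.N; pr.hi = piv - 1; }
    int m = pr.hi - pr.lo + 1;
    pr.nx.resize(m); pr.ny.resize(m); pr.nz.resize(m);
    for (int k = 0; k < m; ++k) {
      double px = s.x[pr.lo + k], py = s.y[pr.lo + k], pz = s.z[pr.lo + k];
      rotate_about(px, py, pz, c, u, ca, sa);
      pr.nx[k] = px; pr.ny[k] = py; pr.nz[k] = pz;
    }
  } else {  // chain translation
    if (s.L <= 0.0 || s.M < 2) { pr.ok = false; return; }
    int c0 = rng.randint(s.M);
    pr.lo = c0 * s.N; pr.hi = pr.lo + s.N - 1;
    double cmx = 0, cmy = 0, cmz = 0;
    for (int i = pr.lo; i <= pr.hi; ++i) { cmx += s.x[i]; cmy += s.y[i]; cmz += s.z[i]; }
    cmx /= s.N; cmy /= s.N; cmz /= s.N;
    double dx = rng.unif(0.0, s.L) - cmx;
    double dy = rng.unif(0.0, s.L) - cmy;
    double dz = rng.unif(0.0, s.L) - cmz;
    int m = s.N;
    pr.nx.resize(m); pr.ny.resize(m); pr.nz.resize(m);
    for (int k = 0; k < m; ++k) {
      pr.nx[k] = s.x[pr.lo + k] + dx;
      pr.ny[k] = s.y[pr.lo + k] + dy;
      pr.nz[k] = s.z[pr.lo + k] + dz;
    }
  }
}

struct Obs {
  double rgyr2, ree, cr, gamma2;
};

Obs measure(const Sys& s) {
  Obs o; o.rgyr2 = 0.0; o.ree = 0.0; o.cr = NA_REAL; o.gamma2 = NA_REAL;
  std::vector<double> ux, uy, uz, cmx(s.M), cmy(s.M), cmz(s.M);
  int ndef = 0;
  for (int c = 0; c < s.M; ++c) {
    int a = c * s.N, b = a + s.N - 1;
    double mx = 0, my = 0, mz = 0;
    for (int i = a; i <= b; ++i) { mx += s.x[i]; my += s.y[i]; mz += s.z[i]; }
    mx /= s.N; my /= s.N; mz /= s.N;
    cmx[c] = mx; cmy[c] = my; cmz[c] = mz;
    double g = 0;
    for (int i = a; i <= b; ++i) {
      double dx = s.x[i] - mx, dy = s.y[i] - my, dz = s.z[i] - mz;
      g += dx * dx + dy * dy + dz * dz;
    }
    o.rgyr2 += g / s.N;
    double ex = s.x[a] - s.x[b], ey = s.y[a] - s.y[b], ez = s.z[a] - s.z[b];
    double rn = std::sqrt(ex * ex + ey * ey + ez * ez);
    o.ree += rn;
    if (rn > 1e-12) { ux.push_back(ex / rn); uy.push_back(ey / rn); uz.push_back(ez / rn); ndef++; }
  }
  o.rgyr2 /= s.M;
  o.ree /= s.M;
  if (s.M >= 2 && ndef >= 2) {
    double acc = 0; int np = 0;
    for (int i = 0; i < ndef; ++i)
      for (int j = i + 1; j < ndef; ++j) {
        double d = ux[i] * ux[j] + uy[i] * uy[j] + uz[i] * uz[j];
        acc += d * d; np++;
      }
    o.cr = acc / np;
  }
  if (s.M >= 2 && s.L > 0.0) {
    double acc = 0;
    for (int i = 0; i < s.M; ++i)
      for (int j = i + 1; j < s.M; ++j) {
        double dx = s.mi(cmx[i] - cmx[j]);
        double dy = s.mi(cmy[i] - cmy[j]);
        double dz = s.mi(cmz[i] - cmz[j]);
        acc += dx * dx + dy * dy + dz * dz;
      }
    o.gamma2 = acc / (s.M * (double)s.M);  // (1/2M^2) * ordered double sum
  }
  return o;
}

}  // namespace

// [[Rcpp::export]]
List total_energy_cpp(NumericMatrix pos, int n_chains, double boxL, List model) {
  Sys s;
  s.n = pos.nrow(); s.M = n_chains; s.N = s.n / n_chains; s.L = boxL;
  s.mod = parse_model(model);
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) { s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2); }
  double elj, eb, ef; bool bad;
  full_energy(s, elj, eb, ef, bad);
  double ep = bad ? E_INF : elj + s.mod.kappa * eb + ef;
  return List::create(_["elj"] = bad ? E_INF : elj,
                      _["ebend"] = bad ? E_INF : eb,
                      _["efene"] = bad ? E_INF : ef,
                      _["ep"] = ep,
                      _["finite"] = !bad);
}

// [[Rcpp::export]]
List propose_move_cpp(NumericMatrix pos, int n_chains, double boxL, List model,
                      int kind, double amp, double seed) {
  Sys s;
  s.n = pos.nrow(); s.M = n_chains; s.N = s.n / n_chains; s.L = boxL;
  s.mod = parse_model(model);
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) { s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2); }
  RNG rng(static_cast<uint64_t>(seed));
  Prop pr;
  gen_proposal(s, kind, amp, rng, pr);
  if (!pr.ok) return List::create(_["ok"] = false);
  int m = pr.hi - pr.lo + 1;
  NumericMatrix np(m, 3);
  for (int k = 0; k < m; ++k) { np(k, 0) = pr.nx[k]; np(k, 1) = pr.ny[k]; np(k, 2) = pr.nz[k]; }
  return List::create(_["ok"] = true, _["lo"] = pr.lo + 1, _["hi"] = pr.hi + 1,
                      _["newpos"] = np, _["symmetric"] = true);
}

// Core sampler.  wtype: 0 canonical (beta), 1 weight table over Ep.
// Weight-table proposals leaving [emin, emin + nbins*de) are rejected.
// [[Rcpp::export]]
List run_mc_cpp(NumericMatrix pos, int n_chains, double boxL, List model,
                int wtype, double beta,
                NumericVector lnW, double emin, double de,
                IntegerVector move_kinds, NumericVector move_prob, NumericVector amp,
                int sweeps, int discard, int thin,
                double seed, bool tune, int full_every) {
  Sys s;
  s.n = pos.nrow(); s.M = n_chains; s.N = s.n / n_chains; s.L = boxL;
  s.mod = parse_model(model);
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) { s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2); }
  RNG rng(static_cast<uint64_t>(seed));

  int nk = move_kinds.size();
  std::vector<double> cumP(nk), amps(nk);
  double acc = 0;
  for (int k = 0; k < nk; ++k) { acc += move_prob[k]; cumP[k] = acc; amps[k] = amp[k]; }
  for (int k = 0; k < nk; ++k) cumP[k] /= acc;

  double elj, eb, ef; bool bad;
  full_energy(s, elj, eb, ef, bad);
  if (bad) stop("starting conformation has non-finite energy");
  double ep = elj + s.mod.kappa * eb + ef;

  int nbins = lnW.size();
  std::vector<double> hist(wtype == 1 ? nbins : 0, 0.0);
  auto binof = [&](double e) -> int {
    int b = static_cast<int>(std::floor((e - emin) / de));
    return (b < 0 || b >= nbins) ? -1 : b;
  };
  if (wtype == 1 && binof(ep) < 0)
    stop("starting energy outside the weight-table range");

  std::vector<long> prop_cnt(nk, 0), acc_cnt(nk, 0), win_prop(nk, 0), win_acc(nk, 0);
  int total_sweeps = discard + sweeps;
  int nmeas = (thin > 0) ? sweeps / thin : 0;
  std::vector<double> m_sweep, m_ep, m_elj, m_eb, m_ef, m_lnw, m_rg, m_ree, m_cr, m_g2;
  if (nmeas > 0) {
    m_sweep.reserve(nmeas); m_ep.reserve(nmeas); m_elj.reserve(nmeas);
    m_eb.reserve(nmeas); m_ef.reserve(nmeas); m_lnw.reserve(nmeas);
    m_rg.reserve(nmeas); m_ree.reserve(nmeas); m_cr.reserve(nmeas); m_g2.reserve(nmeas);
  }
  double max_drift = 0.0;
  int tune_window = 20;  // sweeps per tuning window during equilibration
  Prop pr;

  for (int sw = 1; sw <= total_sweeps; ++sw) {
    for (int st = 0; st < s.n; ++st) {
      double u = rng.unif();
      int kind = 0;
      for (int k = 0; k < nk; ++k) { if (u <= cumP[k]) { kind = k; break; } kind = k; }
      int kcode = move_kinds[kind];
      win_prop[kind]++; prop_cnt[kind]++;
      gen_proposal(s, kcode, amps[kind], rng, pr);
      if (!pr.ok) continue;

      bool badE = false;
      double olj = range_lj(s, pr.lo, pr.hi, badE);
      double obe = range_bend(s, pr.lo, pr.hi);
      double ofe = range_fene(s, pr.lo, pr.hi);
      int m = pr.hi - pr.lo + 1;
      // stash and apply
      std::vector<double> sx(m), sy(m), sz(m);
      for (int k = 0; k < m; ++k) {
        sx[k] = s.x[pr.lo + k]; sy[k] = s.y[pr.lo + k]; sz[k] = s.z[pr.lo + k];
        s.x[pr.lo + k] = pr.nx[k]; s.y[pr.lo + k] = pr.ny[k]; s.z[pr.lo + k] = pr.nz[k];
      }
      bool badN = false;
      double nlj = range_lj(s, pr.lo, pr.hi, badN);
      double nbe = range_bend(s, pr.lo, pr.hi);
      double nfe = range_fene(s, pr.lo, pr.hi);
      bool reject = badN || !std::isfinite(nfe);
      double dep = 0.0;
      if (!reject) {
        if (badE || !std::isfinite(ofe)) {
          // escaping from a flagged state: always allow
          dep = 0.0;
        } else {
          dep = (nlj - olj) + s.mod.kappa * (nbe - obe) + (nfe - ofe);
        }
        double lacc;
        if (wtype == 0) {
          lacc = -beta * dep;
        } else {
          int b0 = binof(ep), b1 = binof(ep + dep);
          if (b1 < 0) { reject = true; lacc = -E_INF; }
          else lacc = lnW[b1] - lnW[b0];
        }
        if (!reject && lacc < 0.0) {
          double uu = rng.unif();
          if (uu <= 0.0 || std::log(uu) >= lacc) reject = true;
        }
      }
      if (reject) {
        for (int k = 0; k < m; ++k) {
          s.x[pr.lo + k] = sx[k]; s.y[pr.lo + k] = sy[k]; s.z[pr.lo + k] = sz[k];
        }
      } else {
        elj += nlj - olj; eb += nbe - obe; ef += nfe - ofe; ep += dep;
        acc_cnt[kind]++; win_acc[kind]++;
      }
    }

    if (tune && sw <= discard && sw % tune_window == 0) {
      for (int k = 0; k < nk; ++k) {
        if (move_kinds[k] == 3 || win_prop[k] == 0) continue;  // translation untuned
        double r = static_cast<double>(win_acc[k]) / win_prop[k];
        if (r > 0.6) amps[k] *= 1.2; else if (r < 0.3) amps[k] /= 1.2;
        double cap = (move_kinds[k] == 0) ? s.mod.sigma : M_PI;
        if (amps[k] > cap) amps[k] = cap;
        if (amps[k] < 1e-4) amps[k] = 1e-4;
        win_prop[k] = 0; win_acc[k] = 0;
      }
    }

    if (full_every > 0 && sw % full_every == 0) {
      double felj, feb, fef; bool fbad;
      full_energy(s, felj, feb, fef, fbad);
      if (!fbad) {
        double fep = felj + s.mod.kappa * feb + fef;
        double d = std::fabs(fep - ep);
        if (d > max_drift) max_drift = d;
        elj = felj; eb = feb; ef = fef; ep = fep;
      }
    }

    if (sw > discard) {
      if (wtype == 1) {
        int b = binof(ep);
        if (b >= 0) hist[b] += 1.0;
      }
      int ms = sw - discard;
      if (thin > 0 && ms % thin == 0) {
        Obs o = measure(s);
        m_sweep.push_back(ms);
        m_ep.push_back(ep); m_elj.push_back(elj); m_eb.push_back(eb); m_ef.push_back(ef);
        double lw;
        if (wtype == 0) lw = -beta * ep;
        else { int b = binof(ep); lw = (b >= 0) ? lnW[b] : NA_REAL; }
        m_lnw.push_back(lw);
        m_rg.push_back(o.rgyr2); m_ree.push_back(o.ree);
        m_cr.push_back(o.cr); m_g2.push_back(o.gamma2);
      }
    }
  }

  // final bookkeeping check
  double felj, feb, fef; bool fbad;
  full_energy(s, felj, feb, fef, fbad);
  double fep = fbad ? E_INF : felj + s.mod.kappa * feb + fef;
  if (!fbad) {
    double d = std::fabs(fep - ep);
    if (d > max_drift) max_drift = d;
  }

  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) { out(i, 0) = s.x[i]; out(i, 1) = s.y[i]; out(i, 2) = s.z[i]; }
  NumericVector hv(hist.begin(), hist.end());
  NumericVector pc(nk), ac(nk), am(nk);
  for (int k = 0; k < nk; ++k) {
    pc[k] = static_cast<double>(prop_cnt[k]);
    ac[k] = static_cast<double>(acc_cnt[k]);
    am[k] = amps[k];
  }
  return List::create(
      _["series"] = List::create(
          _["sweep"] = m_sweep, _["ep"] = m_ep, _["elj"] = m_elj,
          _["ebend"] = m_eb, _["efene"] = m_ef, _["lnw"] = m_lnw,
          _["rgyr2"] = m_rg, _["ree"] = m_ree, _["cr"] = m_cr, _["gamma2"] = m_g2),
      _["positions"] = out,
      _["hist"] = hv,
      _["ep_final"] = ep,
      _["ep_fresh"] = fep,
      _["max_drift"] = max_drift,
      _["proposed"] = pc, _["accepted"] = ac, _["amplitudes"] = am);
}
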