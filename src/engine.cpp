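// Coarse-grained energy/force kernels and Langevin integrator.
//
// Units: length A, energy kcal/mol, mass amu, time tau = sqrt(amu A^2 / (kcal/mol)).
// All bead indices arriving from R are 1-based and converted here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>

// Fast counter-seeded RNG (xoshiro256+) with Box-Muller normals; seeding via
// splitmix64 so distinct seeds give independent streams.
struct FastRng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  explicit FastRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = (s[3] << 45) | (s[3] >> 19);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// ---------------------------------------------------------------------------
// Potential container
// ---------------------------------------------------------------------------

struct Pot {
  int n;
  // bonds: i, j, r0, k
  std::vector<int> b_i, b_j; std::vector<double> b_r0, b_k;
  // angles: i, j, k (vertex j), th0 (rad), kth
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0, a_kt;
  // dihedrals: i, j, k, l, ph0 (rad), kph, multiplicity
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_p0, d_kp, d_m;
  // native contacts (12-10): i, j, r0, eps
  std::vector<int> c_i, c_j; std::vector<double> c_r0, c_eps;
  // excluded volume
  std::vector<double> sigma; double eps_ev; double ev_factor;
  // electrostatics
  std::vector<double> q, qpd; std::vector<int> isdna;
  double lambda, kpre, dh_cut;
  // hydrogen bonds: prev, donor, phosphate, sugar
  bool has_hb;
  std::vector<int> h_prev, h_don, h_p, h_s;
  double hb_r0, hb_sr, hb_t0, hb_st, hb_p0, hb_sp, hb_eps, hb_filt;
  double hb_ct0, hb_sc;
  bool hb_has_phi;
  // nonbonded exclusions (applies to EV and DH), sorted per bead
  std::vector<std::vector<int>> excl;
  double nl_cut, nl_skin;
  bool any_charge;

  inline bool excluded(int i, int j) const {
    int a = i < j ? i : j, b = i < j ? j : i;
    const std::vector<int>& v = excl[a];
    return std::binary_search(v.begin(), v.end(), b);
  }
};

static void parse_pairs(SEXP m, std::vector<int>& vi, std::vector<int>& vj,
                        std::vector<double>& v1, std::vector<double>& v2) {
  if (Rf_isNull(m)) return;
  NumericMatrix mm(m);
  int nr = mm.nrow();
  vi.reserve(nr); vj.reserve(nr); v1.reserve(nr); v2.reserve(nr);
  for (int r = 0; r < nr; ++r) {
    vi.push_back(static_cast<int>(mm(r, 0)) - 1);
    vj.push_back(static_cast<int>(mm(r, 1)) - 1);
    v1.push_back(mm(r, 2));
    v2.push_back(mm(r, 3));
  }
}

static Pot parse_pot(List pot) {
  Pot p;
  p.n = as<int>(pot["n"]);
  parse_pairs(pot["bonds"], p.b_i, p.b_j, p.b_r0, p.b_k);
  if (!Rf_isNull(pot["angles"])) {
    NumericMatrix am(as<NumericMatrix>(pot["angles"]));
    for (int r = 0; r < am.nrow(); ++r) {
      p.a_i.push_back(static_cast<int>(am(r, 0)) - 1);
      p.a_j.push_back(static_cast<int>(am(r, 1)) - 1);
      p.a_k.push_back(static_cast<int>(am(r, 2)) - 1);
      p.a_t0.push_back(am(r, 3));
      p.a_kt.push_back(am(r, 4));
    }
  }
  if (!Rf_isNull(pot["dihedrals"])) {
    NumericMatrix dm(as<NumericMatrix>(pot["dihedrals"]));
    for (int r = 0; r < dm.nrow(); ++r) {
      p.d_i.push_back(static_cast<int>(dm(r, 0)) - 1);
      p.d_j.push_back(static_cast<int>(dm(r, 1)) - 1);
      p.d_k.push_back(static_cast<int>(dm(r, 2)) - 1);
      p.d_l.push_back(static_cast<int>(dm(r, 3)) - 1);
      p.d_p0.push_back(dm(r, 4));
      p.d_kp.push_back(dm(r, 5));
      p.d_m.push_back(dm.ncol() > 6 ? dm(r, 6) : 1.0);
    }
  }
  parse_pairs(pot["contacts"], p.c_i, p.c_j, p.c_r0, p.c_eps);
  p.sigma = as<std::vector<double>>(pot["sigma"]);
  p.eps_ev = as<double>(pot["eps_ev"]);
  p.ev_factor = as<double>(pot["ev_factor"]);
  p.q = as<std::vector<double>>(pot["q"]);
  p.qpd = as<std::vector<double>>(pot["qpd"]);
  p.isdna = as<std::vector<int>>(pot["isdna"]);
  p.lambda = as<double>(pot["lambda"]);
  p.kpre = as<double>(pot["kpre"]);
  p.dh_cut = as<double>(pot["dh_cut"]);
  p.any_charge = false;
  for (double qi : p.q) if (qi != 0.0) { p.any_charge = true; break; }
  p.has_hb = !Rf_isNull(pot["hb"]);
  if (p.has_hb) {
    List hb(pot["hb"]);
    NumericMatrix hm(as<NumericMatrix>(hb["pairs"]));
    for (int r = 0; r < hm.nrow(); ++r) {
      p.h_prev.push_back(static_cast<int>(hm(r, 0)) - 1);
      p.h_don.push_back(static_cast<int>(hm(r, 1)) - 1);
      p.h_p.push_back(static_cast<int>(hm(r, 2)) - 1);
      p.h_s.push_back(static_cast<int>(hm(r, 3)) - 1);
    }
    p.hb_r0 = as<double>(hb["r0"]);   p.hb_sr = as<double>(hb["sr"]);
    p.hb_t0 = as<double>(hb["th0"]);  p.hb_st = as<double>(hb["sth"]);
    p.hb_p0 = as<double>(hb["ph0"]);  p.hb_sp = as<double>(hb["sph"]);
    p.hb_eps = as<double>(hb["eps"]); p.hb_filt = as<double>(hb["filt"]);
    // angular modulation acts on cos(theta): width mapped so that near theta0
    // it matches a theta-Gaussian of width sth; avoids the acos gradient
    // singularity at collinear geometries
    p.hb_ct0 = std::cos(p.hb_t0);
    p.hb_sc = std::max(std::fabs(std::sin(p.hb_t0)) * p.hb_st, 1e-6);
    p.hb_has_phi = p.hb_sp < 10.0;  // sigma_phi >= ~573 deg: no phi term
  }
  p.excl.assign(p.n, std::vector<int>());
  if (!Rf_isNull(pot["excl"])) {
    IntegerMatrix em(as<IntegerMatrix>(pot["excl"]));
    for (int r = 0; r < em.nrow(); ++r) {
      int a = em(r, 0) - 1, b = em(r, 1) - 1;
      if (a > b) std::swap(a, b);
      p.excl[a].push_back(b);
    }
    for (auto& v : p.excl) {
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
    }
  }
  double smax = 0.0;
  for (double s : p.sigma) smax = std::max(smax, s);
  p.nl_cut = std::max(p.any_charge ? p.dh_cut : 0.0, p.ev_factor * smax);
  p.nl_skin = as<double>(pot["nl_skin"]);
  return p;
}

// ---------------------------------------------------------------------------
// Neighbor list (cell binning, falls back to O(n^2) for small n)
// ---------------------------------------------------------------------------

struct NeighborList {
  std::vector<int> pi, pj;     // excluded-volume pairs (short range)
  std::vector<double> prcv2;   // per-pair EV interaction range^2
  std::vector<int> qi, qj;     // charged pairs (Debye-Huckel range)
  std::vector<double> ref; // coordinates at build time
  std::vector<int> cell_start, cell_items, cidx; // scratch (reused)
  double cut, skin;

  inline void consider(const std::vector<double>& x, const Pot& p,
                       double rc2dh, int i, int j) {
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double rint = p.ev_factor * 0.5 * (p.sigma[i] + p.sigma[j]);
    double rev = rint + skin;
    bool ev = r2 < rev * rev;
    bool dh = p.any_charge && r2 < rc2dh &&
      ((p.isdna[i] != p.isdna[j]) ? (p.qpd[i] != 0.0 && p.qpd[j] != 0.0)
                                  : (p.q[i] != 0.0 && p.q[j] != 0.0));
    if ((ev || dh) && !p.excluded(i, j)) {
      if (ev) { pi.push_back(i); pj.push_back(j); prcv2.push_back(rint * rint); }
      if (dh) { qi.push_back(i); qj.push_back(j); }
    }
  }

  void build(const std::vector<double>& x, const Pot& p) {
    pi.clear(); pj.clear(); prcv2.clear(); qi.clear(); qj.clear();
    ref = x;
    cut = p.nl_cut; skin = p.nl_skin;
    const double rc = cut + skin, rc2 = rc * rc;
    const double rcdh = (p.any_charge ? p.dh_cut : 0.0) + skin;
    const double rc2dh = rcdh * rcdh;
    const int n = p.n;
    if (n <= 400) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
                 dz = x[3 * i + 2] - x[3 * j + 2];
          if (dx * dx + dy * dy + dz * dz < rc2) consider(x, p, rc2dh, i, j);
        }
      return;
    }
    double lo[3] = {0, 0, 0}, hi[3] = {0, 0, 0};
    bool first = true;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[3 * i]) || !std::isfinite(x[3 * i + 1]) ||
          !std::isfinite(x[3 * i + 2])) continue;
      for (int d = 0; d < 3; ++d) {
        if (first || x[3 * i + d] < lo[d]) lo[d] = x[3 * i + d];
        if (first || x[3 * i + d] > hi[d]) hi[d] = x[3 * i + d];
      }
      first = false;
    }
    int nc[3];
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, static_cast<int>((hi[d] - lo[d]) / rc));
      nc[d] = std::min(nc[d], 64);
    }
    double cw[3];
    for (int d = 0; d < 3; ++d) cw[d] = std::max((hi[d] - lo[d]) / nc[d], rc);
    int ncell = nc[0] * nc[1] * nc[2];
    // flat counting-sort cell layout (no per-rebuild allocations beyond these)
    cell_start.assign(ncell + 1, 0);
    cell_items.resize(n);
    cidx.resize(n);
    auto cell_of = [](double xi, double lo, double cw, int nc) {
      double t = (xi - lo) / cw;
      if (!(t >= 0.0)) t = 0.0;          // also catches NaN
      if (t > nc - 1) t = nc - 1;
      return static_cast<int>(t);
    };
    for (int i = 0; i < n; ++i) {
      int a = cell_of(x[3 * i], lo[0], cw[0], nc[0]);
      int b = cell_of(x[3 * i + 1], lo[1], cw[1], nc[1]);
      int c = cell_of(x[3 * i + 2], lo[2], cw[2], nc[2]);
      cidx[i] = (a * nc[1] + b) * nc[2] + c;
      ++cell_start[cidx[i] + 1];
    }
    for (int t = 0; t < ncell; ++t) cell_start[t + 1] += cell_start[t];
    {
      std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
      for (int i = 0; i < n; ++i) cell_items[fill[cidx[i]]++] = i;
    }
    // half neighborhood: same cell (j > i) plus 13 forward neighbor cells
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int a = 0; a < nc[0]; ++a)
      for (int b = 0; b < nc[1]; ++b)
        for (int c = 0; c < nc[2]; ++c) {
          int id = (a * nc[1] + b) * nc[2] + c;
          int s0 = cell_start[id], s1 = cell_start[id + 1];
          if (s0 == s1) continue;
          for (int u = s0; u < s1; ++u)
            for (int w = u + 1; w < s1; ++w) {
              int i = cell_items[u], j = cell_items[w];
              double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
                     dz = x[3 * i + 2] - x[3 * j + 2];
              if (dx * dx + dy * dy + dz * dz < rc2) consider(x, p, rc2dh, i, j);
            }
          for (int t = 0; t < 13; ++t) {
            int a2 = a + off[t][0], b2 = b + off[t][1], c2 = c + off[t][2];
            if (a2 < 0 || b2 < 0 || c2 < 0 || a2 >= nc[0] || b2 >= nc[1] ||
                c2 >= nc[2]) continue;
            int id2 = (a2 * nc[1] + b2) * nc[2] + c2;
            for (int u = cell_start[id2]; u < cell_start[id2 + 1]; ++u) {
              int j = cell_items[u];
              for (int w = s0; w < s1; ++w) {
                int i = cell_items[w];
                double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
                       dz = x[3 * i + 2] - x[3 * j + 2];
                if (dx * dx + dy * dy + dz * dz < rc2) consider(x, p, rc2dh, i, j);
              }
            }
          }
        }
  }

  bool stale(const std::vector<double>& x) const {
    const double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = x[i] - ref[i], dy = x[i + 1] - ref[i + 1], dz = x[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// Energy + force evaluation
// ---------------------------------------------------------------------------

struct Breakdown {
  double bond = 0, angle = 0, dihedral = 0, contact = 0, ev = 0, elec = 0, hbond = 0;
  double total() const { return bond + angle + dihedral + contact + ev + elec + hbond; }
};

// Gaussian modulation with C1 smooth cutoff at filt*s:
// g(d) = exp(-d^2/(2 s^2)) * S(|d|/s), S = 1 on [0, filt-1], smoothstep to 0 on
// [filt-1, filt]. Returns value; dg = derivative wrt d.
static inline double hb_gauss(double d, double s, double filt, double& dg) {
  double u = std::fabs(d) / s;
  if (u >= filt) { dg = 0.0; return 0.0; }
  double g = std::exp(-0.5 * d * d / (s * s));
  double dgauss = -d / (s * s) * g;
  double lo = filt - 1.0;
  if (u <= lo) { dg = dgauss; return g; }
  double t = u - lo;                  // in (0, 1)
  double S = 1.0 - (3.0 * t * t - 2.0 * t * t * t);
  double dS = -(6.0 * t - 6.0 * t * t) / s;   // d/du * du/d|d|
  if (d < 0) dS = -dS;
  dg = dgauss * S + g * dS;
  return g * S;
}

static void eval_all(const std::vector<double>& x, const Pot& p,
                     const NeighborList& nl, Breakdown& e,
                     std::vector<double>* f) {
  const int n = p.n;
  if (f) std::fill(f->begin(), f->end(), 0.0);

  // bonds
  for (size_t t = 0; t < p.b_i.size(); ++t) {
    int i = p.b_i[t], j = p.b_j[t];
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double r = norm3(d);
    double dr = r - p.b_r0[t];
    e.bond += p.b_k[t] * dr * dr;
    if (f && r > 1e-12) {
      double c = -2.0 * p.b_k[t] * dr / r;
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * i + d3] += c * d[d3];
        (*f)[3 * j + d3] -= c * d[d3];
      }
    }
  }

  // angles (harmonic in theta; force prefactor vanishes as theta -> theta0)
  for (size_t t = 0; t < p.a_i.size(); ++t) {
    int i = p.a_i[t], j = p.a_j[t], k = p.a_k[t];
    double rij[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
    double rkj[3] = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1],
                     x[3 * k + 2] - x[3 * j + 2]};
    double nij = norm3(rij), nkj = norm3(rkj);
    if (nij < 1e-12 || nkj < 1e-12) continue;
    double c = dot3(rij, rkj) / (nij * nkj);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - p.a_t0[t];
    e.angle += p.a_kt[t] * dth * dth;
    if (f) {
      double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
      double pref = -2.0 * p.a_kt[t] * dth;  // -dU/dtheta
      double gi[3], gk[3];
      for (int d3 = 0; d3 < 3; ++d3) {
        gi[d3] = (c * rij[d3] / nij - rkj[d3] / nkj) / (nij * s);
        gk[d3] = (c * rkj[d3] / nkj - rij[d3] / nij) / (nkj * s);
      }
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * i + d3] += pref * gi[d3];
        (*f)[3 * k + d3] += pref * gk[d3];
        (*f)[3 * j + d3] -= pref * (gi[d3] + gk[d3]);
      }
    }
  }

  // dihedrals: U = k (1 - cos(m (phi - phi0))) * f(s1^2) * f(s3^2), where
  // s1, s3 are the sines of the two inner bending angles and f(u) = u/(u+eps)
  // smoothly switches the term off as the geometry degenerates (the dihedral
  // is undefined at collinearity); forces are the exact gradient of this
  // damped energy, so they stay bounded everywhere.
  const double dih_eps = 0.02;
  for (size_t t = 0; t < p.d_i.size(); ++t) {
    int i = p.d_i[t], j = p.d_j[t], k = p.d_k[t], l = p.d_l[t];
    double b1[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                    x[3 * j + 2] - x[3 * i + 2]};
    double b2[3] = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1],
                    x[3 * k + 2] - x[3 * j + 2]};
    double b3[3] = {x[3 * l] - x[3 * k], x[3 * l + 1] - x[3 * k + 1],
                    x[3 * l + 2] - x[3 * k + 2]};
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double b1sq = dot3(b1, b1), b2sq = dot3(b2, b2), b3sq = dot3(b3, b3);
    double nb2 = std::sqrt(b2sq), n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    if (nb2 < 1e-10 || n1sq < 1e-16 || n2sq < 1e-16) continue;
    double s1sq = n1sq / (b1sq * b2sq);   // sin^2 of angle(i,j,k)
    double s3sq = n2sq / (b2sq * b3sq);   // sin^2 of angle(j,k,l)
    double f1 = s1sq / (s1sq + dih_eps), f3 = s3sq / (s3sq + dih_eps);
    double phi = std::atan2(nb2 * dot3(b1, n2), dot3(n1, n2));
    double dphi = p.d_m[t] * (phi - p.d_p0[t]);
    double u = p.d_kp[t] * (1.0 - std::cos(dphi));
    e.dihedral += u * f1 * f3;
    if (f) {
      // phi-gradient part
      double pref = -p.d_kp[t] * p.d_m[t] * std::sin(dphi) * f1 * f3;
      double gi[3], gl[3], gj[3], gk3[3];
      for (int d3 = 0; d3 < 3; ++d3) {
        gi[d3] = -nb2 / n1sq * n1[d3];
        gl[d3] = nb2 / n2sq * n2[d3];
      }
      double c12 = dot3(b1, b2) / b2sq, c32 = dot3(b3, b2) / b2sq;
      for (int d3 = 0; d3 < 3; ++d3) {
        gj[d3] = -(1.0 + c12) * gi[d3] + c32 * gl[d3];
        gk3[d3] = c12 * gi[d3] - (1.0 + c32) * gl[d3];
      }
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * i + d3] += pref * gi[d3];
        (*f)[3 * j + d3] += pref * gj[d3];
        (*f)[3 * k + d3] += pref * gk3[d3];
        (*f)[3 * l + d3] += pref * gl[d3];
      }
      // damping-gradient part: -u * d(f1 f3)/dx
      double df1 = dih_eps / ((s1sq + dih_eps) * (s1sq + dih_eps));
      double df3 = dih_eps / ((s3sq + dih_eps) * (s3sq + dih_eps));
      double w1 = u * f3 * df1;  // force -= w1 * grad(s1sq)
      double w3 = u * f1 * df3;  // force -= w3 * grad(s3sq)
      // grad s1sq = [grad n1sq - s1sq (b2sq grad b1sq + b1sq grad b2sq)]
      //             / (b1sq b2sq); cross-product identities give grad n1sq
      double b2xn1[3], n1xb1[3], b3xn2[3], n2xb2[3];
      cross3(b2, n1, b2xn1);
      cross3(n1, b1, n1xb1);
      cross3(b3, n2, b3xn2);
      cross3(n2, b2, n2xb2);
      double inv12 = 1.0 / (b1sq * b2sq), inv23 = 1.0 / (b2sq * b3sq);
      for (int d3 = 0; d3 < 3; ++d3) {
        // s1sq gradients (atoms i, j, k)
        double gn_i = -2.0 * b2xn1[d3];
        double gn_j = 2.0 * b2xn1[d3] - 2.0 * n1xb1[d3];
        double gn_k = 2.0 * n1xb1[d3];
        double gb1_i = -2.0 * b1[d3], gb1_j = 2.0 * b1[d3];
        double gb2_j = -2.0 * b2[d3], gb2_k = 2.0 * b2[d3];
        double gs1_i = (gn_i - s1sq * b2sq * gb1_i) * inv12;
        double gs1_j = (gn_j - s1sq * (b2sq * gb1_j + b1sq * gb2_j)) * inv12;
        double gs1_k = (gn_k - s1sq * b1sq * gb2_k) * inv12;
        (*f)[3 * i + d3] -= w1 * gs1_i;
        (*f)[3 * j + d3] -= w1 * gs1_j;
        (*f)[3 * k + d3] -= w1 * gs1_k;
        // s3sq gradients (atoms j, k, l) with b2 <-> b1 roles: n2 = b2 x b3
        double hn_j = -2.0 * b3xn2[d3];
        double hn_k = 2.0 * b3xn2[d3] - 2.0 * n2xb2[d3];
        double hn_l = 2.0 * n2xb2[d3];
        double hb2_j = -2.0 * b2[d3], hb2_k = 2.0 * b2[d3];
        double hb3_k = -2.0 * b3[d3], hb3_l = 2.0 * b3[d3];
        double gs3_j = (hn_j - s3sq * b3sq * hb2_j) * inv23;
        double gs3_k = (hn_k - s3sq * (b3sq * hb2_k + b2sq * hb3_k)) * inv23;
        double gs3_l = (hn_l - s3sq * b2sq * hb3_l) * inv23;
        (*f)[3 * j + d3] -= w3 * gs3_j;
        (*f)[3 * k + d3] -= w3 * gs3_k;
        (*f)[3 * l + d3] -= w3 * gs3_l;
      }
    }
  }

  // native contacts 12-10
  for (size_t t = 0; t < p.c_i.size(); ++t) {
    int i = p.c_i[t], j = p.c_j[t];
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double r2c = dot3(d, d);
    if (r2c < 1e-24) continue;
    double r = std::sqrt(r2c);
    double q2 = p.c_r0[t] * p.c_r0[t] / r2c;
    double s10 = q2 * q2 * q2 * q2 * q2, s12 = s10 * q2;
    e.contact += p.c_eps[t] * (5.0 * s12 - 6.0 * s10);
    if (f) {
      double dU = 60.0 * p.c_eps[t] * (s10 - s12) / r;  // dU/dr
      double c = -dU / r;
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * i + d3] += c * d[d3];
        (*f)[3 * j + d3] -= c * d[d3];
      }
    }
  }

  // nonbonded: excluded volume (12, shifted) and Debye-Huckel (shifted) on
  // their dedicated pair lists
  const double inv_l = 1.0 / p.lambda;
  const double ev_shift = std::pow(1.0 / p.ev_factor, 12);
  const double fdh_cut = std::exp(-p.dh_cut * inv_l) / p.dh_cut;
  for (size_t t = 0; t < nl.pi.size(); ++t) {
    int i = nl.pi[t], j = nl.pj[t];
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double r2 = dot3(d, d);
    if (r2 >= nl.prcv2[t]) continue;
    double sij = 0.5 * (p.sigma[i] + p.sigma[j]);
    double s2 = sij * sij / r2;
    double sr6 = s2 * s2 * s2, sr12 = sr6 * sr6;
    double r = std::sqrt(r2);
    e.ev += p.eps_ev * (sr12 - ev_shift);
    if (f) {
      double c = 12.0 * p.eps_ev * sr12 / r2;
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * i + d3] += c * d[d3];
        (*f)[3 * j + d3] -= c * d[d3];
      }
    }
  }
  for (size_t t = 0; t < nl.qi.size(); ++t) {
    int i = nl.qi[t], j = nl.qj[t];
    double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                   x[3 * i + 2] - x[3 * j + 2]};
    double r2 = dot3(d, d);
    if (r2 >= p.dh_cut * p.dh_cut) continue;
    double qq = (p.isdna[i] != p.isdna[j]) ? p.qpd[i] * p.qpd[j]
                                           : p.q[i] * p.q[j];
    double r = std::sqrt(r2);
    double ex = std::exp(-r * inv_l);
    e.elec += p.kpre * qq * (ex / r - fdh_cut);
    if (f) {
      double c = p.kpre * qq * ex * (inv_l / r + 1.0 / r2) / r;
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * i + d3] += c * d[d3];
        (*f)[3 * j + d3] -= c * d[d3];
      }
    }
  }

  // hydrogen bonds: U = -eps * G(r) * G(theta) * G(phi)
  if (p.has_hb) {
    const double rwin = p.hb_r0 + p.hb_filt * p.hb_sr;
    for (size_t t = 0; t < p.h_don.size(); ++t) {
      int ip = p.h_prev[t], id = p.h_don[t], iph = p.h_p[t], is = p.h_s[t];
      double dv[3] = {x[3 * iph] - x[3 * id], x[3 * iph + 1] - x[3 * id + 1],
                      x[3 * iph + 2] - x[3 * id + 2]};
      double r2 = dot3(dv, dv);
      if (r2 > rwin * rwin) continue;
      double r = std::sqrt(r2);
      if (r < p.hb_r0 - p.hb_filt * p.hb_sr) continue;
      double dgr;
      double gr = hb_gauss(r - p.hb_r0, p.hb_sr, p.hb_filt, dgr);
      if (gr == 0.0) continue;

      // theta: angle prev - donor - phosphate (vertex donor), handled in
      // cosine space so gradients stay finite at collinear geometries
      double rij[3] = {x[3 * ip] - x[3 * id], x[3 * ip + 1] - x[3 * id + 1],
                       x[3 * ip + 2] - x[3 * id + 2]};
      double nij = norm3(rij);
      if (nij < 1e-10) continue;
      double cth = dot3(rij, dv) / (nij * r);
      cth = std::max(-1.0, std::min(1.0, cth));
      double dgt;
      double gt = hb_gauss(cth - p.hb_ct0, p.hb_sc, p.hb_filt, dgt);
      if (gt == 0.0) continue;

      double gp = 1.0, dgp = 0.0;
      double b1[3], b2[3], b3[3], n1[3], n2[3];
      double nb2 = 0, n1sq = 0, n2sq = 0;
      if (p.hb_has_phi) {
        // phi: dihedral prev - donor - phosphate - sugar
        for (int d3 = 0; d3 < 3; ++d3) {
          b1[d3] = x[3 * id + d3] - x[3 * ip + d3];
          b2[d3] = dv[d3];
          b3[d3] = x[3 * is + d3] - x[3 * iph + d3];
        }
        cross3(b1, b2, n1);
        cross3(b2, b3, n2);
        nb2 = norm3(b2); n1sq = dot3(n1, n1); n2sq = dot3(n2, n2);
        if (n1sq < 1e-14 || n2sq < 1e-14 || nb2 < 1e-10) continue;
        double phi = std::atan2(nb2 * dot3(b1, n2), dot3(n1, n2));
        double dphi = phi - p.hb_p0;
        while (dphi > M_PI) dphi -= 2.0 * M_PI;
        while (dphi < -M_PI) dphi += 2.0 * M_PI;
        gp = hb_gauss(dphi, p.hb_sp, p.hb_filt, dgp);
        if (gp == 0.0) continue;
      }

      e.hbond += -p.hb_eps * gr * gt * gp;
      if (!f) continue;

      // r part
      double dUdr = -p.hb_eps * dgr * gt * gp;
      double cr = -dUdr / r;
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * iph + d3] += cr * dv[d3];
        (*f)[3 * id + d3] -= cr * dv[d3];
      }
      // theta part: gradient of cos(theta)
      double dUdc = -p.hb_eps * gr * dgt * gp;
      double gi[3], gk[3];
      for (int d3 = 0; d3 < 3; ++d3) {
        double u1 = rij[d3] / nij, u2 = dv[d3] / r;
        gi[d3] = (u2 - cth * u1) / nij;   // d cth / d r_prev
        gk[d3] = (u1 - cth * u2) / r;     // d cth / d r_P
      }
      for (int d3 = 0; d3 < 3; ++d3) {
        (*f)[3 * ip + d3] -= dUdc * gi[d3];
        (*f)[3 * iph + d3] -= dUdc * gk[d3];
        (*f)[3 * id + d3] += dUdc * (gi[d3] + gk[d3]);
      }
      // phi part
      if (p.hb_has_phi) {
        double dUdp = -p.hb_eps * gr * gt * dgp;
        double hgi[3], hgl[3], hgj[3], hgk[3];
        for (int d3 = 0; d3 < 3; ++d3) {
          hgi[d3] = -nb2 / n1sq * n1[d3];
          hgl[d3] = nb2 / n2sq * n2[d3];
        }
        double c12 = dot3(b1, b2) / (nb2 * nb2), c32 = dot3(b3, b2) / (nb2 * nb2);
        for (int d3 = 0; d3 < 3; ++d3) {
          hgj[d3] = -(1.0 + c12) * hgi[d3] + c32 * hgl[d3];
          hgk[d3] = c12 * hgi[d3] - (1.0 + c32) * hgl[d3];
        }
        for (int d3 = 0; d3 < 3; ++d3) {
          (*f)[3 * ip + d3] -= dUdp * hgi[d3];
          (*f)[3 * id + d3] -= dUdp * hgj[d3];
          (*f)[3 * iph + d3] -= dUdp * hgk[d3];
          (*f)[3 * is + d3] -= dUdp * hgl[d3];
        }
      }
    }
  }
}

static std::vector<double> coords_to_vec(const NumericMatrix& m) {
  int n = m.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = m(i, d);
  return x;
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix coords, List pot) {
  Pot p = parse_pot(pot);
  std::vector<double> x = coords_to_vec(coords);
  NeighborList nl;
  nl.build(x, p);
  Breakdown e;
  eval_all(x, p, nl, e, nullptr);
  return List::create(_["bond"] = e.bond, _["angle"] = e.angle,
                      _["dihedral"] = e.dihedral, _["native_contact"] = e.contact,
                      _["excluded_volume"] = e.ev, _["electrostatic"] = e.elec,
                      _["hbond"] = e.hbond, _["total"] = e.total());
}

// [[Rcpp::export]]
NumericMatrix cg_forces_cpp(NumericMatrix coords, List pot) {
  Pot p = parse_pot(pot);
  std::vector<double> x = coords_to_vec(coords);
  NeighborList nl;
  nl.build(x, p);
  Breakdown e;
  std::vector<double> f(3 * p.n);
  eval_all(x, p, nl, e, &f);
  NumericMatrix out(p.n, 3);
  for (int i = 0; i < p.n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = f[3 * i + d];
  return out;
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator
// ---------------------------------------------------------------------------

static inline void clamp_vel(std::vector<double>& v, double vmax) {
  for (size_t i = 0; i < v.size(); i += 3) {
    double s2 = v[i] * v[i] + v[i + 1] * v[i + 1] + v[i + 2] * v[i + 2];
    if (s2 > vmax * vmax) {
      double sc = vmax / std::sqrt(s2);
      v[i] *= sc; v[i + 1] *= sc; v[i + 2] *= sc;
    }
  }
}

// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix coords, NumericMatrix vel, List pot,
                int n_steps, double dt, double gamma, NumericVector mass,
                double kT, double seed, int stride, bool store_initial) {
  Pot p = parse_pot(pot);
  const int n = p.n;
  std::vector<double> x = coords_to_vec(coords);
  std::vector<double> v = coords_to_vec(vel);
  std::vector<double> m(mass.begin(), mass.end());
  std::vector<double> f(3 * n, 0.0);

  FastRng rng(static_cast<uint64_t>(seed));

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double vmax = 2.0 / dt;  // <= 1 A displacement per half step

  NeighborList nl;
  nl.build(x, p);
  Breakdown e;
  eval_all(x, p, nl, e, &f);

  int n_frames = n_steps / stride + (store_initial ? 1 : 0);
  NumericVector frames(Dimension(n, 3, n_frames));
  IntegerVector frame_steps(n_frames);
  int fidx = 0;
  if (store_initial) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) frames[i + n * d + 3 * n * fidx] = x[3 * i + d];
    frame_steps[fidx++] = 0;
  }

  bool blown = false;
  int blow_step = -1;
  double ke_sum = 0.0;
  long ke_n = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m[i];
      v[3 * i] += h * f[3 * i];
      v[3 * i + 1] += h * f[3 * i + 1];
      v[3 * i + 2] += h * f[3 * i + 2];
    }
    // A (with a per-bead displacement limiter: inert in healthy dynamics,
    // prevents numerical runaway of pathological stiff-pair encounters)
    clamp_vel(v, vmax);
    for (size_t i = 0; i < x.size(); ++i) x[i] += 0.5 * dt * v[i];
    // O
    for (int i = 0; i < n; ++i) {
      double sd = c2 * std::sqrt(kT / m[i]);
      v[3 * i] = c1 * v[3 * i] + sd * rng.normal();
      v[3 * i + 1] = c1 * v[3 * i + 1] + sd * rng.normal();
      v[3 * i + 2] = c1 * v[3 * i + 2] + sd * rng.normal();
    }
    // A
    clamp_vel(v, vmax);
    for (size_t i = 0; i < x.size(); ++i) x[i] += 0.5 * dt * v[i];
    // force (the displacement check runs every few steps; the skin pad is
    // twice the rebuild trigger, so typical per-step motion cannot outrun it)
    if ((step & 3) == 0 && nl.stale(x)) nl.build(x, p);
    eval_all(x, p, nl, e, &f);
    // B
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m[i];
      v[3 * i] += h * f[3 * i];
      v[3 * i + 1] += h * f[3 * i + 1];
      v[3 * i + 2] += h * f[3 * i + 2];
    }

    if ((step & 3) == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        ke += 0.5 * m[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                            v[3 * i + 2] * v[3 * i + 2]);
      }
      ke_sum += ke;
      ++ke_n;
    }
    if (step % 25 == 0 || step == n_steps) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6 ||
            !std::isfinite(v[i])) { blown = true; break; }
      if (blown) { blow_step = step; break; }
    }
    if (step % stride == 0 && fidx < n_frames) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) frames[i + n * d + 3 * n * fidx] = x[3 * i + d];
      frame_steps[fidx++] = step;
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xf(i, d) = x[3 * i + d];
      vf(i, d) = v[3 * i + d];
    }
  if (fidx < n_frames) {
    // truncated run: shrink frame bookkeeping
    frame_steps = head(frame_steps, fidx);
  }
  double mean_ke_dof = ke_n > 0 ? ke_sum / (static_cast<double>(ke_n) * 3 * n)
                                : NA_REAL;
  return List::create(_["frames"] = frames, _["frame_steps"] = frame_steps,
                      _["n_frames"] = fidx, _["coords"] = xf, _["vel"] = vf,
                      _["blown"] = blown, _["blow_step"] = blow_step,
                      _["mean_ke_per_dof"] = mean_ke_dof);
}

// ---------------------------------------------------------------------------
// Analysis kernels
// ---------------------------------------------------------------------------

// Per-frame protein-domain / DNA-bp contacts: bp b contacts domain D iff any
// bead of bp b is strictly within cutoff of any bead of D.
// prot_dom: domain id (1..ndom) per protein bead. Returns ndom x n_bp logical.
// [[Rcpp::export]]
LogicalMatrix cg_contacts_frame(NumericMatrix coords, IntegerVector prot_idx,
                                IntegerVector prot_dom, IntegerVector dna_idx,
                                IntegerVector dna_bp, int ndom, int n_bp,
                                double cutoff) {
  LogicalMatrix out(ndom, n_bp);
  const double c2 = cutoff * cutoff;
  const int np = prot_idx.size(), nd = dna_idx.size();
  for (int a = 0; a < np; ++a) {
    int i = prot_idx[a] - 1, dom = prot_dom[a] - 1;
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int b = 0; b < nd; ++b) {
      int j = dna_idx[b] - 1, bp = dna_bp[b] - 1;
      if (out(dom, bp)) continue;
      double dx = xi - coords(j, 0), dy = yi - coords(j, 1), dz = zi - coords(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) out(dom, bp) = true;
    }
  }
  return out;
}

// Count crossings of a polyline through a triangulated surface.
// pts: (m x 3) polyline vertices; tri: (nt x 9) triangle vertex coordinates.
// Returns total intersection count (Moller-Trumbore, segment version).
// [[Rcpp::export]]
int cg_polyline_crossings(NumericMatrix pts, NumericMatrix tri) {
  int count = 0;
  const int m = pts.nrow(), nt = tri.nrow();
  for (int s = 0; s + 1 < m; ++s) {
    double o[3] = {pts(s, 0), pts(s, 1), pts(s, 2)};
    double d[3] = {pts(s + 1, 0) - o[0], pts(s + 1, 1) - o[1], pts(s + 1, 2) - o[2]};
    for (int t = 0; t < nt; ++t) {
      double v0[3] = {tri(t, 0), tri(t, 1), tri(t, 2)};
      double e1[3] = {tri(t, 3) - v0[0], tri(t, 4) - v0[1], tri(t, 5) - v0[2]};
      double e2[3] = {tri(t, 6) - v0[0], tri(t, 7) - v0[1], tri(t, 8) - v0[2]};
      double pv[3];
      cross3(d, e2, pv);
      double det = dot3(e1, pv);
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      double tv[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
      double u = dot3(tv, pv) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qv[3];
      cross3(tv, e1, qv);
      double vv = dot3(d, qv) * inv;
      if (vv < 0.0 || u + vv > 1.0) continue;
      double tt = dot3(e2, qv) * inv;
      if (tt >= 0.0 && tt < 1.0) ++count;
    }
  }
  return count;
}
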