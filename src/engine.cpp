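// Production kernels: cell-list short-range forces and the Langevin
// velocity-Verlet loop.  All quantities are in reduced units (lengths in the
// monomer diameter a, energies in eps, time in tau0 = a*sqrt(m/eps)).
//
// Species codes: 0 = monomer, 1 = crowder, 2 = wall-forming bead (static).
// Pair parameters are indexed by si*3+sj over the full 3x3 table.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++, Box-Muller normals with caching.
// Self-contained so that a run is bit-reproducible from its integer seed
// regardless of R's RNG state.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  bool have_cached;
  double cached;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) : have_cached(false), cached(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    // avoid the all-zero state (cannot happen with splitmix64, but cheap)
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
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

  inline double unif() {  // in (0, 1]
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }

  inline double normal() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    have_cached = true;
    return r * std::cos(a);
  }
};

// Marsaglia-Tsang ziggurat for standard normals (128 layers), driven by the
// xoshiro stream.  ~3x faster than Box-Muller in the thermostat loop.
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;  // 2^31: hz spans the signed 32-bit range
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  inline double draw(Xoshiro &rng) {
    const double r_tail = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(rng.next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < kn[iz]) return hz * wn[iz];
      if (iz == 0) {  // tail
        double xx, yy;
        do {
          xx = -std::log(rng.unif()) / r_tail;
          yy = -std::log(rng.unif());
        } while (yy + yy < xx * xx);
        return hz > 0 ? r_tail + xx : -(r_tail + xx);
      }
      double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
// Model parameters
// ---------------------------------------------------------------------------

struct Model {
  int n;            // total particles (mobile + static wall beads)
  int n_mobile;     // first n_mobile particles are integrated
  int n_mono;       // monomers are particles 0..n_mono-1
  int n_ring;       // ring length for FENE bonds (0 = no bonds)
  // pair WCA, indexed si*3+sj
  double sig2[9], cut2[9], eps4[9];
  double max_cut_mono;   // largest cutoff for pairs not involving crowders
  double max_cut_cross;  // largest monomer/wall - crowder cutoff
  double cut_cc;         // crowder-crowder cutoff
  // FENE
  double fene_k, fene_r02;
  // dynamics
  double dt, gamma, kT;
  double mass[3];
  // geometry
  double radius;    // D/2
  double length;    // L
  bool periodic;    // longitudinal periodic boundary (else capped)
  bool smooth_wall; // analytic barrel wall (else wall beads provide it)
  double wall_sig[2], wall_eps[2]; // per mobile species
};

static Model model_from_list(const List &par) {
  Model m;
  m.n_mono   = as<int>(par["n_mono"]);
  m.n_ring   = as<int>(par["n_ring"]);
  m.n_mobile = as<int>(par["n_mobile"]);
  m.n        = as<int>(par["n"]);
  NumericVector sig = par["sigma"];   // 3x3 column-major
  NumericVector eps = par["epsilon"];
  const double rc = std::pow(2.0, 1.0 / 6.0);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = sig[i + 3 * j];
      int k = i * 3 + j;
      m.sig2[k] = s * s;
      double c = rc * s;
      m.cut2[k] = c * c;
      m.eps4[k] = 4.0 * eps[i + 3 * j];
    }
  m.max_cut_mono  = std::sqrt(std::max(m.cut2[0], std::max(m.cut2[2 * 3 + 0], m.cut2[2 * 3 + 2])));
  m.max_cut_cross = std::sqrt(std::max(m.cut2[1], m.cut2[1 * 3 + 2]));
  m.cut_cc        = std::sqrt(m.cut2[1 * 3 + 1]);
  m.fene_k   = as<double>(par["fene_k"]);
  double r0  = as<double>(par["fene_r0"]);
  m.fene_r02 = r0 * r0;
  m.dt    = as<double>(par["dt"]);
  m.gamma = as<double>(par["gamma"]);
  m.kT    = as<double>(par["kT"]);
  NumericVector mass = par["mass"];
  m.mass[0] = mass[0]; m.mass[1] = mass[1]; m.mass[2] = mass.size() > 2 ? mass[2] : mass[0];
  m.radius = as<double>(par["radius"]);
  m.length = as<double>(par["length"]);
  m.periodic = as<bool>(par["periodic"]);
  m.smooth_wall = as<bool>(par["smooth_wall"]);
  NumericVector ws = par["wall_sigma"], we = par["wall_epsilon"];
  m.wall_sig[0] = ws[0]; m.wall_sig[1] = ws.size() > 1 ? ws[1] : ws[0];
  m.wall_eps[0] = we[0]; m.wall_eps[1] = we.size() > 1 ? we[1] : we[0];
  return m;
}

// WCA pair force/energy.  Returns energy, adds force on i (fi += f * dr where
// dr = ri - rj).
static inline double wca_pair(double r2, double sig2, double cut2, double eps4,
                              double &fscale) {
  if (r2 >= cut2) { fscale = 0.0; return 0.0; }
  double s2 = sig2 / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  fscale = 6.0 * eps4 * (2.0 * s12 - s6) / r2;  // (24 eps / r^2) (2 s12 - s6)
  return eps4 * (s12 - s6 + 0.25);
}

// ---------------------------------------------------------------------------
// Cell grid (linked cells).  z may be periodic; x and y are clamped.
// ---------------------------------------------------------------------------

struct Grid {
  int nx, ny, nz;
  double x0, y0, z0, icx, icy, icz;
  bool zper;
  std::vector<int> head, nxt;

  void setup(double W, double zlo, double zhi, double cell, bool zperiodic,
             int nmax) {
    x0 = -W; y0 = -W; z0 = zlo;
    nx = std::max(1, (int)std::floor(2.0 * W / cell));
    ny = nx;
    double Lz = zhi - zlo;
    nz = std::max(1, (int)std::floor(Lz / cell));
    icx = nx / (2.0 * W); icy = icx; icz = nz / Lz;
    zper = zperiodic;
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(nmax, -1);
  }

  inline int clampi(int v, int n) const { return v < 0 ? 0 : (v >= n ? n - 1 : v); }

  inline void cell_of(double x, double y, double z, int &ix, int &iy, int &iz) const {
    ix = clampi((int)((x - x0) * icx), nx);
    iy = clampi((int)((y - y0) * icy), ny);
    iz = (int)((z - z0) * icz);
    if (zper) { iz %= nz; if (iz < 0) iz += nz; } else iz = clampi(iz, nz);
  }

  inline int lin(int ix, int iy, int iz) const {
    return ix + nx * (iy + ny * iz);
  }

  void insert(int i, double x, double y, double z) {
    int ix, iy, iz; cell_of(x, y, z, ix, iy, iz);
    int c = lin(ix, iy, iz);
    nxt[i] = head[c];
    head[c] = i;
  }

  void clear() { std::fill(head.begin(), head.end(), -1); }
};

// ---------------------------------------------------------------------------
// Force evaluation.  Positions in x/y/z arrays; forces accumulated into
// fx/fy/fz (zeroed here).  Returns energies; on failure sets *fail_msg.
// ---------------------------------------------------------------------------

struct Energies { double pair, bond, wall; };

struct ForceWork {
  Grid gm;   // monomers + wall beads
  Grid gc;   // crowders
  std::vector<int> set_m, set_c;
  bool sets_ready = false;
  // Verlet neighbor list over all pair classes, rebuilt when any particle
  // has moved more than half the skin since the last build
  std::vector<int> plist;            // flattened (i, j) pairs
  std::vector<double> xr, yr, zr;    // positions at last rebuild
  bool list_ready = false;
  double skin = 0.15;
};

static inline double min_image(double dz, double L, bool periodic) {
  if (!periodic) return dz;
  if (dz >  0.5 * L) return dz - L;
  if (dz < -0.5 * L) return dz + L;
  return dz;
}

// returns false on bond overstretch / wall escape, with message in msg
// Collect every candidate pair within (cutoff + skin) into w.plist via
// linked-cell grids, and remember the build positions for the displacement
// trigger.  The list is reused across steps until some mobile particle has
// moved more than skin/2.
static void build_pair_list(const Model &m, ForceWork &w,
                            const double *x, const double *y, const double *z,
                            const int *sp) {
  const int n = m.n;
  if (!w.sets_ready) {
    w.set_m.clear(); w.set_c.clear();
    for (int i = 0; i < n; ++i) (sp[i] == 1 ? w.set_c : w.set_m).push_back(i);
    w.sets_ready = true;
  }
  w.plist.clear();
  double keep2[9];
  for (int k = 0; k < 9; ++k) {
    double c = std::sqrt(m.cut2[k]) + w.skin;
    keep2[k] = c * c;
  }
  auto consider = [&](int i, int j) {
    if (i >= m.n_mobile && j >= m.n_mobile) return;  // static-static
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double dz = min_image(z[i] - z[j], m.length, m.periodic);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < keep2[sp[i] * 3 + sp[j]]) {
      w.plist.push_back(i);
      w.plist.push_back(j);
    }
  };
  const double W = m.radius + 1.5;
  double zlo = 0.0, zhi = m.length;
  if (!m.periodic) { zlo = -1.0; zhi = m.length + 1.0; }

  // monomer/wall set: grid when the box is large enough, else all pairs
  const std::vector<int> &S = w.set_m;
  const int nm = (int)S.size();
  {
    double cell = m.max_cut_mono + w.skin;
    int nzc = (int)std::floor((zhi - zlo) / cell);
    if (nm > 64 && nzc >= 3) {
      w.gm.setup(W, zlo, zhi, cell, m.periodic, n);
      for (int k = 0; k < nm; ++k) {
        int i = S[k];
        w.gm.insert(i, x[i], y[i], z[i]);
      }
      for (int ci = 0; ci < (int)w.gm.head.size(); ++ci) {
        if (w.gm.head[ci] < 0) continue;
        int izc = ci / (w.gm.nx * w.gm.ny);
        int rem = ci % (w.gm.nx * w.gm.ny);
        int iyc = rem / w.gm.nx, ixc = rem % w.gm.nx;
        for (int i = w.gm.head[ci]; i >= 0; i = w.gm.nxt[i]) {
          for (int j = w.gm.nxt[i]; j >= 0; j = w.gm.nxt[j]) consider(i, j);
          for (int dz1 = -1; dz1 <= 1; ++dz1) {
            int iz2 = izc + dz1;
            if (w.gm.zper) { iz2 = (iz2 + w.gm.nz) % w.gm.nz; }
            else if (iz2 < 0 || iz2 >= w.gm.nz) continue;
            for (int dy1 = -1; dy1 <= 1; ++dy1) {
              int iy2 = iyc + dy1;
              if (iy2 < 0 || iy2 >= w.gm.ny) continue;
              for (int dx1 = -1; dx1 <= 1; ++dx1) {
                int ix2 = ixc + dx1;
                if (ix2 < 0 || ix2 >= w.gm.nx) continue;
                int cj = w.gm.lin(ix2, iy2, iz2);
                if (cj <= ci) continue;
                for (int j = w.gm.head[cj]; j >= 0; j = w.gm.nxt[j])
                  consider(i, j);
              }
            }
          }
        }
      }
    } else {
      for (int a = 0; a < nm; ++a)
        for (int b = a + 1; b < nm; ++b) consider(S[a], S[b]);
    }
  }

  // crowders: fine grid for c-c, searched with a wider stencil for the
  // monomer-crowder and wallbead-crowder classes
  const std::vector<int> &C = w.set_c;
  const int nc = (int)C.size();
  if (nc > 0) {
    double cell = m.cut_cc + w.skin;
    double cross = m.max_cut_cross + w.skin;
    int nzc = (int)std::floor((zhi - zlo) / cell);
    if (nc > 64 && nzc >= 3) {
      w.gc.setup(W, zlo, zhi, cell, m.periodic, n);
      for (int k = 0; k < nc; ++k) {
        int i = C[k];
        w.gc.insert(i, x[i], y[i], z[i]);
      }
      for (int ci = 0; ci < (int)w.gc.head.size(); ++ci) {
        if (w.gc.head[ci] < 0) continue;
        int izc = ci / (w.gc.nx * w.gc.ny);
        int rem = ci % (w.gc.nx * w.gc.ny);
        int iyc = rem / w.gc.nx, ixc = rem % w.gc.nx;
        for (int i = w.gc.head[ci]; i >= 0; i = w.gc.nxt[i]) {
          for (int j = w.gc.nxt[i]; j >= 0; j = w.gc.nxt[j]) consider(i, j);
          for (int dz1 = -1; dz1 <= 1; ++dz1) {
            int iz2 = izc + dz1;
            if (w.gc.zper) { iz2 = (iz2 + w.gc.nz) % w.gc.nz; }
            else if (iz2 < 0 || iz2 >= w.gc.nz) continue;
            for (int dy1 = -1; dy1 <= 1; ++dy1) {
              int iy2 = iyc + dy1;
              if (iy2 < 0 || iy2 >= w.gc.ny) continue;
              for (int dx1 = -1; dx1 <= 1; ++dx1) {
                int ix2 = ixc + dx1;
                if (ix2 < 0 || ix2 >= w.gc.nx) continue;
                int cj = w.gc.lin(ix2, iy2, iz2);
                if (cj <= ci) continue;
                for (int j = w.gc.head[cj]; j >= 0; j = w.gc.nxt[j])
                  consider(i, j);
              }
            }
          }
        }
      }
      int rx = (int)std::ceil(cross * w.gc.icx);
      int ry = (int)std::ceil(cross * w.gc.icy);
      int rz = (int)std::ceil(cross * w.gc.icz);
      for (int a = 0; a < nm; ++a) {
        int i = S[a];
        int ix, iy, iz;
        w.gc.cell_of(x[i], y[i], z[i], ix, iy, iz);
        for (int dz1 = -rz; dz1 <= rz; ++dz1) {
          int iz2 = iz + dz1;
          if (w.gc.zper) { iz2 = ((iz2 % w.gc.nz) + w.gc.nz) % w.gc.nz; }
          else if (iz2 < 0 || iz2 >= w.gc.nz) continue;
          for (int dy1 = -ry; dy1 <= ry; ++dy1) {
            int iy2 = iy + dy1;
            if (iy2 < 0 || iy2 >= w.gc.ny) continue;
            for (int dx1 = -rx; dx1 <= rx; ++dx1) {
              int ix2 = ix + dx1;
              if (ix2 < 0 || ix2 >= w.gc.nx) continue;
              int cj = w.gc.lin(ix2, iy2, iz2);
              for (int j = w.gc.head[cj]; j >= 0; j = w.gc.nxt[j])
                consider(i, j);
            }
          }
        }
      }
    } else {
      for (int a = 0; a < nc; ++a)
        for (int b = a + 1; b < nc; ++b) consider(C[a], C[b]);
      for (int a = 0; a < nm; ++a)
        for (int b = 0; b < nc; ++b) consider(S[a], C[b]);
    }
  }

  w.xr.assign(x, x + n);
  w.yr.assign(y, y + n);
  w.zr.assign(z, z + n);
  w.list_ready = true;
}

static bool need_rebuild(const Model &m, const ForceWork &w,
                         const double *x, const double *y, const double *z) {
  if (!w.list_ready) return true;
  const double lim2 = 0.25 * w.skin * w.skin;
  for (int i = 0; i < m.n_mobile; ++i) {
    double dx = x[i] - w.xr[i], dy = y[i] - w.yr[i];
    double dz = min_image(z[i] - w.zr[i], m.length, m.periodic);
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

static bool compute_forces_core(const Model &m, ForceWork &w,
                                const double *x, const double *y, const double *z,
                                const int *sp,
                                double *fx, double *fy, double *fz,
                                Energies &en, std::string &msg) {
  const int n = m.n;
  std::memset(fx, 0, sizeof(double) * n);
  std::memset(fy, 0, sizeof(double) * n);
  std::memset(fz, 0, sizeof(double) * n);
  en.pair = en.bond = en.wall = 0.0;

  if (need_rebuild(m, w, x, y, z)) build_pair_list(m, w, x, y, z, sp);

  const int npairs = (int)w.plist.size() / 2;
  const int *pl = w.plist.data();
  for (int p = 0; p < npairs; ++p) {
    int i = pl[2 * p], j = pl[2 * p + 1];
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double dz = min_image(z[i] - z[j], m.length, m.periodic);
    double r2 = dx * dx + dy * dy + dz * dz;
    int k = sp[i] * 3 + sp[j];
    if (r2 >= m.cut2[k]) continue;
    double fs;
    en.pair += wca_pair(r2, m.sig2[k], m.cut2[k], m.eps4[k], fs);
    fx[i] += fs * dx; fy[i] += fs * dy; fz[i] += fs * dz;
    fx[j] -= fs * dx; fy[j] -= fs * dy; fz[j] -= fs * dz;
  }

  // --- FENE ring bonds (plus nothing: bonded pairs also interact via WCA,
  // which the pair loops above already include)
  for (int i = 0; i < m.n_ring; ++i) {
    int j = (i + 1) % m.n_ring;
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double dz = min_image(z[i] - z[j], m.length, m.periodic);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= m.fene_r02) {
      char buf[128];
      std::snprintf(buf, sizeof(buf),
                    "bond overstretch between monomers %d and %d (r = %.4f)",
                    i + 1, j + 1, std::sqrt(r2));
      msg = buf;
      return false;
    }
    double u = r2 / m.fene_r02;
    en.bond += -0.5 * m.fene_k * m.fene_r02 * std::log(1.0 - u);
    double fs = -m.fene_k / (1.0 - u);  // attractive: force on i is fs * dr
    fx[i] += fs * dx; fy[i] += fs * dy; fz[i] += fs * dz;
    fx[j] -= fs * dx; fy[j] -= fs * dy; fz[j] -= fs * dz;
  }

  // --- walls (analytic).  Radial barrel only when smooth_wall; caps always
  // analytic in capped mode.
  for (int i = 0; i < m.n_mobile; ++i) {
    int s = sp[i];
    double sw = m.wall_sig[s], ew4 = 4.0 * m.wall_eps[s];
    double sw2 = sw * sw;
    double cut = std::pow(2.0, 1.0 / 6.0) * sw;
    if (m.smooth_wall) {
      double rho2 = x[i] * x[i] + y[i] * y[i];
      double rho = std::sqrt(rho2);
      double h = (m.radius + sw) - rho;
      if (h < 0.5 * sw) {
        char buf[128];
        std::snprintf(buf, sizeof(buf),
                      "particle %d escaped the cylindrical wall (rho = %.4f)",
                      i + 1, rho);
        msg = buf;
        return false;
      }
      if (h < cut && rho > 1e-12) {
        double fs;
        en.wall += wca_pair(h * h, sw2, cut * cut, ew4, fs);
        // force magnitude dU/dh along -rho_hat; wca_pair gives fs = -(dU/dh)/h
        double fr = -fs * h;  // dU/dh (negative) => inward force fr<0 along rho_hat
        fx[i] += fr * x[i] / rho;
        fy[i] += fr * y[i] / rho;
      }
    }
    if (!m.periodic) {
      double hlo = z[i] + sw;
      double hhi = (m.length - z[i]) + sw;
      if (hlo < 0.5 * sw || hhi < 0.5 * sw) {
        char buf[128];
        std::snprintf(buf, sizeof(buf),
                      "particle %d escaped through a cylinder cap (z = %.4f)",
                      i + 1, z[i]);
        msg = buf;
        return false;
      }
      if (hlo < cut) {  // F_z = -dU/dh * dh/dz with dh/dz = +1: repulsive up
        double fs;
        en.wall += wca_pair(hlo * hlo, sw2, cut * cut, ew4, fs);
        fz[i] += fs * hlo;
      }
      if (hhi < cut) {  // dh/dz = -1 at the far cap: repulsive down
        double fs;
        en.wall += wca_pair(hhi * hhi, sw2, cut * cut, ew4, fs);
        fz[i] -= fs * hhi;
      }
    }
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_compute_forces")]]
List cpp_compute_forces(NumericMatrix pos, IntegerVector species, List par) {
  Model m = model_from_list(par);
  int n = pos.nrow();
  if (n != m.n) stop("position count does not match parameter list");
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  std::vector<int> sp(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    sp[i] = species[i];
  }
  ForceWork w;
  Energies en;
  std::string msg;
  bool ok = compute_forces_core(m, w, x.data(), y.data(), z.data(), sp.data(),
                                fx.data(), fy.data(), fz.data(), en, msg);
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  return List::create(_["ok"] = ok, _["message"] = msg, _["forces"] = f,
                      _["energy"] = List::create(_["pair"] = en.pair,
                                                 _["bond"] = en.bond,
                                                 _["wall"] = en.wall,
                                                 _["total"] = en.pair + en.bond + en.wall));
}

// ---------------------------------------------------------------------------
// Langevin velocity-Verlet loop (VRVO splitting: the exact Ornstein-Uhlenbeck
// velocity update is applied once per step after the two deterministic
// half-kicks; gamma = 0 gives plain symplectic velocity-Verlet).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_run_dynamics")]]
List cpp_run_dynamics(NumericMatrix pos, NumericMatrix vel,
                      IntegerVector images, IntegerVector species, List par,
                      int n_steps, int sample_stride, double seed,
                      bool record_all) {
  Model m = model_from_list(par);
  const int n = pos.nrow();
  if (n != m.n) stop("position count does not match parameter list");
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<int> sp(n), img(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    sp[i] = species[i]; img[i] = images[i];
  }
  Xoshiro rng((uint64_t)seed);
  Ziggurat zig;
  ForceWork w;
  Energies en;
  std::string msg;

  const int n_rec = record_all ? n : m.n_mono;
  if (sample_stride < 1) sample_stride = 1;
  const int n_frames = n_steps / sample_stride + 1;

  List frames(n_frames);
  List frame_images(n_frames);
  IntegerVector steps_out(n_frames);
  NumericVector pe_out(n_frames), ke_temp_out(n_frames);

  const double dt = m.dt, half = 0.5 * dt;
  double c1 = 1.0, c2s[2] = {0.0, 0.0};
  if (m.gamma > 0.0) {
    c1 = std::exp(-m.gamma * dt);
    for (int s = 0; s < 2; ++s)
      c2s[s] = std::sqrt(m.kT * (1.0 - c1 * c1) / m.mass[s]);
  }

  auto record = [&](int slot, int step) {
    NumericMatrix fr(n_rec, 3);
    IntegerVector fim(n_rec);
    for (int i = 0; i < n_rec; ++i) {
      fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
      fim[i] = img[i];
    }
    frames[slot] = fr;
    frame_images[slot] = fim;
    steps_out[slot] = step;
    pe_out[slot] = en.pair + en.bond + en.wall;
    double ke2 = 0.0;
    for (int i = 0; i < m.n_mobile; ++i)
      ke2 += m.mass[sp[i]] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    ke_temp_out[slot] = ke2 / (3.0 * m.n_mobile);
  };

  bool ok = compute_forces_core(m, w, x.data(), y.data(), z.data(), sp.data(),
                                fx.data(), fy.data(), fz.data(), en, msg);
  int fail_step = -1;
  int slot = 0;
  if (ok) {
    record(slot++, 0);
    for (int step = 1; step <= n_steps; ++step) {
      for (int i = 0; i < m.n_mobile; ++i) {
        double im = half / m.mass[sp[i]];
        vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
        x[i] += dt * vx[i]; y[i] += dt * vy[i];
        double zz = z[i] + dt * vz[i];
        if (m.periodic) {
          if (zz >= m.length) { zz -= m.length; ++img[i]; }
          else if (zz < 0.0)  { zz += m.length; --img[i]; }
        }
        z[i] = zz;
      }
      ok = compute_forces_core(m, w, x.data(), y.data(), z.data(), sp.data(),
                               fx.data(), fy.data(), fz.data(), en, msg);
      if (!ok) { fail_step = step; break; }
      if (m.gamma > 0.0) {
        for (int i = 0; i < m.n_mobile; ++i) {
          double im = half / m.mass[sp[i]];
          double c2 = c2s[sp[i]];
          vx[i] = c1 * (vx[i] + im * fx[i]) + c2 * zig.draw(rng);
          vy[i] = c1 * (vy[i] + im * fy[i]) + c2 * zig.draw(rng);
          vz[i] = c1 * (vz[i] + im * fz[i]) + c2 * zig.draw(rng);
        }
      } else {
        for (int i = 0; i < m.n_mobile; ++i) {
          double im = half / m.mass[sp[i]];
          vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
        }
      }
      if (step % sample_stride == 0) record(slot++, step);
      if ((step & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    fail_step = 0;
  }

  // truncate frame lists if the run failed mid-way
  if (slot < n_frames) {
    List f2(slot), fi2(slot);
    IntegerVector s2(slot);
    NumericVector p2(slot), k2(slot);
    for (int i = 0; i < slot; ++i) {
      f2[i] = frames[i]; fi2[i] = frame_images[i];
      s2[i] = steps_out[i]; p2[i] = pe_out[i]; k2[i] = ke_temp_out[i];
    }
    frames = f2; frame_images = fi2; steps_out = s2; pe_out = p2; ke_temp_out = k2;
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  IntegerVector img_out(n);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i]; pos_out(i, 2) = z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
    img_out[i] = img[i];
  }
  return List::create(_["ok"] = fail_step < 0, _["message"] = msg,
                      _["fail_step"] = fail_step,
                      _["frames"] = frames, _["frame_images"] = frame_images,
                      _["steps"] = steps_out, _["potential_energy"] = pe_out,
                      _["kinetic_temperature"] = ke_temp_out,
                      _["positions"] = pos_out, _["velocities"] = vel_out,
                      _["images"] = img_out);
}

// ---------------------------------------------------------------------------
// Random sequential insertion of crowders (builder back end).  Uniform over
// the nominal cross-section and cylinder length; rejects candidates deeper
// than the supplied contact distances with existing particles or already
// placed crowders.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_place_crowders")]]
List cpp_place_crowders(int n, double radius, double length, bool periodic,
                        NumericMatrix existing, NumericVector existing_contact2,
                        double cc_contact, double seed, int max_attempts) {
  Xoshiro rng((uint64_t)seed);
  NumericMatrix placed(n, 3);
  const int n_ex = existing.nrow();
  // cell grid over placed crowders
  const double cell = std::max(cc_contact, 0.25);
  const int nx = std::max(1, (int)std::ceil(2.0 * radius / cell));
  const int nz = std::max(1, (int)std::ceil(length / cell));
  std::vector<int> head((size_t)nx * nx * nz, -1), nxt(std::max(1, n), -1);
  const double cc2 = cc_contact * cc_contact;
  auto cell_ix = [&](double v) {
    int i = (int)((v + radius) / cell);
    return i < 0 ? 0 : (i >= nx ? nx - 1 : i);
  };
  int k = 0;
  long attempts = 0, budget = (long)max_attempts * std::max(1, n);
  while (k < n && attempts < budget) {
    ++attempts;
    double r = radius * std::sqrt(rng.unif());
    double th = 6.283185307179586 * rng.unif();
    double px = r * std::cos(th), py = r * std::sin(th);
    double pz = length * rng.unif();
    bool ok = true;
    for (int e = 0; e < n_ex && ok; ++e) {
      double dx = existing(e, 0) - px, dy = existing(e, 1) - py;
      double dz = existing(e, 2) - pz;
      if (periodic) dz = min_image(dz, length, true);
      if (dx * dx + dy * dy + dz * dz < existing_contact2[e]) ok = false;
    }
    if (ok && k > 0) {
      int ix = cell_ix(px), iy = cell_ix(py);
      int iz = (int)(pz / cell);
      if (iz >= nz) iz = nz - 1;
      for (int dx1 = -1; dx1 <= 1 && ok; ++dx1) {
        int jx = ix + dx1;
        if (jx < 0 || jx >= nx) continue;
        for (int dy1 = -1; dy1 <= 1 && ok; ++dy1) {
          int jy = iy + dy1;
          if (jy < 0 || jy >= nx) continue;
          for (int dz1 = -1; dz1 <= 1 && ok; ++dz1) {
            int jz = iz + dz1;
            if (periodic) { jz = (jz + nz) % nz; }
            else if (jz < 0 || jz >= nz) continue;
            for (int j = head[jx + nx * (jy + nx * jz)]; j >= 0; j = nxt[j]) {
              double ddx = placed(j, 0) - px, ddy = placed(j, 1) - py;
              double ddz = placed(j, 2) - pz;
              if (periodic) ddz = min_image(ddz, length, true);
              if (ddx * ddx + ddy * ddy + ddz * ddz < cc2) { ok = false; break; }
            }
          }
        }
      }
    }
    if (ok) {
      placed(k, 0) = px; placed(k, 1) = py; placed(k, 2) = pz;
      int c = cell_ix(px) + nx * (cell_ix(py) + nx * std::min(nz - 1, (int)(pz / cell)));
      nxt[k] = head[c];
      head[c] = k;
      ++k;
    }
  }
  return List::create(_["achieved"] = k, _["positions"] = placed);
}
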