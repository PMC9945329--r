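// Coarse-grained C-alpha structure-based (Go-type) model:
// energy, forces, fraction of native contacts, and a BAOAB Langevin
// integrator. Reduced units: epsilon = kB = mass = 1.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// topology copied once into contiguous plain arrays (row-wise index
// tuples) so the per-step force loop avoids Rcpp accessor overhead
struct Topo {
  int n;
  int n_bonds, n_angles, n_dihedrals, n_contacts, n_rep;
  std::vector<int> bonds;      // 2 per term
  std::vector<double> bond_r0;
  std::vector<int> angles;     // 3 per term
  std::vector<double> angle_t0;
  std::vector<int> dihedrals;  // 4 per term
  std::vector<double> dihedral_p0;
  std::vector<int> contacts;   // 2 per term
  std::vector<double> contact_r0;
  std::vector<int> rep_pairs;  // 2 per term
  double kb, ka, kd, eps, rep_sigma;
};

static void flatten_idx(const IntegerMatrix& m, std::vector<int>& out) {
  out.resize((size_t)m.nrow() * m.ncol());
  for (int r = 0; r < m.nrow(); ++r)
    for (int c = 0; c < m.ncol(); ++c)
      out[(size_t)r * m.ncol() + c] = m(r, c);
}

Topo unpack(const List& t) {
  Topo o;
  o.n = as<int>(t["n_beads"]);
  IntegerMatrix bonds = as<IntegerMatrix>(t["bonds"]);
  IntegerMatrix angles = as<IntegerMatrix>(t["angles"]);
  IntegerMatrix dihedrals = as<IntegerMatrix>(t["dihedrals"]);
  IntegerMatrix contacts = as<IntegerMatrix>(t["contacts"]);
  IntegerMatrix rep_pairs = as<IntegerMatrix>(t["rep_pairs"]);
  o.n_bonds = bonds.nrow();
  o.n_angles = angles.nrow();
  o.n_dihedrals = dihedrals.nrow();
  o.n_contacts = contacts.nrow();
  o.n_rep = rep_pairs.nrow();
  flatten_idx(bonds, o.bonds);
  flatten_idx(angles, o.angles);
  flatten_idx(dihedrals, o.dihedrals);
  flatten_idx(contacts, o.contacts);
  flatten_idx(rep_pairs, o.rep_pairs);
  o.bond_r0 = as<std::vector<double>>(t["bond_r0"]);
  o.angle_t0 = as<std::vector<double>>(t["angle_t0"]);
  o.dihedral_p0 = as<std::vector<double>>(t["dihedral_p0"]);
  o.contact_r0 = as<std::vector<double>>(t["contact_r0"]);
  o.kb = as<double>(t["k_bond"]);
  o.ka = as<double>(t["k_angle"]);
  o.kd = as<double>(t["k_dihedral"]);
  o.eps = as<double>(t["energy_scale"]);
  o.rep_sigma = as<double>(t["excluded_radius"]);
  return o;
}

inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// energy components and (optionally) forces; xyz is n x 3 row-major
void eval_model(const Topo& t, const double* x, double* f,
                double comp[5]) {
  const int n = t.n;
  comp[0] = comp[1] = comp[2] = comp[3] = comp[4] = 0.0;
  if (f) std::fill(f, f + 3 * n, 0.0);

  // bonds: kb * (r - r0)^2
  for (int m = 0; m < t.n_bonds; ++m) {
    int i = t.bonds[2 * m], j = t.bonds[2 * m + 1];
    double d[3]; vsub(x + 3 * j, x + 3 * i, d);
    double r = vnorm(d);
    double dr = r - t.bond_r0[m];
    comp[0] += t.kb * dr * dr;
    if (f && r > 0) {
      double c = 2.0 * t.kb * dr / r; // dV/dr / r
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += c * d[k];
        f[3 * j + k] -= c * d[k];
      }
    }
  }

  // angles: ka * (theta - theta0)^2
  for (int m = 0; m < t.n_angles; ++m) {
    int i = t.angles[3 * m], j = t.angles[3 * m + 1], k = t.angles[3 * m + 2];
    double u[3], v[3];
    vsub(x + 3 * i, x + 3 * j, u);
    vsub(x + 3 * k, x + 3 * j, v);
    double nu = vnorm(u), nv = vnorm(v);
    double ct = vdot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double theta = std::acos(ct);
    double dth = theta - t.angle_t0[m];
    comp[1] += t.ka * dth * dth;
    if (f) {
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      if (st < 1e-8) continue; // angle at 0/pi: gradient direction undefined
      double dv = 2.0 * t.ka * dth; // dV/dtheta
      for (int c = 0; c < 3; ++c) {
        double dth_di = (ct * u[c] / nu - v[c] / nv) / (nu * st);
        double dth_dk = (ct * v[c] / nv - u[c] / nu) / (nv * st);
        f[3 * i + c] -= dv * dth_di;
        f[3 * k + c] -= dv * dth_dk;
        f[3 * j + c] += dv * (dth_di + dth_dk);
      }
    }
  }

  // dihedrals: kd * [(1 - cos(phi - phi0)) + 0.5 (1 - cos 3(phi - phi0))]
  for (int m = 0; m < t.n_dihedrals; ++m) {
    int i1 = t.dihedrals[4 * m], i2 = t.dihedrals[4 * m + 1],
        i3 = t.dihedrals[4 * m + 2], i4 = t.dihedrals[4 * m + 3];
    double b1[3], b2[3], b3[3], n1[3], n2[3];
    vsub(x + 3 * i2, x + 3 * i1, b1);
    vsub(x + 3 * i3, x + 3 * i2, b2);
    vsub(x + 3 * i4, x + 3 * i3, b3);
    vcross(b1, b2, n1);
    vcross(b2, b3, n2);
    double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
    double nb2 = vnorm(b2);
    if (n1sq < 1e-12 || n2sq < 1e-12 || nb2 < 1e-12) continue;
    // phi = atan2((n1 x n2).b2hat, n1.n2), the standard IUPAC convention
    double n1xn2[3]; vcross(n1, n2, n1xn2);
    double phi = std::atan2(vdot(n1xn2, b2), vdot(n1, n2) * nb2);
    double dphi = phi - t.dihedral_p0[m];
    comp[2] += t.kd * ((1.0 - std::cos(dphi)) +
                       0.5 * (1.0 - std::cos(3.0 * dphi)));
    if (f) {
      double dv = t.kd * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
      double p = vdot(b1, b2) / (nb2 * nb2);
      double q = vdot(b3, b2) / (nb2 * nb2);
      for (int c = 0; c < 3; ++c) {
        double g1 = -(nb2 / n1sq) * n1[c];   // dphi/dr1
        double g4 = (nb2 / n2sq) * n2[c];    // dphi/dr4
        double g2 = -(1.0 + p) * g1 + q * g4; // dphi/dr2
        double g3 = -(1.0 + q) * g4 + p * g1; // dphi/dr3
        f[3 * i1 + c] -= dv * g1;
        f[3 * i2 + c] -= dv * g2;
        f[3 * i3 + c] -= dv * g3;
        f[3 * i4 + c] -= dv * g4;
      }
    }
  }

  // native contacts: 10-12 LJ, eps * (5 (r0/r)^12 - 6 (r0/r)^10)
  for (int m = 0; m < t.n_contacts; ++m) {
    int i = t.contacts[2 * m], j = t.contacts[2 * m + 1];
    double d[3]; vsub(x + 3 * j, x + 3 * i, d);
    double r2 = vdot(d, d);
    double r = std::sqrt(r2);
    double s2 = t.contact_r0[m] * t.contact_r0[m] / r2;
    double s10 = s2 * s2 * s2 * s2 * s2;
    double s12 = s10 * s2;
    comp[3] += t.eps * (5.0 * s12 - 6.0 * s10);
    if (f) {
      // dV/dr = eps * (-60 s12 + 60 s10) / r
      double dv_r = t.eps * 60.0 * (s10 - s12) / r2; // (dV/dr)/r
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += dv_r * d[k];
        f[3 * j + k] -= dv_r * d[k];
      }
    }
  }

  // excluded volume: eps * (sigma/r)^12 for non-contact pairs
  double sig2 = t.rep_sigma * t.rep_sigma;
  for (int m = 0; m < t.n_rep; ++m) {
    int i = t.rep_pairs[2 * m], j = t.rep_pairs[2 * m + 1];
    double d[3]; vsub(x + 3 * j, x + 3 * i, d);
    double r2 = vdot(d, d);
    if (r2 > 9.0 * sig2) continue; // (sigma/r)^12 < 2e-6: negligible
    double s2 = sig2 / r2;
    double s12 = s2 * s2 * s2; s12 = s12 * s12;
    comp[4] += t.eps * s12;
    if (f) {
      double dv_r = -t.eps * 12.0 * s12 / r2;
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k] += dv_r * d[k];
        f[3 * j + k] -= dv_r * d[k];
      }
    }
  }
}

double q_of(const Topo& t, const double* x, int* formed) {
  int nf = 0;
  int nc = t.n_contacts;
  for (int m = 0; m < nc; ++m) {
    int i = t.contacts[2 * m], j = t.contacts[2 * m + 1];
    double d[3]; vsub(x + 3 * j, x + 3 * i, d);
    double r = vnorm(d);
    int ok = r < 1.2 * t.contact_r0[m];
    if (formed) formed[m] = ok;
    nf += ok;
  }
  return (double)nf / (double)nc;
}

// xorshift128+ seeded via splitmix64; Box-Muller normals
struct Rng {
  uint64_t s0, s1;
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t& z) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      return x ^ (x >> 31);
    };
    s0 = mix(z);
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector sbm_energy_cpp(NumericMatrix xyz, List topo) {
  Topo t = unpack(topo);
  if (xyz.nrow() != t.n || xyz.ncol() != 3)
    stop("coordinate matrix must be n_beads x 3");
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = xyz(i, c);
  double comp[5];
  eval_model(t, x.data(), nullptr, comp);
  NumericVector out = NumericVector::create(
    _["bond"] = comp[0], _["angle"] = comp[1], _["dihedral"] = comp[2],
    _["contact"] = comp[3], _["repulsion"] = comp[4],
    _["total"] = comp[0] + comp[1] + comp[2] + comp[3] + comp[4]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix sbm_forces_cpp(NumericMatrix xyz, List topo) {
  Topo t = unpack(topo);
  if (xyz.nrow() != t.n || xyz.ncol() != 3)
    stop("coordinate matrix must be n_beads x 3");
  std::vector<double> x(3 * t.n), f(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = xyz(i, c);
  double comp[5];
  eval_model(t, x.data(), f.data(), comp);
  NumericMatrix out(t.n, 3);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = f[3 * i + c];
  return out;
}

// [[Rcpp::export]]
List sbm_q_cpp(NumericMatrix xyz, List topo) {
  Topo t = unpack(topo);
  if (t.n_contacts == 0) stop("topology has no native contacts");
  if (xyz.nrow() != t.n || xyz.ncol() != 3)
    stop("coordinate matrix must be n_beads x 3");
  std::vector<double> x(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = xyz(i, c);
  std::vector<int> formed(t.n_contacts);
  double q = q_of(t, x.data(), formed.data());
  return List::create(_["q"] = q, _["formed"] = LogicalVector(formed.begin(),
                                                              formed.end()));
}

// [[Rcpp::export]]
List run_dynamics_cpp(List topo, NumericMatrix start_xyz, double n_steps_d,
                      double dt, double friction, double temperature,
                      int save_every, double seed_d, bool record_flags) {
  Topo t = unpack(topo);
  const int n = t.n;
  const long long n_steps = (long long)n_steps_d;
  if (start_xyz.nrow() != n || start_xyz.ncol() != 3)
    stop("start coordinates must be n_beads x 3");
  if (n_steps < 1 || dt <= 0) stop("invalid integration parameters");
  const int nc = t.n_contacts;
  if (nc == 0) stop("topology has no native contacts");

  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = start_xyz(i, c);

  Rng rng((uint64_t)(long long)seed_d);
  double sdT = std::sqrt(temperature);
  for (int i = 0; i < 3 * n; ++i) v[i] = sdT * rng.norm();

  double comp[5];
  eval_model(t, x.data(), f.data(), comp);

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * sdT;
  const long long n_frames = n_steps / save_every;

  NumericVector qs(n_frames), es(n_frames), kes(n_frames);
  LogicalMatrix flags;
  if (record_flags) flags = LogicalMatrix(n_frames, nc);
  std::vector<int> formed(nc);

  long long frame = 0;
  for (long long step = 1; step <= n_steps; ++step) {
    // BAOAB
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * rng.norm();
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    eval_model(t, x.data(), f.data(), comp);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];

    if (step % save_every == 0) {
      double e = comp[0] + comp[1] + comp[2] + comp[3] + comp[4];
      if (!std::isfinite(e)) {
        stop("numerical blow-up at step %lld", step);
      }
      double ke = 0.0;
      for (int i = 0; i < 3 * n; ++i) ke += 0.5 * v[i] * v[i];
      qs[frame] = q_of(t, x.data(), record_flags ? formed.data() : nullptr);
      es[frame] = e;
      kes[frame] = ke;
      if (record_flags)
        for (int m = 0; m < nc; ++m) flags(frame, m) = formed[m];
      ++frame;
      if (frame % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix final_xyz(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) final_xyz(i, c) = x[3 * i + c];

  List out = List::create(
    _["q_series"] = qs, _["e_series"] = es, _["ke_series"] = kes,
    _["final_xyz"] = final_xyz);
  if (record_flags) out["contact_formed"] = flags;
  return out;
}
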