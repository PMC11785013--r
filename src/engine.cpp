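// Inner loops of the structure-based model: energy/force evaluation for all
// term classes and Langevin (BAOAB) / velocity-Verlet integration.
// Reduced units: length Angstrom, energy epsilon, mass 1, k_B = 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Engine {
  int n;
  std::vector<int> b_i, b_j;           std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;      std::vector<double> a_th0, a_k2;
  std::vector<int> im_i, im_j, im_k, im_l; std::vector<double> im_x0, im_k2;
  std::vector<int> pl_i, pl_j, pl_k, pl_l; std::vector<double> pl_k2;
  std::vector<int> d_i, d_j, d_k, d_l; std::vector<double> d_phi0, d_k2;
  std::vector<int> c_i, c_j;           std::vector<double> c_sig, c_eps;
  std::vector<int> r_i, r_j;           std::vector<double> r_r0, r_k;
  double nc_eps, nc_sig, nc_cut, nc_shift;
  std::vector<char> excluded; // flat n*n lookup

  std::vector<Vec3> x, f;
  double e_bond, e_angle, e_imp, e_planar, e_dih, e_con, e_nc, e_res;

  void load(const List& spec) {
    n = as<int>(spec["n"]);
    auto iv = [&](const char* nm) {
      IntegerVector v = spec[nm];
      return std::vector<int>(v.begin(), v.end());
    };
    auto dv = [&](const char* nm) {
      NumericVector v = spec[nm];
      return std::vector<double>(v.begin(), v.end());
    };
    b_i = iv("bonds_i"); b_j = iv("bonds_j");
    b_r0 = dv("bonds_r0"); b_k = dv("bonds_k");
    a_i = iv("angles_ai"); a_j = iv("angles_aj"); a_k = iv("angles_ak");
    a_th0 = dv("angles_th0"); a_k2 = dv("angles_k");
    im_i = iv("imps_i"); im_j = iv("imps_j"); im_k = iv("imps_k");
    im_l = iv("imps_l"); im_x0 = dv("imps_x0"); im_k2 = dv("imps_w");
    pl_i = iv("plan_i"); pl_j = iv("plan_j"); pl_k = iv("plan_k");
    pl_l = iv("plan_l"); pl_k2 = dv("plan_w");
    d_i = iv("dih_i"); d_j = iv("dih_j"); d_k = iv("dih_k");
    d_l = iv("dih_l"); d_phi0 = dv("dih_phi0"); d_k2 = dv("dih_w");
    c_i = iv("con_i"); c_j = iv("con_j");
    c_sig = dv("con_sigma"); c_eps = dv("con_eps");
    r_i = iv("res_i"); r_j = iv("res_j");
    r_r0 = dv("res_r0"); r_k = dv("res_k");
    nc_eps = as<double>(spec["nc_eps"]);
    nc_sig = as<double>(spec["nc_sigma"]);
    nc_cut = as<double>(spec["nc_cutoff"]);
    double sc = nc_sig / nc_cut;
    nc_shift = nc_eps * std::pow(sc, 12); // truncation shift, keeps U continuous
    excluded.assign((size_t)n * n, 0);
    std::vector<int> ei = iv("excl_i"), ej = iv("excl_j");
    for (size_t q = 0; q < ei.size(); ++q) {
      excluded[(size_t)ei[q] * n + ej[q]] = 1;
      excluded[(size_t)ej[q] * n + ei[q]] = 1;
    }
    x.assign(n, Vec3());
    f.assign(n, Vec3());
  }

  void set_coords(const NumericMatrix& xyz) {
    for (int i = 0; i < n; ++i) x[i] = Vec3(xyz(i, 0), xyz(i, 1), xyz(i, 2));
  }

  static double wrap(double a) {
    while (a > M_PI) a -= 2 * M_PI;
    while (a <= -M_PI) a += 2 * M_PI;
    return a;
  }

  // dihedral angle and d(phi)/dr for the four atoms
  double dihedral(int i, int j, int k, int l,
                  Vec3& gi, Vec3& gj, Vec3& gk, Vec3& gl) const {
    Vec3 b1 = x[j] - x[i], b2 = x[k] - x[j], b3 = x[l] - x[k];
    Vec3 m = cross(b1, b2), nn = cross(b2, b3);
    double nb2 = norm(b2);
    double phi = std::atan2(dot(cross(m, nn), b2) / nb2, dot(m, nn));
    double m2 = dot(m, m), n2 = dot(nn, nn);
    gi = m * (-nb2 / m2);
    gl = nn * (nb2 / n2);
    double c12 = dot(b1, b2) / (nb2 * nb2);
    double c32 = dot(b3, b2) / (nb2 * nb2);
    gj = gi * (-1.0 - c12) + gl * c32;
    gk = gi * c12 - gl * (1.0 + c32);
    return phi;
  }

  // returns false on overlapping atoms in a pair term
  bool compute(std::string& err) {
    for (int i = 0; i < n; ++i) f[i] = Vec3();
    e_bond = e_angle = e_imp = e_planar = e_dih = e_con = e_nc = e_res = 0;

    for (size_t q = 0; q < b_i.size(); ++q) {
      Vec3 d = x[b_i[q]] - x[b_j[q]];
      double r = norm(d);
      if (r < 1e-6) { err = "overlapping atoms in bond term"; return false; }
      double dr = r - b_r0[q];
      e_bond += 0.5 * b_k[q] * dr * dr;
      Vec3 g = d * (b_k[q] * dr / r);
      f[b_i[q]] = f[b_i[q]] - g;
      f[b_j[q]] = f[b_j[q]] + g;
    }

    for (size_t q = 0; q < a_i.size(); ++q) {
      int i = a_i[q], j = a_j[q], k = a_k[q];
      Vec3 u = x[i] - x[j], v = x[k] - x[j];
      double nu = norm(u), nv = norm(v);
      double c = dot(u, v) / (nu * nv);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      double s = std::sqrt(std::max(1e-12, 1.0 - c * c));
      double dth = th - a_th0[q];
      e_angle += 0.5 * a_k2[q] * dth * dth;
      double coef = a_k2[q] * dth;
      Vec3 gi = (u * (c / nu) - v * (1.0 / nv)) * (1.0 / (nu * s));
      Vec3 gk = (v * (c / nv) - u * (1.0 / nu)) * (1.0 / (nv * s));
      f[i] = f[i] - gi * coef;
      f[k] = f[k] - gk * coef;
      f[j] = f[j] + (gi + gk) * coef;
    }

    Vec3 gi, gj, gk, gl;
    for (size_t q = 0; q < im_i.size(); ++q) {
      double chi = dihedral(im_i[q], im_j[q], im_k[q], im_l[q], gi, gj, gk, gl);
      double d = wrap(chi - im_x0[q]);
      e_imp += 0.5 * im_k2[q] * d * d;
      double coef = im_k2[q] * d;
      f[im_i[q]] = f[im_i[q]] - gi * coef;
      f[im_j[q]] = f[im_j[q]] - gj * coef;
      f[im_k[q]] = f[im_k[q]] - gk * coef;
      f[im_l[q]] = f[im_l[q]] - gl * coef;
    }

    for (size_t q = 0; q < pl_i.size(); ++q) {
      double chi = dihedral(pl_i[q], pl_j[q], pl_k[q], pl_l[q], gi, gj, gk, gl);
      e_planar += pl_k2[q] * (1.0 - std::cos(2.0 * chi));
      double coef = 2.0 * pl_k2[q] * std::sin(2.0 * chi);
      f[pl_i[q]] = f[pl_i[q]] - gi * coef;
      f[pl_j[q]] = f[pl_j[q]] - gj * coef;
      f[pl_k[q]] = f[pl_k[q]] - gk * coef;
      f[pl_l[q]] = f[pl_l[q]] - gl * coef;
    }

    for (size_t q = 0; q < d_i.size(); ++q) {
      double phi = dihedral(d_i[q], d_j[q], d_k[q], d_l[q], gi, gj, gk, gl);
      double d = phi - d_phi0[q];
      e_dih += d_k2[q] * ((1.0 - std::cos(d)) + 0.5 * (1.0 - std::cos(3.0 * d)));
      double coef = d_k2[q] * (std::sin(d) + 1.5 * std::sin(3.0 * d));
      f[d_i[q]] = f[d_i[q]] - gi * coef;
      f[d_j[q]] = f[d_j[q]] - gj * coef;
      f[d_k[q]] = f[d_k[q]] - gk * coef;
      f[d_l[q]] = f[d_l[q]] - gl * coef;
    }

    for (size_t q = 0; q < c_i.size(); ++q) {
      Vec3 d = x[c_i[q]] - x[c_j[q]];
      double r = norm(d);
      if (r < 1e-6) { err = "overlapping atoms in contact term"; return false; }
      double s6 = std::pow(c_sig[q] / r, 6), s12 = s6 * s6;
      e_con += c_eps[q] * (s12 - 2.0 * s6);
      double dUdr = 12.0 * c_eps[q] * (s6 - s12) / r;
      Vec3 g = d * (dUdr / r);
      f[c_i[q]] = f[c_i[q]] - g;
      f[c_j[q]] = f[c_j[q]] + g;
    }

    double cut2 = nc_cut * nc_cut;
    for (int i = 0; i < n - 1; ++i) {
      const Vec3& xi = x[i];
      const char* ex = &excluded[(size_t)i * n];
      for (int j = i + 1; j < n; ++j) {
        if (ex[j]) continue;
        double dx = xi.x - x[j].x, dy = xi.y - x[j].y, dz = xi.z - x[j].z;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= cut2) continue;
        if (r2 < 1e-12) { err = "overlapping atoms in non-contact pair"; return false; }
        double s2 = nc_sig * nc_sig / r2;
        double s12 = s2 * s2 * s2; s12 *= s12;
        e_nc += nc_eps * s12 - nc_shift;
        double dUdr_r = -12.0 * nc_eps * s12 / r2; // (dU/dr)/r
        f[i].x -= dUdr_r * dx; f[i].y -= dUdr_r * dy; f[i].z -= dUdr_r * dz;
        f[j].x += dUdr_r * dx; f[j].y += dUdr_r * dy; f[j].z += dUdr_r * dz;
      }
    }

    for (size_t q = 0; q < r_i.size(); ++q) {
      Vec3 d = x[r_i[q]] - x[r_j[q]];
      double r = norm(d);
      if (r < 1e-6) { err = "overlapping atoms in restraint term"; return false; }
      double dr = r - r_r0[q];
      e_res += 0.5 * r_k[q] * dr * dr;
      Vec3 g = d * (r_k[q] * dr / r);
      f[r_i[q]] = f[r_i[q]] - g;
      f[r_j[q]] = f[r_j[q]] + g;
    }
    return true;
  }

  double total() const {
    return e_bond + e_angle + e_imp + e_planar + e_dih + e_con + e_nc + e_res;
  }
};

// [[Rcpp::export(name = ".engine_energy_forces")]]
List engine_energy_forces(List spec, NumericMatrix xyz) {
  Engine eng;
  eng.load(spec);
  eng.set_coords(xyz);
  std::string err;
  if (!eng.compute(err)) stop(err);
  NumericMatrix forces(eng.n, 3);
  for (int i = 0; i < eng.n; ++i) {
    forces(i, 0) = eng.f[i].x;
    forces(i, 1) = eng.f[i].y;
    forces(i, 2) = eng.f[i].z;
  }
  NumericVector breakdown = NumericVector::create(
    _["bonds"] = eng.e_bond, _["angles"] = eng.e_angle,
    _["impropers"] = eng.e_imp, _["planars"] = eng.e_planar,
    _["dihedrals"] = eng.e_dih, _["contacts"] = eng.e_con,
    _["noncontacts"] = eng.e_nc, _["restraints"] = eng.e_res);
  return List::create(_["energy"] = eng.total(), _["forces"] = forces,
                      _["breakdown"] = breakdown);
}

// Integrate nsteps of BAOAB Langevin dynamics (velocity Verlet when
// gamma == 0). noise must have nsteps * n rows of standard normals when
// gamma > 0; it is ignored otherwise. Mass = 1 for every atom.
// [[Rcpp::export(name = ".engine_integrate")]]
List engine_integrate(List spec, NumericMatrix xyz, NumericMatrix vel,
                      double dt, double gamma, double temperature,
                      int nsteps, NumericMatrix noise) {
  Engine eng;
  eng.load(spec);
  eng.set_coords(xyz);
  int n = eng.n;
  std::vector<Vec3> v(n);
  for (int i = 0; i < n; ++i) v[i] = Vec3(vel(i, 0), vel(i, 1), vel(i, 2));

  std::string err;
  if (!eng.compute(err)) stop(err);

  bool thermo = gamma > 0;
  double c1 = thermo ? std::exp(-gamma * dt) : 1.0;
  double c2 = thermo ? std::sqrt(temperature * (1.0 - c1 * c1)) : 0.0;
  double half = 0.5 * dt;

  bool ok = true;
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < n; ++i) { // B then A
      v[i] = v[i] + eng.f[i] * half;
      eng.x[i] = eng.x[i] + v[i] * half;
    }
    if (thermo) { // O
      size_t off = (size_t)s * n;
      for (int i = 0; i < n; ++i) {
        v[i].x = c1 * v[i].x + c2 * noise(off + i, 0);
        v[i].y = c1 * v[i].y + c2 * noise(off + i, 1);
        v[i].z = c1 * v[i].z + c2 * noise(off + i, 2);
      }
    }
    for (int i = 0; i < n; ++i) eng.x[i] = eng.x[i] + v[i] * half; // A
    if (!eng.compute(err)) { ok = false; break; }
    for (int i = 0; i < n; ++i) v[i] = v[i] + eng.f[i] * half; // B
    double u = eng.total();
    if (!std::isfinite(u) || std::fabs(u) > 1e10) {
      ok = false;
      err = "potential energy diverged";
      break;
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    xout(i, 0) = eng.x[i].x; xout(i, 1) = eng.x[i].y; xout(i, 2) = eng.x[i].z;
    vout(i, 0) = v[i].x; vout(i, 1) = v[i].y; vout(i, 2) = v[i].z;
  }
  double ke = 0;
  for (int i = 0; i < n; ++i) ke += 0.5 * dot(v[i], v[i]);
  NumericVector breakdown = NumericVector::create(
    _["bonds"] = eng.e_bond, _["angles"] = eng.e_angle,
    _["impropers"] = eng.e_imp, _["planars"] = eng.e_planar,
    _["dihedrals"] = eng.e_dih, _["contacts"] = eng.e_con,
    _["noncontacts"] = eng.e_nc, _["restraints"] = eng.e_res);
  return List::create(_["coordinates"] = xout, _["velocities"] = vout,
                      _["potential"] = eng.total(), _["kinetic"] = ke,
                      _["breakdown"] = breakdown,
                      _["ok"] = ok, _["error"] = err);
}
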