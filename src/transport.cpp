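// Monte-Carlo transport kernel: bremsstrahlung source at the target,
// treatment-head geometry (primary collimator, optional flattening filter,
// jaws, air column), and coupled photon/electron transport in a voxelised
// water phantom with analog-dose and collision-kerma tallies.
//
// All randomness comes from R's generator (unif_rand/norm_rand), so runs are
// reproducible under set.seed() and batch streams are controlled from R.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double ME = 0.511;  // electron rest energy, MeV

// ---------------------------------------------------------------------------
// interpolation helpers

struct LogLogTable {
  std::vector<double> lx, ly;
  void set(const NumericVector &x, const NumericVector &y) {
    lx.resize(x.size()); ly.resize(y.size());
    for (int i = 0; i < x.size(); ++i) { lx[i] = std::log(x[i]); ly[i] = std::log(y[i]); }
  }
  double operator()(double x) const {
    double l = std::log(x);
    if (l <= lx.front()) return std::exp(ly.front());
    if (l >= lx.back())  return std::exp(ly.back());
    size_t hi = std::upper_bound(lx.begin(), lx.end(), l) - lx.begin();
    size_t lo = hi - 1;
    double f = (l - lx[lo]) / (lx[hi] - lx[lo]);
    return std::exp(ly[lo] + f * (ly[hi] - ly[lo]));
  }
};

struct MatTables {
  LogLogTable pe, co, pa, tot, tr;   // linear coefficients, 1/cm
  bool has_tr = false;
};

static MatTables load_mat(List m) {
  MatTables t;
  NumericVector E = m["energy"];
  t.pe.set(E, as<NumericVector>(m["pe"]));
  t.co.set(E, as<NumericVector>(m["co"]));
  t.pa.set(E, as<NumericVector>(m["pa"]));
  t.tot.set(E, as<NumericVector>(m["tot"]));
  if (m.containsElementNamed("tr")) {
    t.tr.set(E, as<NumericVector>(m["tr"]));
    t.has_tr = true;
  }
  return t;
}

// ---------------------------------------------------------------------------
// samplers

// Klein-Nishina: returns scattered fraction eps and cos(theta)
static inline void sample_kn(double E, double &eps, double &cth) {
  double a = E / ME;
  double emin = 1.0 / (1.0 + 2.0 * a);
  double lemin = std::log(emin);
  for (;;) {
    eps = std::exp(lemin * (1.0 - unif_rand()));
    cth = 1.0 - (1.0 / eps - 1.0) / a;
    double s2 = 1.0 - cth * cth;
    double g = eps * eps + 1.0 - eps * s2;
    if (unif_rand() * 2.0 <= g) return;
  }
}

// thin-target bremsstrahlung spectrum ~ (1/k) (1 - k/E + 0.75 (k/E)^2)
static inline double sample_schiff(double Eeff, double kmin) {
  double lr = std::log(Eeff / kmin);
  for (;;) {
    double k = kmin * std::exp(lr * unif_rand());
    double f = k / Eeff;
    double B = 1.0 - f + 0.75 * f * f;
    if (unif_rand() <= B) return k;
  }
}

// intrinsic bremsstrahlung emission angle, p(theta) ~ theta/(1+(theta/tc)^2)^2
static inline double sample_intrinsic_angle(double tc) {
  double u = unif_rand();
  double th = tc * std::sqrt(u / (1.0 - u + 1e-12));
  return th > 1.3 ? 1.3 : th;
}

// rotate direction (u,v,w) by polar angle (cos ct) and uniform azimuth
static inline void rotate_dir(double &u, double &v, double &w, double cth) {
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double phi = 2.0 * M_PI * unif_rand();
  double sp = std::sin(phi), cp = std::cos(phi);
  double uu, vv, ww;
  if (std::fabs(w) > 0.99999) {
    uu = sth * cp; vv = sth * sp; ww = (w > 0 ? cth : -cth);
  } else {
    double s = std::sqrt(1.0 - w * w);
    uu = u * cth + sth * (u * w * cp - v * sp) / s;
    vv = v * cth + sth * (v * w * cp + u * sp) / s;
    ww = w * cth - sth * s * cp;
  }
  double n = std::sqrt(uu * uu + vv * vv + ww * ww);
  u = uu / n; v = vv / n; w = ww / n;
}

static inline void isotropic_dir(double &u, double &v, double &w) {
  w = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - w * w));
  u = s * std::cos(phi); v = s * std::sin(phi);
}

// Highland multiple-scattering angle for path x (cm) in a medium with
// radiation length X0 (cm); E is the electron kinetic energy in MeV and the
// 13.6 MeV coefficient with p*beta in MeV gives the angle in radians.
static inline double highland(double E, double x_cm, double X0_cm) {
  if (x_cm <= 0) return 0.0;
  double pc = std::sqrt(E * (E + 2.0 * ME));
  double pbeta = pc * pc / (E + ME);
  double xr = x_cm / X0_cm;
  double corr = 1.0 + 0.038 * std::log(xr);
  if (corr < 0.25) corr = 0.25;
  return 13.6 / pbeta * std::sqrt(xr) * corr;
}

// ---------------------------------------------------------------------------
// engine

struct Particle {
  int kind;                  // 0 photon, 1 electron, 2 positron
  double E, x, y, z, u, v, w, wt;
};

struct PlaneSpec { double z, xc, yc, hw; };

struct Engine {
  // source
  double src_mean, src_sigma, spot_sigma;     // MeV, MeV, cm
  double n_tot_mean, kmin, delta_half, theta0, thetac;
  LogLogTable tbar;
  // geometry (cm, z increases from target toward phantom)
  bool mode_flat;
  double t_target, z_pc, r_pc, z_filter, z_jaw, ap_jaw, z_psf, z_phantom;
  double phantom_half, phantom_depth;
  std::vector<double> filt_r, filt_t;
  // materials
  MatTables water, air, steel;
  LogLogTable stop_w;          // water stopping power MeV/cm
  double e_cut, photon_cut;
  // options
  bool air_on, absorb_only, kill_electrons, kerma_mode, psf_capture;
  int psf_max;
  // tallies
  bool grid_on;  double gx0, gy0, gz0, gd; int gnx, gny, gnz;
  bool cyl_on;   double cxo, cyo, crad, cz0, cdz; int cnz;
  std::vector<double> grid, cyl;
  // kerma profile slabs: rows (z0, z1, yhalf, xmin, dx, nx)
  NumericMatrix prof_spec;
  std::vector<std::vector<double>> prof;
  // scoring planes
  std::vector<PlaneSpec> planes;
  int nbins; double bin_w, e_max;
  std::vector<double> phist;   // [plane][kind(2)][bin]
  std::vector<double> psum, pesum; // [plane][kind]
  // ledger
  double led_enter = 0, led_dep = 0, led_exit = 0;
  double killed_weight = 0;
  // electron-kill runs transport the killed electron with scoring muted so
  // the random stream stays aligned with the paired full run (CRN)
  bool mute = false;
  // psf out
  std::vector<double> psf_out;
  long psf_count = 0;
  std::vector<Particle> stack;

  double filter_thickness(double r) const {
    if (filt_r.empty()) return 0.0;
    if (r >= filt_r.back()) return filt_t.back();
    if (r <= filt_r.front()) return filt_t.front();
    size_t hi = std::upper_bound(filt_r.begin(), filt_r.end(), r) - filt_r.begin();
    size_t lo = hi - 1;
    double f = (r - filt_r[lo]) / (filt_r[hi] - filt_r[lo]);
    return filt_t[lo] + f * (filt_t[hi] - filt_t[lo]);
  }

  void plane_cross(const Particle &p, double z1, double z2) {
    if (planes.empty()) return;
    for (size_t i = 0; i < planes.size(); ++i) {
      double zp = planes[i].z;
      if (zp <= z1 || zp > z2 + 1e-12) continue;
      double t = (zp - p.z) / p.w;
      double xx = p.x + p.u * t, yy = p.y + p.v * t;
      if (std::fabs(xx - planes[i].xc) <= planes[i].hw &&
          std::fabs(yy - planes[i].yc) <= planes[i].hw) {
        int kd = p.kind == 0 ? 0 : 1;
        int b = (int)std::floor(p.E / bin_w);
        if (b >= nbins) b = nbins - 1;
        if (b < 0) b = 0;
        phist[(i * 2 + kd) * nbins + b] += p.wt;
        psum[i * 2 + kd] += p.wt;
        pesum[i * 2 + kd] += p.wt * p.E;
      }
    }
  }

  void deposit(double x, double y, double z, double e, double wt) {
    if (mute) return;
    double ewt = e * wt;
    led_dep += ewt;
    if (grid_on) {
      int ix = (int)std::floor((x - gx0) / gd);
      int iy = (int)std::floor((y - gy0) / gd);
      int iz = (int)std::floor((z - gz0) / gd);
      if (ix >= 0 && ix < gnx && iy >= 0 && iy < gny && iz >= 0 && iz < gnz)
        grid[(size_t)iz * gnx * gny + (size_t)iy * gnx + ix] += ewt;
    }
    if (cyl_on) {
      double dx = x - cxo, dy = y - cyo;
      if (dx * dx + dy * dy <= crad * crad) {
        int iz = (int)std::floor((z - cz0) / cdz);
        if (iz >= 0 && iz < cnz) cyl[iz] += ewt;
      }
    }
  }

  inline bool in_phantom(double x, double y, double z) const {
    return z >= z_phantom && z <= z_phantom + phantom_depth &&
           std::fabs(x) <= phantom_half && std::fabs(y) <= phantom_half;
  }

  // collision-kerma line estimator over a photon flight segment
  void kerma_segment(const Particle &p, double len) {
    double mtr = water.tr(p.E) * p.E * p.wt;
    if (cyl_on && std::fabs(p.w) > 1e-6) {
      double zA = p.z, zB = p.z + p.w * len;
      double zlo = std::min(zA, zB), zhi = std::max(zA, zB);
      zlo = std::max(zlo, cz0); zhi = std::min(zhi, cz0 + cnz * cdz);
      if (zhi > zlo) {
        int i0 = (int)std::floor((zlo - cz0) / cdz);
        int i1 = (int)std::floor((zhi - cz0) / cdz - 1e-12);
        if (i0 < 0) i0 = 0; if (i1 >= cnz) i1 = cnz - 1;
        for (int iz = i0; iz <= i1; ++iz) {
          double za = std::max(zlo, cz0 + iz * cdz);
          double zb = std::min(zhi, cz0 + (iz + 1) * cdz);
          if (zb <= za) continue;
          double tm = ((za + zb) / 2 - p.z) / p.w;
          double xm = p.x + p.u * tm - cxo, ym = p.y + p.v * tm - cyo;
          if (xm * xm + ym * ym <= crad * crad)
            cyl[iz] += mtr * (zb - za) / std::fabs(p.w);
        }
      }
    }
    int np = prof_spec.nrow();
    for (int k = 0; k < np; ++k) {
      double z0 = prof_spec(k, 0), z1 = prof_spec(k, 1);
      double yh = prof_spec(k, 2), xmin = prof_spec(k, 3);
      double dx = prof_spec(k, 4); int nx = (int)prof_spec(k, 5);
      int axis = prof_spec.ncol() > 6 ? (int)prof_spec(k, 6) : 0;
      if (std::fabs(p.w) < 1e-6) continue;
      double ta = (z0 - p.z) / p.w, tb = (z1 - p.z) / p.w;
      double t0 = std::max(0.0, std::min(ta, tb));
      double t1 = std::min(len, std::max(ta, tb));
      if (t1 <= t0) continue;
      double tm = (t0 + t1) / 2;
      double xm = p.x + p.u * tm, ym = p.y + p.v * tm;
      double along = axis == 0 ? xm : ym, perp = axis == 0 ? ym : xm;
      if (std::fabs(perp) > yh) continue;
      int ix = (int)std::floor((along - xmin) / dx);
      if (ix >= 0 && ix < nx) prof[k][ix] += mtr * (t1 - t0);
    }
  }

  // condensed-history electron in water; returns final position
  void electron_water(Particle p, double *end = nullptr) {
    const double X0w = 36.08;
    int guard = 0;
    while (p.E > e_cut && ++guard < 4000) {
      double S = stop_w(p.E);
      double step = std::min(0.1, (p.E - e_cut * 0.5) / S);
      if (step < 2e-4) break;
      double dE = S * step;
      if (dE > p.E - e_cut) dE = p.E - e_cut;
      double mx = p.x + p.u * step / 2, my = p.y + p.v * step / 2,
             mz = p.z + p.w * step / 2;
      deposit(mx, my, mz, dE, p.wt);
      p.x += p.u * step; p.y += p.v * step; p.z += p.w * step;
      p.E -= dE;
      if (!in_phantom(p.x, p.y, p.z)) {
        if (!mute) led_exit += p.wt * p.E;
        if (end) { end[0] = p.x; end[1] = p.y; end[2] = p.z; }
        return;
      }
      double th = highland(p.E, step, X0w);
      if (th > 0) rotate_dir(p.u, p.v, p.w, std::cos(std::fabs(th * norm_rand())));
    }
    deposit(p.x, p.y, p.z, p.E, p.wt);
    if (end) { end[0] = p.x; end[1] = p.y; end[2] = p.z; }
  }

  // analog photon (and secondaries) inside phantom
  void photon_water(Particle p) {
    int guard = 0;
    while (++guard < 10000) {
      if (p.E <= photon_cut) {
        if (!kerma_mode) deposit(p.x, p.y, p.z, p.E, p.wt);
        return;
      }
      double mu = water.tot(p.E);
      double s = -std::log(unif_rand()) / mu;
      // distance to phantom boundary
      double tb = 1e30;
      if (p.w > 0) tb = std::min(tb, (z_phantom + phantom_depth - p.z) / p.w);
      else if (p.w < 0) tb = std::min(tb, (z_phantom - p.z) / p.w);
      if (p.u > 0) tb = std::min(tb, (phantom_half - p.x) / p.u);
      else if (p.u < 0) tb = std::min(tb, (-phantom_half - p.x) / p.u);
      if (p.v > 0) tb = std::min(tb, (phantom_half - p.y) / p.v);
      else if (p.v < 0) tb = std::min(tb, (-phantom_half - p.y) / p.v);
      double seg = std::min(s, tb);
      if (kerma_mode) kerma_segment(p, seg);
      if (s >= tb) { led_exit += p.wt * p.E; return; }
      p.x += p.u * s; p.y += p.v * s; p.z += p.w * s;
      if (absorb_only) {
        if (!kerma_mode) deposit(p.x, p.y, p.z, p.E, p.wt);
        return;
      }
      double mpe = water.pe(p.E), mco = water.co(p.E), mpa = water.pa(p.E);
      double r = unif_rand() * (mpe + mco + mpa);
      if (r < mpe) {                       // photoelectric
        if (!kerma_mode) {
          Particle e = p; e.kind = 1;
          if (e.E <= e_cut) deposit(e.x, e.y, e.z, e.E, e.wt);
          else electron_water(e);
        }
        return;
      } else if (r < mpe + mco) {          // Compton
        double eps, cth;
        sample_kn(p.E, eps, cth);
        double Ee = p.E * (1.0 - eps);
        if (!kerma_mode) {
          Particle e = p; e.kind = 1; e.E = Ee;
          double a = p.E / ME;
          double tph = std::acos(std::min(1.0, std::max(-1.0, cth)));
          double te = std::atan(1.0 / ((1.0 + a) * std::tan(tph / 2 + 1e-12)));
          rotate_dir(e.u, e.v, e.w, std::cos(te));
          if (e.E <= e_cut) deposit(e.x, e.y, e.z, e.E, e.wt);
          else electron_water(e);
        }
        p.E *= eps;
        rotate_dir(p.u, p.v, p.w, cth);
      } else {                             // pair production
        double Ek = (p.E - 2 * ME) / 2;
        double endp[3] = { p.x, p.y, p.z };
        if (!kerma_mode) {
          Particle e = p; e.kind = 1; e.E = std::max(Ek, 1e-6);
          if (e.E <= e_cut) deposit(e.x, e.y, e.z, e.E, e.wt);
          else electron_water(e);
          Particle po = p; po.kind = 2; po.E = std::max(Ek, 1e-6);
          if (po.E <= e_cut) deposit(po.x, po.y, po.z, po.E, po.wt);
          else electron_water(po, endp);
        }
        // annihilation: two back-to-back 0.511 MeV photons (their energy
        // balances the 2 m_e c^2 taken from the pair's kinetic budget, so
        // the phantom ledger stays enter = deposited + exited)
        Particle g1; g1.kind = 0; g1.E = ME; g1.wt = p.wt;
        g1.x = endp[0]; g1.y = endp[1]; g1.z = endp[2];
        isotropic_dir(g1.u, g1.v, g1.w);
        Particle g2 = g1; g2.u = -g1.u; g2.v = -g1.v; g2.w = -g1.w;
        if (in_phantom(g1.x, g1.y, g1.z)) {
          stack.push_back(g1); stack.push_back(g2);
        } else {
          led_exit += 2 * ME * p.wt;  // positron left the phantom first
        }
        return;
      }
    }
  }

  void enter_water(Particle p) {
    if (!in_phantom(p.x, p.y, p.z)) return;
    led_enter += p.wt * p.E;
    if (p.kind == 0) {
      stack.push_back(p);
    } else {
      if (kerma_mode) { led_exit += p.wt * p.E; return; }  // not tracked here
      if (p.E <= e_cut) deposit(p.x, p.y, p.z, p.E, p.wt);
      else electron_water(p);
    }
    while (!stack.empty()) {
      Particle q = stack.back(); stack.pop_back();
      photon_water(q);
    }
  }

  // contaminant electron in the head/air: ballistic to the phantom surface
  void head_electron(Particle p) {
    if (p.E < 0.15 || p.w < 0.05) return;
    double L = (z_phantom - p.z) / p.w;
    // air multiple scattering over the full remaining column
    double th = highland(p.E, L, 36.66 / 1.205e-3);  // X0_air = 36.66 g/cm^2
    if (th > 0) rotate_dir(p.u, p.v, p.w, std::cos(std::fabs(th * norm_rand())));
    if (p.w < 0.05) return;
    // collision loss in air (~2 MeV cm^2/g)
    double dE = 2.0 * 1.205e-3 * (z_phantom - p.z) / p.w;
    if (p.E - dE < 0.1) return;
    p.E -= dE;
    // apertures downstream of creation point
    if (p.z < z_pc) {
      double t = (z_pc - p.z) / p.w;
      double xx = p.x + p.u * t, yy = p.y + p.v * t;
      if (xx * xx + yy * yy > r_pc * r_pc) return;
    }
    if (p.z < z_jaw) {
      double t = (z_jaw - p.z) / p.w;
      if (std::fabs(p.x + p.u * t) > ap_jaw || std::fabs(p.y + p.v * t) > ap_jaw)
        return;
    }
    plane_cross(p, p.z, z_phantom);
    double t = (z_phantom - p.z) / p.w;
    p.x += p.u * t; p.y += p.v * t; p.z = z_phantom;
    if (kill_electrons) {
      // discard the dose but keep the transport draws (CRN pairing)
      killed_weight += p.wt * p.E;
      if (in_phantom(p.x, p.y, p.z) && p.E > e_cut) {
        mute = true;
        electron_water(p);
        mute = false;
      }
      return;
    }
    enter_water(p);
  }

  // degrade an electron created inside a dense head component through the
  // residual slab thickness (cm): collision loss and extra scatter, or
  // absorption if its range is exhausted; returns false when absorbed.
  // Steel filter: stopping ~11.6 MeV/cm, X0 ~1.76 cm.
  bool slab_escape(Particle &e, double slab_t) {
    if (slab_t <= 0) return true;
    double resid = slab_t * unif_rand();
    if (e.w < 0.05) return false;
    double path = resid / e.w;
    double loss = 11.6 * path;
    if (e.E - loss < 0.2) return false;
    double thsc = highland(e.E - loss / 2, path, 1.76);
    if (thsc > 0) rotate_dir(e.u, e.v, e.w, std::cos(std::fabs(thsc * norm_rand())));
    e.E -= loss;
    return true;
  }

  // interaction of a photon in a head component or air; returns false if the
  // photon was terminated; slab_t > 0 marks an interaction inside a dense
  // component of that residual thickness (electron escape is attenuated)
  bool photon_interact(Particle &p, const MatTables &mat, double slab_t = 0) {
    double mpe = mat.pe(p.E), mco = mat.co(p.E), mpa = mat.pa(p.E);
    double r = unif_rand() * (mpe + mco + mpa);
    if (r < mpe) return false;
    if (r < mpe + mco) {
      double eps, cth;
      sample_kn(p.E, eps, cth);
      Particle e = p; e.kind = 1; e.E = p.E * (1.0 - eps);
      double a = p.E / ME;
      double tph = std::acos(std::min(1.0, std::max(-1.0, cth)));
      double te = std::atan(1.0 / ((1.0 + a) * std::tan(tph / 2 + 1e-12)));
      rotate_dir(e.u, e.v, e.w, std::cos(te));
      if (slab_escape(e, slab_t)) head_electron(e);
      p.E *= eps;
      rotate_dir(p.u, p.v, p.w, cth);
      if (p.E <= photon_cut) return false;
      return true;
    }
    // pair in head material: charged pair forwarded as contaminant electrons,
    // annihilation photons emitted in place
    double Ek = (p.E - 2 * ME) / 2;
    if (Ek > 0.15) {
      Particle e = p; e.kind = 1; e.E = Ek;
      if (slab_escape(e, slab_t)) head_electron(e);
      Particle po = p; po.kind = 2; po.E = Ek;
      if (slab_escape(po, slab_t)) head_electron(po);
    }
    Particle g1 = p; g1.E = ME;
    isotropic_dir(g1.u, g1.v, g1.w);
    if (g1.w > 0.05) stack.push_back(g1);
    Particle g2 = g1; g2.u = -g1.u; g2.v = -g1.v; g2.w = -g1.w;
    if (g2.w > 0.05) stack.push_back(g2);
    return false;
  }

  // advance a head photon to z target through air, with optional sampled
  // interactions; returns false if terminated before reaching it
  bool leg(Particle &p, double zt) {
    int guard = 0;
    while (++guard < 50) {
      if (p.w < 1e-4) return false;
      double path = (zt - p.z) / p.w;
      if (path <= 0) return true;
      if (air_on && p.kind == 0) {
        double mu = air.tot(p.E) ;
        double s = -std::log(unif_rand()) / mu;
        if (s < path) {
          double z2 = p.z + p.w * s;
          plane_cross(p, p.z, z2);
          p.x += p.u * s; p.y += p.v * s; p.z = z2;
          if (!photon_interact(p, air)) return false;
          continue;
        }
      }
      plane_cross(p, p.z, zt);
      double t = path;
      p.x += p.u * t; p.y += p.v * t; p.z = zt;
      return true;
    }
    return false;
  }

  void psf_record(const Particle &p) {
    ++psf_count;
    if ((long)(psf_out.size() / 8) >= psf_max) return;
    psf_out.push_back(p.kind); psf_out.push_back(p.E);
    psf_out.push_back(p.x * 10); psf_out.push_back(p.y * 10);  // mm
    psf_out.push_back(p.u); psf_out.push_back(p.v); psf_out.push_back(p.w);
    psf_out.push_back(p.wt);
  }

  // transport one photon from its creation point through the head into water
  void head_photon(Particle p) {
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      Particle q = stack.back(); stack.pop_back();
      head_photon_one(q);
    }
  }

  void head_photon_one(Particle &p) {
    // primary collimator
    if (p.z < z_pc) {
      if (!leg(p, z_pc)) return;
      if (p.x * p.x + p.y * p.y > r_pc * r_pc) return;
    }
    // flattening filter
    if (mode_flat && p.z < z_filter) {
      if (!leg(p, z_filter)) return;
      double r = std::sqrt(p.x * p.x + p.y * p.y);
      double t = filter_thickness(r);
      if (t > 0) {
        double pl = t / p.w;
        double pint = 1.0 - std::exp(-steel.tot(p.E) * pl);
        if (unif_rand() < pint) {
          if (!photon_interact(p, steel, t)) return;
        }
      }
    }
    // phase-space plane
    if (psf_capture && p.z < z_psf) {
      if (!leg(p, z_psf)) return;
      psf_record(p);
    }
    // jaws
    if (p.z < z_jaw) {
      if (!leg(p, z_jaw)) return;
      if (std::fabs(p.x) > ap_jaw || std::fabs(p.y) > ap_jaw) return;
    }
    // drift to phantom surface
    if (!leg(p, z_phantom)) return;
    enter_water(p);
  }

  // one primary-electron history
  void primary_history() {
    double E0 = src_mean + src_sigma * norm_rand();
    int guard = 0;
    while (E0 <= 0.3 && ++guard < 100) E0 = src_mean + src_sigma * norm_rand();
    if (E0 <= 0.3) return;
    double Eeff = E0 - delta_half;
    if (Eeff <= kmin * 3) return;
    double ud = unif_rand();
    double k = sample_schiff(Eeff, kmin);
    double wt = n_tot_mean * std::pow(E0 / src_mean, 1.5) * tbar(k);
    double sigu = theta0 * std::sqrt(ud);
    double tx = sigu * norm_rand(), ty = sigu * norm_rand();
    double thi = sample_intrinsic_angle(thetac);
    double phi = 2.0 * M_PI * unif_rand();
    double dx = tx + thi * std::cos(phi), dy = ty + thi * std::sin(phi);
    double nz = 1.0 / std::sqrt(1.0 + dx * dx + dy * dy);
    Particle p;
    p.kind = 0; p.E = k; p.wt = wt;
    p.x = spot_sigma * norm_rand(); p.y = spot_sigma * norm_rand();
    p.z = ud * t_target;
    p.u = dx * nz; p.v = dy * nz; p.w = nz;
    head_photon(p);
  }
};

static Engine build_engine(List model) {
  Engine e;
  List src = model["source"], head = model["head"], run = model["run"],
       sc = model["scoring"];
  e.src_mean = src["mean_energy"]; e.src_sigma = src["sigma"];
  e.spot_sigma = src["spot_sigma_cm"];
  List br = model["brems"];
  e.n_tot_mean = br["n_tot_mean"]; e.kmin = br["kmin"];
  e.delta_half = br["delta_half"]; e.theta0 = br["theta0"];
  e.thetac = br["thetac"];
  e.tbar.set(as<NumericVector>(br["k_grid"]), as<NumericVector>(br["tbar"]));
  e.mode_flat = as<bool>(head["flat"]);
  e.t_target = head["t_target"]; e.z_pc = head["z_pc"]; e.r_pc = head["r_pc"];
  e.z_filter = head["z_filter"]; e.z_jaw = head["z_jaw"];
  e.ap_jaw = head["ap_jaw"]; e.z_psf = head["z_psf"];
  e.z_phantom = head["z_phantom"];
  e.phantom_half = head["phantom_half"]; e.phantom_depth = head["phantom_depth"];
  e.filt_r = as<std::vector<double>>(head["filter_r"]);
  e.filt_t = as<std::vector<double>>(head["filter_t"]);
  List mats = model["materials"];
  e.water = load_mat(mats["water"]);
  e.air = load_mat(mats["air"]);
  e.steel = load_mat(mats["steel"]);
  List sw = model["stopping_water"];
  e.stop_w.set(as<NumericVector>(sw["energy"]), as<NumericVector>(sw["stopping"]));
  e.e_cut = model["e_cut"]; e.photon_cut = model["photon_cut"];
  e.air_on = as<bool>(run["air_on"]);
  e.absorb_only = as<bool>(run["absorb_only"]);
  e.kill_electrons = as<bool>(run["kill_electrons"]);
  e.kerma_mode = as<bool>(run["kerma_mode"]);
  e.psf_capture = as<bool>(run["psf_capture"]);
  e.psf_max = as<int>(run["psf_max"]);
  e.grid_on = as<bool>(sc["grid_on"]);
  if (e.grid_on) {
    e.gx0 = sc["gx0"]; e.gy0 = sc["gy0"]; e.gz0 = sc["gz0"]; e.gd = sc["gd"];
    e.gnx = sc["gnx"]; e.gny = sc["gny"]; e.gnz = sc["gnz"];
    e.grid.assign((size_t)e.gnx * e.gny * e.gnz, 0.0);
  } else { e.gnx = e.gny = e.gnz = 0; }
  e.cyl_on = as<bool>(sc["cyl_on"]);
  if (e.cyl_on) {
    e.cxo = sc["cxo"]; e.cyo = sc["cyo"]; e.crad = sc["crad"];
    e.cz0 = sc["cz0"]; e.cdz = sc["cdz"]; e.cnz = sc["cnz"];
    e.cyl.assign(e.cnz, 0.0);
  } else e.cnz = 0;
  e.prof_spec = as<NumericMatrix>(sc["prof_spec"]);
  e.prof.resize(e.prof_spec.nrow());
  for (int i = 0; i < e.prof_spec.nrow(); ++i)
    e.prof[i].assign((int)e.prof_spec(i, 5), 0.0);
  NumericMatrix pl = as<NumericMatrix>(sc["planes"]);
  for (int i = 0; i < pl.nrow(); ++i)
    e.planes.push_back({pl(i, 0), pl(i, 1), pl(i, 2), pl(i, 3)});
  e.bin_w = sc["bin_w"]; e.e_max = sc["e_max"];
  e.nbins = (int)std::round(e.e_max / e.bin_w);
  e.phist.assign((size_t)e.planes.size() * 2 * e.nbins, 0.0);
  e.psum.assign(e.planes.size() * 2, 0.0);
  e.pesum.assign(e.planes.size() * 2, 0.0);
  return e;
}

static List engine_result(Engine &e, double n_hist) {
  List out;
  out["grid"] = NumericVector(e.grid.begin(), e.grid.end());
  out["cyl"] = NumericVector(e.cyl.begin(), e.cyl.end());
  List pr(e.prof.size());
  for (size_t i = 0; i < e.prof.size(); ++i)
    pr[i] = NumericVector(e.prof[i].begin(), e.prof[i].end());
  out["prof"] = pr;
  out["plane_hist"] = NumericVector(e.phist.begin(), e.phist.end());
  out["plane_sum"] = NumericVector(e.psum.begin(), e.psum.end());
  out["plane_esum"] = NumericVector(e.pesum.begin(), e.pesum.end());
  out["ledger"] = NumericVector::create(
    _["enter"] = e.led_enter, _["deposited"] = e.led_dep,
    _["exited"] = e.led_exit, _["killed"] = e.killed_weight);
  out["n_hist"] = n_hist;
  if (e.psf_capture) {
    size_t nr = e.psf_out.size() / 8;
    NumericMatrix rec(nr, 8);
    for (size_t i = 0; i < nr; ++i)
      for (int j = 0; j < 8; ++j) rec(i, j) = e.psf_out[i * 8 + j];
    out["psf"] = rec;
    out["psf_total"] = (double)e.psf_count;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_batch(List model, double n_hist) {
  Engine e = build_engine(model);
  List run = model["run"];
  int mode = as<int>(run["source_mode"]);
  long n = (long)n_hist;
  if (mode == 0) {
    for (long i = 0; i < n; ++i) e.primary_history();
  } else if (mode == 2) {
    double E = run["pp_energy"], cone = run["pp_cone"];
    double cmin = std::cos(cone);
    for (long i = 0; i < n; ++i) {
      Particle p; p.kind = 0; p.E = E; p.wt = 1.0;
      p.x = p.y = p.z = 0.0;
      double c = cmin + (1.0 - cmin) * unif_rand();
      double phi = 2.0 * M_PI * unif_rand();
      double s = std::sqrt(1.0 - c * c);
      p.u = s * std::cos(phi); p.v = s * std::sin(phi); p.w = c;
      e.head_photon(p);
    }
  } else if (mode == 1) {
    NumericMatrix rec = as<NumericMatrix>(run["psf_records"]);
    int factor = as<int>(run["psf_factor"]);
    bool rot = as<bool>(run["psf_rotate"]);
    double zp = as<double>(run["psf_plane_z"]);
    for (int i = 0; i < rec.nrow(); ++i) {
      for (int f = 0; f < factor; ++f) {
        Particle p;
        p.kind = (int)rec(i, 0); p.E = rec(i, 1);
        p.x = rec(i, 2) / 10; p.y = rec(i, 3) / 10;
        p.u = rec(i, 4); p.v = rec(i, 5); p.w = rec(i, 6);
        p.wt = rec(i, 7); p.z = zp;
        if (rot) {
          double phi = 2.0 * M_PI * unif_rand();
          double cp = std::cos(phi), sp = std::sin(phi);
          double x2 = cp * p.x - sp * p.y, y2 = sp * p.x + cp * p.y;
          double u2 = cp * p.u - sp * p.v, v2 = sp * p.u + cp * p.v;
          p.x = x2; p.y = y2; p.u = u2; p.v = v2;
        }
        if (p.kind == 0) {
          e.stack.clear();
          e.stack.push_back(p);
          while (!e.stack.empty()) {
            Particle q = e.stack.back(); e.stack.pop_back();
            // continue below the PSF plane: jaws, air, phantom
            if (q.z < e.z_jaw) {
              if (!e.leg(q, e.z_jaw)) continue;
              if (std::fabs(q.x) > e.ap_jaw || std::fabs(q.y) > e.ap_jaw) continue;
            }
            if (!e.leg(q, e.z_phantom)) continue;
            e.enter_water(q);
          }
        } else {
          e.head_electron(p);
        }
      }
    }
  }
  return engine_result(e, n_hist);
}

// run the head stage only for externally supplied particles; returns the
// survivors at the phantom surface plane (columns: kind, E, x, y, u, v, w, wt)
// [[Rcpp::export]]
NumericMatrix cpp_head_transmit(NumericMatrix particles, List model) {
  Engine e = build_engine(model);
  std::vector<double> out;
  for (int i = 0; i < particles.nrow(); ++i) {
    Particle p;
    p.kind = (int)particles(i, 0); p.E = particles(i, 1);
    p.x = particles(i, 2); p.y = particles(i, 3); p.z = particles(i, 4);
    p.u = particles(i, 5); p.v = particles(i, 6); p.w = particles(i, 7);
    p.wt = particles(i, 8);
    if (p.kind != 0) { e.head_electron(p); continue; }
    // transport through head but capture at surface instead of entering water
    e.stack.clear(); e.stack.push_back(p);
    while (!e.stack.empty()) {
      Particle q = e.stack.back(); e.stack.pop_back();
      bool alive = true;
      if (q.z < e.z_pc) {
        alive = e.leg(q, e.z_pc) &&
                (q.x * q.x + q.y * q.y <= e.r_pc * e.r_pc);
      }
      if (alive && e.mode_flat && q.z < e.z_filter) {
        alive = e.leg(q, e.z_filter);
        if (alive) {
          double r = std::sqrt(q.x * q.x + q.y * q.y);
          double t = e.filter_thickness(r);
          if (t > 0 && q.w > 1e-4) {
            double pint = 1.0 - std::exp(-e.steel.tot(q.E) * t / q.w);
            if (unif_rand() < pint) alive = e.photon_interact(q, e.steel, t);
          }
        }
      }
      if (alive && q.z < e.z_jaw) {
        alive = e.leg(q, e.z_jaw) &&
                std::fabs(q.x) <= e.ap_jaw && std::fabs(q.y) <= e.ap_jaw;
      }
      if (alive) alive = e.leg(q, e.z_phantom);
      if (alive) {
        out.push_back(q.kind); out.push_back(q.E);
        out.push_back(q.x); out.push_back(q.y);
        out.push_back(q.u); out.push_back(q.v); out.push_back(q.w);
        out.push_back(q.wt);
      }
    }
  }
  size_t nr = out.size() / 8;
  NumericMatrix res(nr, 8);
  for (size_t i = 0; i < nr; ++i)
    for (int j = 0; j < 8; ++j) res(i, j) = out[i * 8 + j];
  return res;
}

// standalone condensed-history electron track in water (diagnostics/tests)
// [[Rcpp::export]]
List cpp_electron_track(double energy, NumericVector pos, NumericVector dir,
                        List model) {
  Engine e = build_engine(model);
  Particle p;
  p.kind = 1; p.E = energy; p.wt = 1.0;
  p.x = pos[0]; p.y = pos[1]; p.z = pos[2];
  p.u = dir[0]; p.v = dir[1]; p.w = dir[2];
  e.led_dep = 0;
  if (p.E <= e.e_cut) {
    e.deposit(p.x, p.y, p.z, p.E, 1.0);
  } else {
    e.electron_water(p);
  }
  return List::create(_["deposited"] = e.led_dep,
                      _["exited"] = e.led_exit,
                      _["grid"] = NumericVector(e.grid.begin(), e.grid.end()),
                      _["cyl"] = NumericVector(e.cyl.begin(), e.cyl.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(int n, double energy) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double eps, cth;
    sample_kn(energy, eps, cth);
    out(i, 0) = energy * eps;
    out(i, 1) = energy * (1.0 - eps);
    out(i, 2) = std::acos(std::min(1.0, std::max(-1.0, cth)));
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_brems(int n, double e_eff, double kmin,
                               double thetac) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = sample_schiff(e_eff, kmin);
    out(i, 1) = sample_intrinsic_angle(thetac);
  }
  return out;
}

// ---------------------------------------------------------------------------
// composite angular density q(theta | u): Gaussian multiple-scattering tilt
// (sigma = theta0 sqrt(u)) convolved with the intrinsic bremsstrahlung factor;
// density per steradian in the small-angle approximation.

static double intrinsic_density(double th, double tc) {
  double x = th / tc;
  return 1.0 / (M_PI * tc * tc) / ((1 + x * x) * (1 + x * x));
}

// [[Rcpp::export]]
List cpp_angular_table(double theta0, double thetac, int n_u = 56,
                       int n_theta = 160, double theta_max = 1.2) {
  NumericVector th(n_theta), uu(n_u);
  // geometric-ish theta grid, dense near zero
  for (int i = 0; i < n_theta; ++i) {
    double f = (double)i / (n_theta - 1);
    th[i] = theta_max * (std::pow(50.0, f) - 1.0) / 49.0;
  }
  // log-spaced emission-depth grid: the tilt sigma shrinks like sqrt(u), so
  // the near-axis intensity builds up logarithmically toward u -> 0 until
  // the intrinsic angle takes over at u* = (thetac/theta0)^2
  double u0 = (thetac / (6 * theta0)) * (thetac / (6 * theta0));
  for (int j = 0; j < n_u; ++j)
    uu[j] = std::exp(std::log(u0) * (1.0 - (double)j / (n_u - 1)));
  NumericMatrix q(n_theta, n_u);
  // equal-probability-mass nodes of the intrinsic angle: the intrinsic CDF
  // in x = (delta/thetac)^2 is x/(1+x), so delta_a = thetac sqrt(v/(1-v))
  // at uniform v; the smooth Gaussian tilt is then averaged over these
  // nodes and the relative azimuth.
  const int nv = 40, npsi = 32;
  std::vector<double> dnode(nv), cpsi(npsi);
  for (int a = 0; a < nv; ++a) {
    double v = (a + 0.5) / nv;
    dnode[a] = thetac * std::sqrt(v / (1.0 - v));
  }
  for (int b = 0; b < npsi; ++b)
    cpsi[b] = std::cos((b + 0.5) * M_PI / npsi);   // psi symmetric about pi
  for (int j = 0; j < n_u; ++j) {
    double sig = theta0 * std::sqrt(uu[j]);
    double gnorm = 1.0 / (2 * M_PI * sig * sig);
    for (int i = 0; i < n_theta; ++i) {
      double t = th[i];
      if (sig < thetac / 6) { q(i, j) = intrinsic_density(t, thetac); continue; }
      double acc = 0.0;
      for (int a = 0; a < nv; ++a) {
        double dd = dnode[a];
        double base = t * t + dd * dd;
        double cross = 2 * t * dd;
        double s = 0.0;
        for (int b = 0; b < npsi; ++b) {
          double d2 = base - cross * cpsi[b];
          s += std::exp(-d2 / (2 * sig * sig));
        }
        acc += s / npsi;
      }
      q(i, j) = gnorm * acc / nv;
    }
  }
  // u-averaged intensity: trapezoid over the log grid plus the [0, u0]
  // segment where the conditional density is the intrinsic one
  NumericVector avg(n_theta);
  for (int i = 0; i < n_theta; ++i) {
    double s = intrinsic_density(th[i], thetac) * uu[0];
    for (int j = 0; j + 1 < n_u; ++j)
      s += 0.5 * (q(i, j) + q(i, j + 1)) * (uu[j + 1] - uu[j]);
    avg[i] = s;
  }
  return List::create(_["theta"] = th, _["u"] = uu, _["q"] = q,
                      _["intensity"] = avg);
}

// next-event (expected-value) spectral estimator on small scoring planes at
// the phantom surface; integrates the known separable angular density per
// history instead of waiting for analog hits.
// planes: rows (xc, yc, hw) in cm at z = z_phantom.
// [[Rcpp::export]]
List cpp_offaxis_nextevent(List model, double n_hist, NumericMatrix planes) {
  Engine e = build_engine(model);
  List br = model["brems"];
  List qt = cpp_angular_table(e.theta0, e.thetac);
  NumericVector th = qt["theta"];
  NumericVector ug = qt["u"];
  NumericMatrix q = qt["q"];
  int n_u = q.ncol(), n_t = q.nrow();
  int np = planes.nrow();
  int nb = e.nbins;
  std::vector<double> hist((size_t)np * nb, 0.0);
  std::vector<double> sumw(np, 0.0), sumwe(np, 0.0);
  // per-plane geometry
  std::vector<double> thp(np), r2(np), open(np), area(np), rfil(np), cosp(np);
  for (int i = 0; i < np; ++i) {
    double xc = planes(i, 0), yc = planes(i, 1), hw = planes(i, 2);
    double r = std::sqrt(xc * xc + yc * yc);
    double R2 = e.z_phantom * e.z_phantom + r * r;
    thp[i] = std::atan(r / e.z_phantom);
    r2[i] = R2;
    cosp[i] = e.z_phantom / std::sqrt(R2);
    area[i] = 4 * hw * hw;
    bool ok = true;
    double rp = r * e.z_pc / e.z_phantom;
    if (rp > e.r_pc) ok = false;
    if (std::fabs(xc) * e.z_jaw / e.z_phantom > e.ap_jaw ||
        std::fabs(yc) * e.z_jaw / e.z_phantom > e.ap_jaw) ok = false;
    open[i] = ok ? 1.0 : 0.0;
    rfil[i] = r * e.z_filter / e.z_phantom;
  }
  long n = (long)n_hist;
  for (long hgt = 0; hgt < n; ++hgt) {
    double E0 = e.src_mean + e.src_sigma * norm_rand();
    if (E0 <= 0.3) continue;
    double Eeff = E0 - e.delta_half;
    if (Eeff <= e.kmin * 3) continue;
    double ud = unif_rand();
    double k = sample_schiff(Eeff, e.kmin);
    double wt = e.n_tot_mean * std::pow(E0 / e.src_mean, 1.5) * e.tbar(k);
    // locate the sampled emission depth in the log-spaced u grid
    double uc = std::max(ud, ug[0]);
    int ju = n_u - 2;
    for (int s = 0; s < n_u - 1; ++s) if (ug[s + 1] >= uc) { ju = s; break; }
    double fu = (uc - ug[ju]) / (ug[ju + 1] - ug[ju]);
    int b = (int)std::floor(k / e.bin_w);
    if (b >= nb) b = nb - 1;
    double mu_air = e.air.tot(k);
    for (int i = 0; i < np; ++i) {
      if (open[i] == 0.0) continue;
      // interpolate q(theta | u)
      double t = thp[i];
      int it = n_t - 2;
      for (int s = 0; s < n_t - 1; ++s) if (th[s + 1] >= t) { it = s; break; }
      double f = (t - th[it]) / (th[it + 1] - th[it] + 1e-15);
      double q0 = q(it, ju) + f * (q(it + 1, ju) - q(it, ju));
      double q1 = q(it, ju + 1) + f * (q(it + 1, ju + 1) - q(it, ju + 1));
      double qq = q0 + fu * (q1 - q0);
      double w = wt * qq * area[i] * cosp[i] / r2[i];
      // air attenuation along the ray
      w *= std::exp(-mu_air * std::sqrt(r2[i]));
      if (e.mode_flat) {
        double ft = e.filter_thickness(rfil[i]);
        if (ft > 0) w *= std::exp(-e.steel.tot(k) * ft / cosp[i]);
      }
      hist[(size_t)i * nb + b] += w;
      sumw[i] += w; sumwe[i] += w * k;
    }
  }
  NumericMatrix h(nb, np);
  for (int i = 0; i < np; ++i)
    for (int bb = 0; bb < nb; ++bb) h(bb, i) = hist[(size_t)i * nb + bb];
  return List::create(_["hist"] = h,
                      _["sumw"] = NumericVector(sumw.begin(), sumw.end()),
                      _["sumwe"] = NumericVector(sumwe.begin(), sumwe.end()),
                      _["n_hist"] = n_hist);
}
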