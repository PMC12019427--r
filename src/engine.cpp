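// Langevin dynamics core for the bead-spring dsDNA chain.
//
// Internal unit system: length in Angstrom, energy in kBT (at the run
// temperature), mass in Dalton.  The derived time unit is
// sqrt(Da * A^2 / kBT) ~ 63.3 fs at 300 K; all times entering here are
// already converted to that unit by the R layer.
//
// Bond potential (piecewise, C1):
//   r <= ra : (kl/2) (r - r0)^2                      harmonic B-form branch
//   ra..rb  : U(ra) + fp (r - ra) + delta sin^2(pi s) tangent + bump,
//             s = (r - ra)/(rb - ra), fp = kl (ra - r0)
//   r >= rb : U(rb) + fp (r - rb) + (kr/2) (r - rb)^2 convex continuation
// The lower convex envelope over [ra, rb] is the tangent line, so the
// Maxwell/common-tangent plateau force equals fp.
//
// Bending: E = (ka/2) (pi - phi)^2 per interior angle (discrete WLC).
// Trap: E = (ktrap/2) (r_d - r_eql)^2 between the last bead and a fixed
// anchor; measured trap force is ktrap (r_d - r_eql).

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct FragPar {
  int nb;                       // number of bonds (n_beads - 1)
  std::vector<double> kl, r0, ra, rb, dl, kr, fp, ua, ub;
  std::vector<double> ka;       // nb - 1 angle constants, kBT/rad^2
  double mass, ktrap, reql;
};

FragPar unpack(List fr) {
  FragPar p;
  NumericVector kl = fr["kl"], r0 = fr["r0"], ra = fr["ra"], rb = fr["rb"],
                dl = fr["delta"], kr = fr["kr"], ka = fr["ka"];
  p.nb = kl.size();
  p.kl.assign(kl.begin(), kl.end());
  p.r0.assign(r0.begin(), r0.end());
  p.ra.assign(ra.begin(), ra.end());
  p.rb.assign(rb.begin(), rb.end());
  p.dl.assign(dl.begin(), dl.end());
  p.kr.assign(kr.begin(), kr.end());
  p.ka.assign(ka.begin(), ka.end());
  p.fp.resize(p.nb); p.ua.resize(p.nb); p.ub.resize(p.nb);
  for (int i = 0; i < p.nb; ++i) {
    p.fp[i] = p.kl[i] * (p.ra[i] - p.r0[i]);
    p.ua[i] = 0.5 * p.kl[i] * (p.ra[i] - p.r0[i]) * (p.ra[i] - p.r0[i]);
    p.ub[i] = p.ua[i] + p.fp[i] * (p.rb[i] - p.ra[i]);
  }
  p.mass  = as<double>(fr["mass"]);
  p.ktrap = as<double>(fr["ktrap"]);
  p.reql  = as<double>(fr["reql"]);
  return p;
}

inline double bond_u(const FragPar& p, int i, double r) {
  if (r <= p.ra[i]) {
    double d = r - p.r0[i];
    return 0.5 * p.kl[i] * d * d;
  }
  if (r < p.rb[i]) {
    double s = (r - p.ra[i]) / (p.rb[i] - p.ra[i]);
    double sn = std::sin(M_PI * s);
    return p.ua[i] + p.fp[i] * (r - p.ra[i]) + p.dl[i] * sn * sn;
  }
  double d = r - p.rb[i];
  return p.ub[i] + p.fp[i] * d + 0.5 * p.kr[i] * d * d;
}

inline double bond_du(const FragPar& p, int i, double r) {
  if (r <= p.ra[i]) return p.kl[i] * (r - p.r0[i]);
  if (r < p.rb[i]) {
    double w = p.rb[i] - p.ra[i];
    double s = (r - p.ra[i]) / w;
    return p.fp[i] + p.dl[i] * (M_PI / w) * std::sin(2.0 * M_PI * s);
  }
  return p.fp[i] + p.kr[i] * (r - p.rb[i]);
}

struct Work {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
};

// Fills forces (negative gradient of the total potential), returns the
// trap spring elongation r_d - r_eql.  Forces are NOT constraint-masked
// here; the integrator masks.
double forces(const FragPar& p, Work& w, double anchor_x, bool with_trap) {
  const int n = w.n;
  std::fill(w.fx.begin(), w.fx.end(), 0.0);
  std::fill(w.fy.begin(), w.fy.end(), 0.0);
  std::fill(w.fz.begin(), w.fz.end(), 0.0);

  for (int i = 0; i < p.nb; ++i) {
    double dx = w.x[i + 1] - w.x[i];
    double dy = w.y[i + 1] - w.y[i];
    double dz = w.z[i + 1] - w.z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-10) stop("coincident adjacent beads at bond %d", i + 1);
    double g = bond_du(p, i, r) / r;   // dU/dr / r
    w.fx[i]     += g * dx;  w.fy[i]     += g * dy;  w.fz[i]     += g * dz;
    w.fx[i + 1] -= g * dx;  w.fy[i + 1] -= g * dy;  w.fz[i + 1] -= g * dz;
  }

  for (int i = 1; i < n - 1; ++i) {
    double ka = p.ka[i - 1];
    if (ka == 0.0) continue;
    double ux = w.x[i - 1] - w.x[i], uy = w.y[i - 1] - w.y[i], uz = w.z[i - 1] - w.z[i];
    double vxx = w.x[i + 1] - w.x[i], vyy = w.y[i + 1] - w.y[i], vzz = w.z[i + 1] - w.z[i];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vxx * vxx + vyy * vyy + vzz * vzz);
    if (nu < 1e-10 || nv < 1e-10) stop("degenerate angle at bead %d", i + 1);
    double c = (ux * vxx + uy * vyy + uz * vzz) / (nu * nv);
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    double phi = std::acos(c);
    double sn = std::sqrt(1.0 - c * c);
    // F = ka (pi - phi) * dphi/dr; (pi - phi)/sin(phi) -> 1 as phi -> pi
    double pref;
    if (sn < 1e-8) {
      pref = (phi > 1.5) ? ka : ka * (M_PI - phi) / 1e-8;
    } else {
      pref = ka * (M_PI - phi) / sn;
    }
    double gax = pref * (c * ux / nu - vxx / nv) / nu;
    double gay = pref * (c * uy / nu - vyy / nv) / nu;
    double gaz = pref * (c * uz / nu - vzz / nv) / nu;
    double gcx = pref * (c * vxx / nv - ux / nu) / nv;
    double gcy = pref * (c * vyy / nv - uy / nu) / nv;
    double gcz = pref * (c * vzz / nv - uz / nu) / nv;
    w.fx[i - 1] += gax;  w.fy[i - 1] += gay;  w.fz[i - 1] += gaz;
    w.fx[i + 1] += gcx;  w.fy[i + 1] += gcy;  w.fz[i + 1] += gcz;
    w.fx[i] -= gax + gcx;  w.fy[i] -= gay + gcy;  w.fz[i] -= gaz + gcz;
  }

  double elong = 0.0;
  if (with_trap && p.ktrap > 0.0) {
    double dx = anchor_x - w.x[n - 1];
    double dy = -w.y[n - 1];
    double dz = -w.z[n - 1];
    double rd = std::sqrt(dx * dx + dy * dy + dz * dz);
    elong = rd - p.reql;
    if (rd > 1e-10) {
      double g = p.ktrap * elong / rd;    // pull toward anchor if stretched
      w.fx[n - 1] += g * dx;
      w.fy[n - 1] += g * dy;
      w.fz[n - 1] += g * dz;
    }
  }
  return elong;
}

double energy(const FragPar& p, const Work& w, double anchor_x, bool with_trap,
              double* ebond, double* ebend, double* etrap) {
  const int n = w.n;
  double eb = 0.0, ea = 0.0, et = 0.0;
  for (int i = 0; i < p.nb; ++i) {
    double dx = w.x[i + 1] - w.x[i], dy = w.y[i + 1] - w.y[i], dz = w.z[i + 1] - w.z[i];
    eb += bond_u(p, i, std::sqrt(dx * dx + dy * dy + dz * dz));
  }
  for (int i = 1; i < n - 1; ++i) {
    double ux = w.x[i - 1] - w.x[i], uy = w.y[i - 1] - w.y[i], uz = w.z[i - 1] - w.z[i];
    double vxx = w.x[i + 1] - w.x[i], vyy = w.y[i + 1] - w.y[i], vzz = w.z[i + 1] - w.z[i];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vxx * vxx + vyy * vyy + vzz * vzz);
    double c = (ux * vxx + uy * vyy + uz * vzz) / (nu * nv);
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    double d = M_PI - std::acos(c);
    ea += 0.5 * p.ka[i - 1] * d * d;
  }
  if (with_trap && p.ktrap > 0.0) {
    double dx = anchor_x - w.x[n - 1], dy = -w.y[n - 1], dz = -w.z[n - 1];
    double el = std::sqrt(dx * dx + dy * dy + dz * dz) - p.reql;
    et = 0.5 * p.ktrap * el * el;
  }
  if (ebond) *ebond = eb;
  if (ebend) *ebend = ea;
  if (etrap) *etrap = et;
  return eb + ea + et;
}

// xoshiro256++ (Blackman & Vigna) with splitmix64 seeding, plus a
// Marsaglia-polar Gaussian; used instead of std::mt19937_64 +
// std::normal_distribution because the thermostat draws ~300 normals per
// time step and dominates the step cost otherwise.  Deterministic for a
// given integer seed on any platform.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {     // splitmix64
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {               // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  inline double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

Work make_work(NumericMatrix pos, NumericMatrix vel) {
  Work w;
  w.n = pos.nrow();
  w.x.resize(w.n); w.y.resize(w.n); w.z.resize(w.n);
  w.vx.assign(w.n, 0.0); w.vy.assign(w.n, 0.0); w.vz.assign(w.n, 0.0);
  w.fx.resize(w.n); w.fy.resize(w.n); w.fz.resize(w.n);
  for (int i = 0; i < w.n; ++i) {
    w.x[i] = pos(i, 0); w.y[i] = pos(i, 1); w.z[i] = pos(i, 2);
  }
  if (vel.nrow() == w.n) {
    for (int i = 0; i < w.n; ++i) {
      w.vx[i] = vel(i, 0); w.vy[i] = vel(i, 1); w.vz[i] = vel(i, 2);
    }
  }
  return w;
}

} // namespace

// [[Rcpp::export]]
List cg_energy(NumericMatrix pos, double anchor_x, List fr, bool with_trap = true) {
  FragPar p = unpack(fr);
  NumericMatrix novel(0, 3);
  Work w = make_work(pos, novel);
  double eb, ea, et;
  double tot = energy(p, w, anchor_x, with_trap, &eb, &ea, &et);
  return List::create(_["bond"] = eb, _["bend"] = ea, _["trap"] = et,
                      _["total"] = tot);
}

// [[Rcpp::export]]
NumericMatrix cg_forces(NumericMatrix pos, double anchor_x, List fr,
                        bool with_trap = true, bool constrained = false) {
  FragPar p = unpack(fr);
  NumericMatrix novel(0, 3);
  Work w = make_work(pos, novel);
  forces(p, w, anchor_x, with_trap);
  if (constrained) {
    w.fx[0] = w.fy[0] = w.fz[0] = 0.0;
    w.fy[w.n - 1] = w.fz[w.n - 1] = 0.0;
  }
  NumericMatrix out(w.n, 3);
  for (int i = 0; i < w.n; ++i) {
    out(i, 0) = w.fx[i]; out(i, 1) = w.fy[i]; out(i, 2) = w.fz[i];
  }
  return out;
}

// BAOAB splitting of the Langevin equation; one force evaluation per step.
// Constraints: bead 1 fully fixed (fix_first), last bead restricted to x
// motion (last_x_only).  Constrained components receive no kick, drift or
// noise, so the fixed coordinates are preserved bitwise.
// [[Rcpp::export]]
List cg_run(NumericMatrix pos, NumericMatrix vel, double anchor_x, List fr,
            double dt, double gamma, int n_equil, int n_prod,
            int sample_every, int seed,
            bool fix_first = true, bool last_x_only = true) {
  FragPar p = unpack(fr);
  Work w = make_work(pos, vel);
  const int n = w.n;
  const double m = p.mass;
  const double hdt = 0.5 * dt;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) / m);   // kBT = 1 internally

  Xoshiro rng(static_cast<uint64_t>(seed));

  const int i0 = fix_first ? 1 : 0;
  const int last = n - 1;

  if (fix_first) { w.vx[0] = w.vy[0] = w.vz[0] = 0.0; }
  if (last_x_only) { w.vy[last] = w.vz[last] = 0.0; }

  double elong = forces(p, w, anchor_x, true);

  // production accumulators
  double sum_f = 0.0, sum_lx = 0.0, sum_ke = 0.0;
  std::vector<double> sum_x(n, 0.0), sum_x2(n, 0.0);
  int n_samples = (sample_every > 0 && n_prod > 0) ? n_prod / sample_every : 0;
  NumericMatrix bond_samples(n_samples, p.nb);
  int isample = 0;

  const int n_total = n_equil + n_prod;
  for (int step = 0; step < n_total; ++step) {
    // B: half kick
    for (int i = i0; i < n; ++i) {
      w.vx[i] += hdt * w.fx[i] / m;
      if (i == last && last_x_only) continue;
      w.vy[i] += hdt * w.fy[i] / m;
      w.vz[i] += hdt * w.fz[i] / m;
    }
    // A: half drift
    for (int i = i0; i < n; ++i) {
      w.x[i] += hdt * w.vx[i];
      w.y[i] += hdt * w.vy[i];
      w.z[i] += hdt * w.vz[i];
    }
    // O: Ornstein-Uhlenbeck velocity update
    if (gamma > 0.0) {
      for (int i = i0; i < n; ++i) {
        w.vx[i] = c1 * w.vx[i] + c2 * rng.gauss();
        if (i == last && last_x_only) continue;
        w.vy[i] = c1 * w.vy[i] + c2 * rng.gauss();
        w.vz[i] = c1 * w.vz[i] + c2 * rng.gauss();
      }
    }
    // A: half drift
    for (int i = i0; i < n; ++i) {
      w.x[i] += hdt * w.vx[i];
      w.y[i] += hdt * w.vy[i];
      w.z[i] += hdt * w.vz[i];
    }
    elong = forces(p, w, anchor_x, true);
    // B: half kick
    for (int i = i0; i < n; ++i) {
      w.vx[i] += hdt * w.fx[i] / m;
      if (i == last && last_x_only) continue;
      w.vy[i] += hdt * w.fy[i] / m;
      w.vz[i] += hdt * w.fz[i] / m;
    }

    if ((step & 1023) == 0) {
      for (int i = 0; i < p.nb; ++i) {
        double dx = w.x[i + 1] - w.x[i], dy = w.y[i + 1] - w.y[i], dz = w.z[i + 1] - w.z[i];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (!std::isfinite(r) || r > 10.0 * p.r0[i])
          stop("integration failure: bond %d reached r = %.1f A at step %d",
               i + 1, r, step + 1);
      }
      if ((step & 65535) == 0) Rcpp::checkUserInterrupt();
    }

    if (step >= n_equil) {
      int ps = step - n_equil;
      sum_f += p.ktrap * elong;
      sum_lx += w.x[last] - w.x[0];
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += w.vx[i] * w.vx[i] + w.vy[i] * w.vy[i] + w.vz[i] * w.vz[i];
      sum_ke += 0.5 * m * ke;
      for (int i = 0; i < n; ++i) {
        sum_x[i] += w.x[i];
        sum_x2[i] += w.x[i] * w.x[i];
      }
      if (sample_every > 0 && (ps + 1) % sample_every == 0 && isample < n_samples) {
        for (int i = 0; i < p.nb; ++i) {
          double dx = w.x[i + 1] - w.x[i], dy = w.y[i + 1] - w.y[i], dz = w.z[i + 1] - w.z[i];
          bond_samples(isample, i) = std::sqrt(dx * dx + dy * dy + dz * dz);
        }
        ++isample;
      }
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = w.x[i]; pos_out(i, 1) = w.y[i]; pos_out(i, 2) = w.z[i];
    vel_out(i, 0) = w.vx[i]; vel_out(i, 1) = w.vy[i]; vel_out(i, 2) = w.vz[i];
  }
  double np = n_prod > 0 ? static_cast<double>(n_prod) : 1.0;
  NumericVector mean_x(n), var_x(n);
  for (int i = 0; i < n; ++i) {
    mean_x[i] = sum_x[i] / np;
    var_x[i] = sum_x2[i] / np - mean_x[i] * mean_x[i];
  }
  return List::create(
    _["pos"] = pos_out, _["vel"] = vel_out,
    _["mean_force"] = sum_f / np,          // kBT/A
    _["mean_lx"] = sum_lx / np,            // A
    _["mean_ke"] = sum_ke / np,            // kBT
    _["mean_x"] = mean_x, _["var_x"] = var_x,
    _["bond_samples"] = bond_samples,
    _["n_prod"] = n_prod, _["final_elong"] = elong);
}
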