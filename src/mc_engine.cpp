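// Condensed-history proton transport in a voxelized phantom under a uniform
// transverse magnetic field (B along +x, beam along +z).
// Physics per step: RK2 mean Bethe-Bloch energy loss, Bohr Gaussian energy
// straggling, Highland multiple Coulomb scattering (two independent
// transverse planes), analog nuclear removal with one representative
// forward-peaked secondary proton (the lateral halo), and an exact
// circular-arc magnetic push at the step-midpoint momentum.
// Constants and the stopping-power formula must match R/materials.R.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

static const double MP = 938.27208816;   // proton rest energy, MeV
static const double ME = 0.51099895;     // electron rest energy, MeV
static const double KB = 0.307075;       // MeV cm^2/mol

// --- deterministic RNG (mt19937_64 + Box-Muller), bit-stable across runs ---
struct Rng {
  std::mt19937_64 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {  // in (0, 1)
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

static inline double bethe_bloch(double E, double I_MeV, double ZA) {
  double gamma = 1.0 + E / MP;
  double b2g2 = (E * E + 2.0 * E * MP) / (MP * MP);
  double beta2 = b2g2 / (gamma * gamma);
  double r = ME / MP;
  double Tmax = 2.0 * ME * b2g2 / (1.0 + 2.0 * gamma * r + r * r);
  return KB * ZA / beta2 *
         (0.5 * std::log(2.0 * ME * b2g2 * Tmax / (I_MeV * I_MeV)) - beta2);
}

// [[Rcpp::export]]
List mc_simulate_cpp(double E0, double sigma_x, double sigma_y,
                     double x0, double y0,
                     IntegerVector mat_idx, IntegerVector dims,
                     NumericVector spacing, NumericVector origin,
                     NumericMatrix mat_props,  // cols: rho, I(eV), ZA, X0, lambda_nuc
                     double B, int n_hist, double step, double seed_d,
                     bool straggling, bool nuclear, bool mcs,
                     double nuclear_local_frac, double e_cut,
                     double e_nuc_min, int n_batches) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double xlo = origin[0] - dx / 2.0, ylo = origin[1] - dy / 2.0,
               zlo = origin[2] - dz / 2.0;
  const double xhi = xlo + nx * dx, yhi = ylo + ny * dy, zhi = zlo + nz * dz;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

  const int nmat = mat_props.nrow();
  std::vector<double> rho(nmat), I_MeV(nmat), ZA(nmat), X0(nmat), lam(nmat);
  for (int m = 0; m < nmat; ++m) {
    rho[m] = mat_props(m, 0);
    I_MeV[m] = mat_props(m, 1) * 1e-6;
    ZA[m] = mat_props(m, 2);
    X0[m] = mat_props(m, 3);
    lam[m] = mat_props(m, 4);
  }

  NumericVector values(nvox);          // accumulated energy, MeV
  std::vector<double> batch, sumsq;
  if (n_batches > 0) {
    batch.assign(nvox, 0.0);
    sumsq.assign(nvox, 0.0);
  }
  double *acc = (n_batches > 0) ? batch.data() : REAL(values);

  double E_scored = 0.0, E_escaped = 0.0, E_nuclear_lost = 0.0;
  Rng rng((uint64_t)seed_d);

  int per_batch = (n_batches > 0) ? (n_hist + n_batches - 1) / n_batches : n_hist;
  int hist_in_batch = 0;

  for (int h = 0; h < n_hist; ++h) {
    double x = x0 + sigma_x * rng.norm();
    double y = y0 + sigma_y * rng.norm();
    double z = zlo + 1e-9;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double E = E0, w = 1.0;

    for (int it = 0; it < 100000; ++it) {
      if (x < xlo || x >= xhi || y < ylo || y >= yhi || z < zlo || z >= zhi) {
        E_escaped += w * E;
        break;
      }
      int ix = (int)((x - xlo) / dx), iy = (int)((y - ylo) / dy),
          iz = (int)((z - zlo) / dz);
      R_xlen_t v = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
      int m = mat_idx[v] - 1;
      double lrho = rho[m] / 10.0;  // g/cm^2 per mm

      if (E <= e_cut) {  // residual below transport floor: deposit locally
        acc[v] += w * E; E_scored += w * E;
        break;
      }

      double h_mm = step;
      double dE = bethe_bloch(E, I_MeV[m], ZA[m]) * lrho * h_mm;
      if (dE > 0.2 * E) {            // refine near range end
        h_mm = step * 0.2 * E / dE;
        if (h_mm < 0.01) h_mm = 0.01;
        dE = bethe_bloch(E, I_MeV[m], ZA[m]) * lrho * h_mm;
      }
      double Em = E - dE / 2.0;
      if (Em <= e_cut) {             // cannot complete the step: stop here
        acc[v] += w * E; E_scored += w * E;
        break;
      }
      dE = bethe_bloch(Em, I_MeV[m], ZA[m]) * lrho * h_mm;
      if (dE > E) dE = E;
      if (straggling) {
        double b2g2 = (Em * Em + 2.0 * Em * MP) / (MP * MP);
        double g2 = (1.0 + Em / MP) * (1.0 + Em / MP);
        double beta2 = b2g2 / g2;
        double om2 = 0.1569 * ZA[m] * rho[m] * (h_mm / 10.0) *
                     (1.0 - beta2 / 2.0) / (1.0 - beta2);
        dE += std::sqrt(om2) * rng.norm();
        if (dE < 0.0) dE = 0.0;
        if (dE > E) dE = E;
      }

      // score ionization at the step midpoint
      double mx = x + ux * h_mm / 2.0, my = y + uy * h_mm / 2.0,
             mz = z + uz * h_mm / 2.0;
      R_xlen_t vm = v;
      if (mx >= xlo && mx < xhi && my >= ylo && my < yhi && mz >= zlo && mz < zhi) {
        int jx = (int)((mx - xlo) / dx), jy = (int)((my - ylo) / dy),
            jz = (int)((mz - zlo) / dz);
        vm = (R_xlen_t)jx + nx * ((R_xlen_t)jy + (R_xlen_t)ny * jz);
        acc[vm] += w * dE; E_scored += w * dE;
      } else {
        E_escaped += w * dE;
      }

      E -= dE;
      if (E < 0.0) E = 0.0;

      // nuclear interaction (analog): the primary is absorbed; a fraction
      // of its residual energy is carried off by one representative
      // forward-peaked secondary proton (the lateral halo), the rest is
      // treated as escaping (neutrals, short-range fragments). Energy
      // accounting is exact per event.
      if (nuclear && E > e_nuc_min && rng.unif() < lrho * h_mm / lam[m]) {
        double Esec = 0.5 * E;
        double wsec = w * nuclear_local_frac * E / Esec;
        E_nuclear_lost += (1.0 - nuclear_local_frac) * w * E;
        // emission direction: primary direction tilted by a Gaussian polar
        // angle (RMS 0.5 rad, the quasi-free scattering regime), uniform
        // azimuth
        double th = 0.5 * std::fabs(rng.norm());
        double phi = 6.283185307179586 * rng.unif();
        double e1x, e1y, e1z;
        if (std::fabs(uz) < 0.9) { e1x = -uy; e1y = ux; e1z = 0.0; }
        else { e1x = 1.0 - ux * ux; e1y = -ux * uy; e1z = -ux * uz; }
        double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
        e1x /= n1; e1y /= n1; e1z /= n1;
        double e2x = uy * e1z - uz * e1y;
        double e2y = uz * e1x - ux * e1z;
        double e2z = ux * e1y - uy * e1x;
        double st = std::sin(th), ct = std::cos(th);
        double cp = std::cos(phi), sp = std::sin(phi);
        double sx = ct * ux + st * (cp * e1x + sp * e2x);
        double sy = ct * uy + st * (cp * e1y + sp * e2y);
        double sz = ct * uz + st * (cp * e1z + sp * e2z);
        double px = x, py = y, pz = z, Es = Esec;
        for (int js = 0; js < 4000; ++js) {
          if (px < xlo || px >= xhi || py < ylo || py >= yhi ||
              pz < zlo || pz >= zhi) { E_escaped += wsec * Es; break; }
          int jx = (int)((px - xlo) / dx), jy = (int)((py - ylo) / dy),
              jz = (int)((pz - zlo) / dz);
          R_xlen_t vs = (R_xlen_t)jx + nx * ((R_xlen_t)jy + (R_xlen_t)ny * jz);
          int ms = mat_idx[vs] - 1;
          double hs = 2.0;
          double dEs = (Es > e_cut)
            ? bethe_bloch(Es, I_MeV[ms], ZA[ms]) * (rho[ms] / 10.0) * hs : Es;
          if (dEs >= Es - e_cut) {   // range end: deposit the remainder here
            acc[vs] += wsec * Es; E_scored += wsec * Es;
            break;
          }
          acc[vs] += wsec * dEs; E_scored += wsec * dEs;
          Es -= dEs;
          if (B != 0.0) {
            double ps = std::sqrt(Es * Es + 2.0 * Es * MP);
            double rs = ps / (0.299792458 * std::fabs(B));
            double dps = (B > 0 ? 1.0 : -1.0) * hs / rs;
            double cf = std::cos(dps), sf = std::sin(dps);
            double ny2 = sy * cf + sz * sf, nz2 = -sy * sf + sz * cf;
            sy = ny2; sz = nz2;
          }
          px += hs * sx; py += hs * sy; pz += hs * sz;
        }
        break;  // primary absorbed
      }

      // magnetic push: exact arc at midpoint momentum (rotation about +x)
      if (B != 0.0) {
        double p = std::sqrt(Em * Em + 2.0 * Em * MP);
        double r_mm = p / (0.299792458 * std::fabs(B));
        double dphi = (B > 0 ? 1.0 : -1.0) * h_mm / r_mm;
        double ch = std::cos(dphi / 2.0), sh = std::sin(dphi / 2.0);
        double hy = uy * ch + uz * sh, hz = -uy * sh + uz * ch;
        x += h_mm * ux; y += h_mm * hy; z += h_mm * hz;
        double cf = std::cos(dphi), sf = std::sin(dphi);
        double ny_ = uy * cf + uz * sf, nz_ = -uy * sf + uz * cf;
        uy = ny_; uz = nz_;
      } else {
        x += h_mm * ux; y += h_mm * uy; z += h_mm * uz;
      }

      // Highland multiple scattering, independent small rotations in the
      // two planes transverse to the current direction
      if (mcs) {
        double t = lrho * h_mm / X0[m];
        if (t > 0.0) {
          double p = std::sqrt(Em * Em + 2.0 * Em * MP);
          double betap = p * p / (Em + MP);  // beta * p, MeV
          double f = 1.0 + 0.038 * std::log(t);
          if (f < 0.1) f = 0.1;
          double th0 = 13.6 / betap * std::sqrt(t) * f;
          double a1 = th0 * rng.norm(), a2 = th0 * rng.norm();
          // orthonormal frame (e1, e2) transverse to u
          double e1x, e1y, e1z;
          if (std::fabs(uz) < 0.9) { e1x = -uy; e1y = ux; e1z = 0.0; }
          else { e1x = 1.0 - ux * ux; e1y = -ux * uy; e1z = -ux * uz; }
          double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
          e1x /= n1; e1y /= n1; e1z /= n1;
          double e2x = uy * e1z - uz * e1y;
          double e2y = uz * e1x - ux * e1z;
          double e2z = ux * e1y - uy * e1x;
          ux += a1 * e1x + a2 * e2x;
          uy += a1 * e1y + a2 * e2y;
          uz += a1 * e1z + a2 * e2z;
          double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nn; uy /= nn; uz /= nn;
        }
      }
    }

    if (n_batches > 0 && (++hist_in_batch == per_batch || h == n_hist - 1)) {
      double *tot = REAL(values);
      for (R_xlen_t i = 0; i < nvox; ++i) {
        tot[i] += batch[i];
        sumsq[i] += batch[i] * batch[i];
        batch[i] = 0.0;
      }
      hist_in_batch = 0;
    }
  }

  List out = List::create(
    _["values"] = values,
    _["E_in"] = (double)n_hist * E0,
    _["E_scored"] = E_scored,
    _["E_escaped"] = E_escaped,
    _["E_nuclear_lost"] = E_nuclear_lost);
  if (n_batches > 0) {
    out["batch_sumsq"] = NumericVector(sumsq.begin(), sumsq.end());
    out["n_batches"] = n_batches;
  }
  return out;
}
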