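// Metropolis Monte Carlo core for a bead-spring chain with explicit ions in a
// cubic periodic box. Energies are in kT. All nonbonded pairs (bead-bead,
// bead-ion, ion-ion) use the minimum-image convention with truncated Coulomb
// and WCA excluded volume; bonded neighbours add a harmonic bond computed on
// direct distances, so the chain itself is stored whole (beads are never
// wrapped, ions are). Pairwise parameters are precomputed into flat n x n
// tables so the O(n) move loops stay tight.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct System {
  int n, nb;
  double box, inv_box;
  double bond_k, bond_r0;
  double rcut2;
  std::vector<double> x, y, z;
  std::vector<double> sig2;     // n*n: squared mixed diameter
  std::vector<double> wcut2;    // n*n: squared WCA cutoff (2^(1/3) sig2)
  std::vector<double> ql;       // n*n: lambda_B * q_i * q_j

  // energy of particle i at (xi,yi,zi) interacting with j (nonbonded terms)
  inline double pair_u(int i, double xi, double yi, double zi, int j) const {
    const size_t k = (size_t)i * n + j;
    double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
    dx -= box * std::nearbyint(dx * inv_box);
    dy -= box * std::nearbyint(dy * inv_box);
    dz -= box * std::nearbyint(dz * inv_box);
    const double r2 = dx * dx + dy * dy + dz * dz;
    double u = 0.0;
    if (r2 < wcut2[k]) {
      const double s2 = sig2[k] / (r2 > 1e-12 ? r2 : 1e-12);
      const double s6 = s2 * s2 * s2;
      u += 4.0 * (s6 * s6 - s6) + 1.0;
    }
    const double q = ql[k];
    if (q != 0.0 && r2 < rcut2) u += q / std::sqrt(r2);
    return u;
  }

  inline double bond_u(double xi, double yi, double zi, int j) const {
    const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double d = r - bond_r0;
    return 0.5 * bond_k * d * d;
  }

  double delta_move(int i, double nx, double ny, double nz) const {
    double dE = 0.0;
    const double xi = x[i], yi = y[i], zi = z[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      dE += pair_u(i, nx, ny, nz, j) - pair_u(i, xi, yi, zi, j);
    }
    if (i < nb) {
      if (i > 0)      dE += bond_u(nx, ny, nz, i - 1) - bond_u(xi, yi, zi, i - 1);
      if (i < nb - 1) dE += bond_u(nx, ny, nz, i + 1) - bond_u(xi, yi, zi, i + 1);
    }
    return dE;
  }
};

inline bool metropolis(double dE) {
  if (dE <= 0.0) return true;
  if (dE > 700.0) return false;
  return unif_rand() < std::exp(-dE);
}

void rotation_from_axis_angle(double ux, double uy, double uz, double th,
                              double R[3][3]) {
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
  double c = std::cos(th), s = std::sin(th), t = 1.0 - c;
  R[0][0] = c + ux * ux * t;      R[0][1] = ux * uy * t - uz * s; R[0][2] = ux * uz * t + uy * s;
  R[1][0] = uy * ux * t + uz * s; R[1][1] = c + uy * uy * t;      R[1][2] = uy * uz * t - ux * s;
  R[2][0] = uz * ux * t - uy * s; R[2][1] = uz * uy * t + ux * s; R[2][2] = c + uz * uz * t;
}

} // namespace

// [[Rcpp::export]]
List mc_engine(NumericMatrix coords0, NumericVector charge, NumericVector diam,
               int n_beads, double bond_k, double bond_r0,
               double box, double lambda_b, double rcut,
               int n_sweeps, int equil_sweeps, int sample_interval,
               double max_disp, double pivot_prob) {
  System sys;
  const int n = coords0.nrow();
  sys.n = n;
  sys.nb = n_beads;
  sys.box = box;
  sys.inv_box = 1.0 / box;
  sys.bond_k = bond_k;
  sys.bond_r0 = bond_r0;
  sys.rcut2 = rcut * rcut;
  sys.x.resize(n); sys.y.resize(n); sys.z.resize(n);
  for (int i = 0; i < n; ++i) {
    sys.x[i] = coords0(i, 0); sys.y[i] = coords0(i, 1); sys.z[i] = coords0(i, 2);
  }
  sys.sig2.resize((size_t)n * n);
  sys.wcut2.resize((size_t)n * n);
  sys.ql.resize((size_t)n * n);
  const double two_13 = std::cbrt(2.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const size_t k = (size_t)i * n + j;
      const double sig = 0.5 * (diam[i] + diam[j]);
      sys.sig2[k] = sig * sig;
      sys.wcut2[k] = two_13 * sig * sig;
      sys.ql[k] = lambda_b * charge[i] * charge[j];
    }
  }

  const int n_prod = n_sweeps - equil_sweeps;
  const int nf = sample_interval > 0 ? n_prod / sample_interval : 0;
  NumericVector out(Dimension(n, 3, std::max(nf, 1)));

  long acc_d = 0, att_d = 0, acc_p = 0, att_p = 0;
  long tune_acc = 0, tune_att = 0;
  std::vector<int> moved_idx(n);
  std::vector<double> nx_v(n), ny_v(n), nz_v(n);
  int stored = 0;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    const bool in_equil = sweep <= equil_sweeps;
    for (int m = 0; m < n; ++m) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      const bool do_pivot = (i < sys.nb) && sys.nb >= 3 &&
        pivot_prob > 0.0 && unif_rand() < pivot_prob;
      if (do_pivot) {
        int p = 1 + (int)(unif_rand() * (sys.nb - 2));
        if (p >= sys.nb - 1) p = sys.nb - 2;
        int lo, hi;                      // moved range: the shorter tail
        if (p < sys.nb / 2) { lo = 0; hi = p - 1; } else { lo = p + 1; hi = sys.nb - 1; }
        double R[3][3];
        rotation_from_axis_angle(norm_rand(), norm_rand(), norm_rand(),
                                 (unif_rand() * 2.0 - 1.0) * M_PI, R);
        const double px = sys.x[p], py = sys.y[p], pz = sys.z[p];
        const int nm = hi - lo + 1;
        for (int k = 0; k < nm; ++k) {
          const int b = lo + k;
          const double vx = sys.x[b] - px, vy = sys.y[b] - py, vz = sys.z[b] - pz;
          nx_v[k] = px + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
          ny_v[k] = py + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
          nz_v[k] = pz + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
        }
        // rigid rotation: intra-segment distances and distances to the
        // anchor are preserved; only segment vs the rest changes
        double dE = 0.0;
        for (int k = 0; k < nm; ++k) {
          const int b = lo + k;
          for (int j = 0; j < n; ++j) {
            if ((j >= lo && j <= hi) || j == p) continue;
            dE += sys.pair_u(b, nx_v[k], ny_v[k], nz_v[k], j)
                - sys.pair_u(b, sys.x[b], sys.y[b], sys.z[b], j);
          }
          if (dE > 1e6) break;
        }
        ++att_p;
        if (metropolis(dE)) {
          for (int k = 0; k < nm; ++k) {
            const int b = lo + k;
            sys.x[b] = nx_v[k]; sys.y[b] = ny_v[k]; sys.z[b] = nz_v[k];
          }
          ++acc_p;
        }
      } else {
        double nx = sys.x[i] + (unif_rand() * 2.0 - 1.0) * max_disp;
        double ny = sys.y[i] + (unif_rand() * 2.0 - 1.0) * max_disp;
        double nz = sys.z[i] + (unif_rand() * 2.0 - 1.0) * max_disp;
        const double dE = sys.delta_move(i, nx, ny, nz);
        ++att_d;
        if (in_equil) ++tune_att;
        if (metropolis(dE)) {
          if (i >= sys.nb) {                 // ions stay wrapped in the box
            nx -= box * std::floor(nx * sys.inv_box);
            ny -= box * std::floor(ny * sys.inv_box);
            nz -= box * std::floor(nz * sys.inv_box);
          }
          sys.x[i] = nx; sys.y[i] = ny; sys.z[i] = nz;
          ++acc_d;
          if (in_equil) ++tune_acc;
        }
      }
    }
    if (in_equil) {
      if (sweep % 200 == 0 && tune_att > 0) {   // auto-tune the step size
        const double acc = (double)tune_acc / (double)tune_att;
        if (acc > 0.5) max_disp *= 1.15;
        else if (acc < 0.3) max_disp *= 0.85;
        if (max_disp > box / 4.0) max_disp = box / 4.0;
        if (max_disp < 0.01) max_disp = 0.01;
        tune_acc = tune_att = 0;
      }
      if (sweep == equil_sweeps) { acc_d = att_d = acc_p = att_p = 0; }
    } else {
      const int s = sweep - equil_sweeps;
      if (sample_interval > 0 && s % sample_interval == 0 && stored < nf) {
        double* base = REAL(out) + (R_xlen_t)stored * n * 3;
        for (int i = 0; i < n; ++i) {
          base[i] = sys.x[i];
          base[n + i] = sys.y[i];
          base[2 * n + i] = sys.z[i];
        }
        ++stored;
      }
    }
    if (sweep % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["coords"] = out,
    _["n_frames"] = stored,
    _["acc_disp"] = att_d > 0 ? (double)acc_d / (double)att_d : NA_REAL,
    _["acc_pivot"] = att_p > 0 ? (double)acc_p / (double)att_p : NA_REAL,
    _["max_disp"] = max_disp);
}
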