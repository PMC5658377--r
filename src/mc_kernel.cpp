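#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Metropolis kernel for the primitive model: charged hard spheres with bare
// Coulomb interactions (energies in kBT, lengths in Angstrom) inside a closed
// hard-wall rectangular cell.  Particle 0 is the frozen nanoparticle; when
// `mobile` is true, particle 1 is the second nanoparticle, restricted to
// x-axis motion under a harmonic tether of stiffness k (kBT/A^2) with rest
// length x0 to particle 0.  All remaining particles are ions.

namespace {

struct McState {
  int n;
  std::vector<double> x, y, z, rad, q;
  double Lx, Ly, Lz, lB;
};

// energy change of moving particle i to (xi,yi,zi), in one pass over the
// other particles; returns false if the trial position overlaps anything
inline bool delta_energy(const McState &s, int i, double xi, double yi,
                         double zi, double &du) {
  du = 0.0;
  const double qi = s.q[i], ri = s.rad[i];
  const double oxi = s.x[i], oyi = s.y[i], ozi = s.z[i];
  for (int j = 0; j < s.n; ++j) {
    if (j == i) continue;
    const double dx = xi - s.x[j], dy = yi - s.y[j], dz = zi - s.z[j];
    const double r2 = dx * dx + dy * dy + dz * dz;
    const double sig = ri + s.rad[j];
    if (r2 < sig * sig) return false;
    const double qq = qi * s.q[j];
    if (qq != 0.0) {
      const double ox = oxi - s.x[j], oy = oyi - s.y[j], oz = ozi - s.z[j];
      du += qq * s.lB *
            (1.0 / std::sqrt(r2) -
             1.0 / std::sqrt(ox * ox + oy * oy + oz * oz));
    }
  }
  return true;
}

inline bool in_wall(const McState &s, int i, double xi, double yi, double zi) {
  const double r = s.rad[i];
  return xi >= r && xi <= s.Lx - r && yi >= r && yi <= s.Ly - r &&
         zi >= r && zi <= s.Lz - r;
}

inline bool metro_accept(double du) {
  if (du <= 0.0) return true;
  if (du > 700.0) return false;
  return unif_rand() < std::exp(-du);
}

}  // namespace

// [[Rcpp::export]]
double total_energy_cpp(NumericMatrix pos, NumericVector radius,
                        NumericVector charge, double lB) {
  const int n = pos.nrow();
  double u = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      const double dz = pos(i, 2) - pos(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double sig = radius[i] + radius[j];
      if (r2 < sig * sig) return R_PosInf;
      const double qq = charge[i] * charge[j];
      if (qq != 0.0) u += qq * lB / std::sqrt(r2);
    }
  }
  return u;
}

// [[Rcpp::export]]
List mc_chain_cpp(NumericMatrix pos0, NumericVector radius,
                  NumericVector charge, NumericVector cell, double lB,
                  bool mobile, double k_kt, double x0, int n_ion_start,
                  int n_equil, int n_prod, double ion_step0, double np_step0,
                  int np_attempts, int frame_stride, bool tune,
                  bool store_frames) {
  McState s;
  s.n = pos0.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.rad.resize(s.n); s.q.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos0(i, 0); s.y[i] = pos0(i, 1); s.z[i] = pos0(i, 2);
    s.rad[i] = radius[i]; s.q[i] = charge[i];
  }
  s.Lx = cell[0]; s.Ly = cell[1]; s.Lz = cell[2]; s.lB = lB;

  const int n_ion = s.n - n_ion_start;
  double ion_step = ion_step0, np_step = np_step0;

  // running total energy (Coulomb only; spring handled in the NP move)
  double utot = total_energy_cpp(pos0, radius, charge, lB);
  if (!R_finite(utot)) stop("initial configuration contains an overlap");

  long long acc_ion = 0, try_ion = 0, acc_np = 0, try_np = 0;
  long long tune_acc_ion = 0, tune_try_ion = 0, tune_acc_np = 0,
            tune_try_np = 0;

  NumericVector dx_series(n_prod);
  const int n_frames =
      (store_frames && frame_stride > 0) ? n_prod / frame_stride : 0;
  NumericMatrix frames(n_frames, store_frames ? 3 * s.n : 0);
  int frame_at = 0;

  const int n_total = n_equil + n_prod;
  for (int sweep = 0; sweep < n_total; ++sweep) {
    const bool production = sweep >= n_equil;
    // one attempted displacement per ion
    for (int i = n_ion_start; i < s.n; ++i) {
      const double xi = s.x[i] + ion_step * (2.0 * unif_rand() - 1.0);
      const double yi = s.y[i] + ion_step * (2.0 * unif_rand() - 1.0);
      const double zi = s.z[i] + ion_step * (2.0 * unif_rand() - 1.0);
      ++try_ion; ++tune_try_ion;
      if (!in_wall(s, i, xi, yi, zi)) continue;
      double du;
      if (!delta_energy(s, i, xi, yi, zi, du)) continue;
      if (metro_accept(du)) {
        s.x[i] = xi; s.y[i] = yi; s.z[i] = zi;
        utot += du;
        ++acc_ion; ++tune_acc_ion;
      }
    }
    // several attempted x-axis displacements of the tethered nanoparticle
    if (mobile) {
      for (int t = 0; t < np_attempts; ++t) {
        const double xi = s.x[1] + np_step * (2.0 * unif_rand() - 1.0);
        ++try_np; ++tune_try_np;
        if (!in_wall(s, 1, xi, s.y[1], s.z[1])) continue;
        double du_coul;
        if (!delta_energy(s, 1, xi, s.y[1], s.z[1], du_coul)) continue;
        const double sep_new = std::fabs(xi - s.x[0]);
        const double sep_old = std::fabs(s.x[1] - s.x[0]);
        const double du = du_coul +
            0.5 * k_kt * ((sep_new - x0) * (sep_new - x0) -
                          (sep_old - x0) * (sep_old - x0));
        if (metro_accept(du)) {
          s.x[1] = xi;
          utot += du_coul;
          ++acc_np; ++tune_acc_np;
        }
      }
    }
    // step-size auto-tuning toward ~40% acceptance, equilibration only
    if (tune && !production && (sweep + 1) % 250 == 0) {
      if (tune_try_ion > 0) {
        const double a = double(tune_acc_ion) / double(tune_try_ion);
        double f = a / 0.4;
        f = std::max(0.5, std::min(2.0, f));
        ion_step = std::max(0.05, std::min(0.45 * std::min(s.Lx, std::min(s.Ly, s.Lz)), ion_step * f));
      }
      if (tune_try_np > 0) {
        const double a = double(tune_acc_np) / double(tune_try_np);
        double f = a / 0.4;
        f = std::max(0.5, std::min(2.0, f));
        np_step = std::max(0.002, std::min(2.0, np_step * f));
      }
      tune_acc_ion = tune_try_ion = tune_acc_np = tune_try_np = 0;
    }
    if (production) {
      const int ps = sweep - n_equil;
      dx_series[ps] =
          mobile ? std::fabs(s.x[1] - s.x[0]) - x0 : NA_REAL;
      if (store_frames && frame_stride > 0 && (ps + 1) % frame_stride == 0 &&
          frame_at < n_frames) {
        for (int i = 0; i < s.n; ++i) {
          frames(frame_at, 3 * i) = s.x[i];
          frames(frame_at, 3 * i + 1) = s.y[i];
          frames(frame_at, 3 * i + 2) = s.z[i];
        }
        ++frame_at;
      }
    }
    if ((sweep & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_final(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    pos_final(i, 0) = s.x[i]; pos_final(i, 1) = s.y[i];
    pos_final(i, 2) = s.z[i];
  }
  const double u_check = total_energy_cpp(pos_final, radius, charge, lB);

  return List::create(
      _["dx"] = dx_series, _["frames"] = frames, _["n_frames"] = frame_at,
      _["acc_ion"] = try_ion > 0 ? double(acc_ion) / double(try_ion) : NA_REAL,
      _["acc_np"] = try_np > 0 ? double(acc_np) / double(try_np) : NA_REAL,
      _["ion_step"] = ion_step, _["np_step"] = np_step,
      _["energy_running"] = utot, _["energy_recomputed"] = u_check,
      _["pos_final"] = pos_final, _["n_ion"] = n_ion);
}
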