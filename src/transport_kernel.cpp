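#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Condensed-history transport kernel. All physics coefficients
// (restricted stopping, effective charge, inverse nuclear mean free path,
// Bohr coefficient, radiation length, optional LQ coefficients) are
// precomputed in R on a uniform log-energy grid and interpolated here.
// Uses R's RNG so a set.seed() in R makes runs bit-reproducible.

namespace {

struct LogGrid {
  double le0, dle;
  int n;
  double idx(double E) const {
    double x = (std::log(E) - le0) / dle;
    if (x < 0) x = 0;
    if (x > n - 1.000001) x = n - 1.000001;
    return x;
  }
};

inline double interp_row(const NumericMatrix &tab, int row, const LogGrid &g,
                         double E) {
  double x = g.idx(E);
  int i = (int)x;
  double f = x - i;
  return tab(row, i) * (1 - f) + tab(row, i + 1) * f;
}

inline double interp_vec(const NumericVector &v, const LogGrid &g, double E) {
  double x = g.idx(E);
  int i = (int)x;
  double f = x - i;
  return v[i] * (1 - f) + v[i + 1] * f;
}

} // namespace

// [[Rcpp::export(name = ".run_transport_cpp")]]
List run_transport_cpp(IntegerVector mat_index, NumericVector density_scale,
                       IntegerVector dims, NumericVector spacing_cm,
                       NumericVector mat_density, NumericVector logE_grid,
                       NumericMatrix S_rest, NumericMatrix inv_lambda,
                       NumericVector bohr_coef, NumericVector X0,
                       NumericVector zeff_grid, NumericVector alpha_grid,
                       NumericVector beta_grid, bool has_lq,
                       double proj_mass, int proj_A, int proj_z,
                       double E0, double sigE, double sx, double sy,
                       NumericVector pos0_cm, NumericVector dir0,
                       int n_primaries,
                       double f_max, bool straggle, bool mcs, int nuclear_mode,
                       double local_frac, double fwd_frac, double tail_mfp,
                       double e_cutoff, int n_batches,
                       NumericVector fluence_edges) {
  RNGScope scope;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing_cm[0], dy = spacing_cm[1], dz = spacing_cm[2];
  const double Lx = nx * dx, Ly = ny * dy, Lz = nz * dz;
  const int nvox = nx * ny * nz;

  LogGrid grid;
  grid.le0 = logE_grid[0];
  grid.dle = logE_grid[1] - logE_grid[0];
  grid.n = logE_grid.size();

  const int nEf = fluence_edges.size() - 1;
  const double lf0 = std::log(fluence_edges[0]);
  const double dlf = std::log(fluence_edges[1]) - lf0;

  NumericVector dose(nvox);
  NumericMatrix slice_batch(nz, n_batches);
  NumericMatrix fluence(nz, nEf);
  NumericVector crossings(nz);
  NumericVector sum_d(has_lq ? nvox : 1), sum_da(has_lq ? nvox : 1),
      sum_db(has_lq ? nvox : 1);

  double led_input = 0, led_dep = 0, led_geom = 0, led_nucl = 0, led_tail = 0;
  const double me = 0.51099895;

  for (int ip = 0; ip < n_primaries; ++ip) {
    int batch = (int)(((double)ip * n_batches) / n_primaries);
    double E = E0;
    if (sigE > 0) {
      E = E0 + sigE * R::norm_rand();
      if (E < 2 * e_cutoff) E = 2 * e_cutoff;
    }
    double px = pos0_cm[0] + (sx > 0 ? sx * R::norm_rand() : 0.0);
    double py = pos0_cm[1] + (sy > 0 ? sy * R::norm_rand() : 0.0);
    double pz = pos0_cm[2];
    double ux = dir0[0], uy = dir0[1], uz = dir0[2];
    led_input += E * proj_A;

    // clip ray to the phantom box if starting outside
    bool alive = true;
    if (px < 0 || px >= Lx || py < 0 || py >= Ly || pz < 0 || pz >= Lz) {
      double tmin = 0, tmax = 1e30;
      double pp[3] = {px, py, pz}, uu[3] = {ux, uy, uz},
             LL[3] = {Lx, Ly, Lz};
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(uu[a]) < 1e-12) {
          if (pp[a] < 0 || pp[a] >= LL[a]) { alive = false; break; }
        } else {
          double t1 = (0 - pp[a]) / uu[a], t2 = (LL[a] - pp[a]) / uu[a];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
        }
      }
      if (!alive || tmax <= tmin) {
        led_geom += E * proj_A;
        continue;
      }
      px += ux * (tmin + 1e-9);
      py += uy * (tmin + 1e-9);
      pz += uz * (tmin + 1e-9);
    }

    int last_k = -1;
    for (int istep = 0; istep < 200000 && alive; ++istep) {
      int i = (int)std::floor(px / dx), j = (int)std::floor(py / dy),
          k = (int)std::floor(pz / dz);
      if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
        led_geom += E * proj_A;
        break;
      }
      if (k != last_k) { crossings[k] += 1.0; last_k = k; }
      int v = i + nx * (j + ny * k);
      int m = mat_index[v] - 1;
      double rho = mat_density[m] * density_scale[v];

      // chord to the next voxel face along the current direction
      double tb = 1e30;
      if (ux > 1e-12) tb = std::min(tb, ((i + 1) * dx - px) / ux);
      else if (ux < -1e-12) tb = std::min(tb, (i * dx - px) / ux);
      if (uy > 1e-12) tb = std::min(tb, ((j + 1) * dy - py) / uy);
      else if (uy < -1e-12) tb = std::min(tb, (j * dy - py) / uy);
      if (uz > 1e-12) tb = std::min(tb, ((k + 1) * dz - pz) / uz);
      else if (uz < -1e-12) tb = std::min(tb, (k * dz - pz) / uz);
      double chord = tb + 1e-7;

      double step, mean_loss = 0;
      if (rho <= 1e-12) {          // vacuum drift
        step = chord;
      } else {
        double S = interp_row(S_rest, m, grid, E) * rho;  // MeV/cm
        step = f_max * (E * proj_A) / S;
        if (step > chord) step = chord;
        if (step < 1e-6) step = 1e-6;
        mean_loss = S * step;
        double Emid = E - 0.5 * mean_loss / proj_A;
        if (Emid > e_cutoff)
          mean_loss = interp_row(S_rest, m, grid, Emid) * rho * step;
      }

      double gamma = 1.0 + E * proj_A / proj_mass;
      double beta2 = 1.0 - 1.0 / (gamma * gamma);

      double loss = mean_loss;
      if (straggle && rho > 1e-12) {
        double zeff = interp_vec(zeff_grid, grid, E);
        double var = bohr_coef[m] * zeff * zeff * rho * step *
                     (1 - beta2 / 2) / (1 - beta2);
        loss = mean_loss + std::sqrt(var) * R::norm_rand();
        if (loss < 0) loss = 0;
        if (loss > E * proj_A) loss = E * proj_A;
      }

      // scoring
      if (loss > 0) {
        dose[v] += loss;
        slice_batch(k, batch) += loss;
        if (has_lq) {
          double al = interp_vec(alpha_grid, grid, E);
          double be = interp_vec(beta_grid, grid, E);
          sum_d[v] += loss;
          sum_da[v] += loss * al;
          sum_db[v] += loss * be;
        }
        led_dep += loss;
      }
      if (E >= fluence_edges[0] && E < fluence_edges[nEf]) {
        int eb = (int)((std::log(E) - lf0) / dlf);
        if (eb >= 0 && eb < nEf) fluence(k, eb) += step;
      }

      double Enew = E - loss / proj_A;

      // nuclear interaction over this step
      if (nuclear_mode > 0 && rho > 1e-12) {
        double il = interp_row(inv_lambda, m, grid, E) * density_scale[v];
        double psurv = std::exp(-il * step);
        if (R::unif_rand() > psurv) {
          double Eres = std::max(Enew, 0.0) * proj_A;
          if (nuclear_mode == 1) {
            led_nucl += Eres;
          } else {
            double eloc = local_frac * Eres, etail = fwd_frac * Eres;
            double eesc = Eres - eloc - etail;
            dose[v] += eloc;
            slice_batch(k, batch) += eloc;
            led_dep += eloc;
            if (has_lq) {
              double al = interp_vec(alpha_grid, grid, std::max(Enew, e_cutoff));
              double be = interp_vec(beta_grid, grid, std::max(Enew, e_cutoff));
              sum_d[v] += eloc;
              sum_da[v] += eloc * al;
              sum_db[v] += eloc * be;
            }
            // exponential forward tail down the (i, j) column
            if (etail > 0) {
              double placed = 0;
              double z0 = pz;
              for (int kk = k; kk < nz; ++kk) {
                double za = std::max(kk * dz, z0), zb = (kk + 1) * dz;
                if (zb <= z0) continue;
                double w = std::exp(-(za - z0) / tail_mfp) -
                           std::exp(-(zb - z0) / tail_mfp);
                double e = etail * w;
                int vv = i + nx * (j + ny * kk);
                dose[vv] += e;
                slice_batch(kk, batch) += e;
                if (has_lq) {
                  double al = interp_vec(alpha_grid, grid,
                                         std::max(Enew, e_cutoff));
                  double be = interp_vec(beta_grid, grid,
                                         std::max(Enew, e_cutoff));
                  sum_d[vv] += e;
                  sum_da[vv] += e * al;
                  sum_db[vv] += e * be;
                }
                placed += e;
              }
              led_dep += placed;
              led_tail += etail - placed;  // beyond the distal face
            }
            led_nucl += eesc;
          }
          alive = false;
          break;
        }
      }

      E = Enew;
      if (E <= e_cutoff) {       // stop: deposit residual locally
        double res = E * proj_A;
        if (res > 0) {
          dose[v] += res;
          slice_batch(k, batch) += res;
          if (has_lq) {
            double al = interp_vec(alpha_grid, grid, e_cutoff);
            double be = interp_vec(beta_grid, grid, e_cutoff);
            sum_d[v] += res;
            sum_da[v] += res * al;
            sum_db[v] += res * be;
          }
          led_dep += res;
        }
        break;
      }

      // move and scatter
      px += ux * step;
      py += uy * step;
      pz += uz * step;
      if (mcs && rho > 1e-12) {
        double t_x0 = step * rho / X0[m];
        if (t_x0 > 0) {
          double p_mom = gamma * proj_mass * std::sqrt(beta2);
          double fac = 1 + 0.038 * std::log(t_x0);
          if (fac < 0) fac = 0;
          double th0 = 13.6 / (std::sqrt(beta2) * p_mom) * proj_z *
                       std::sqrt(t_x0) * fac;
          if (th0 > 0) {
            double t1 = th0 * R::norm_rand(), t2 = th0 * R::norm_rand();
            // orthonormal transverse basis
            double ax = -uy, ay = ux, az = 0;
            double an = std::sqrt(ax * ax + ay * ay);
            if (an < 1e-9) { ax = 1; ay = 0; az = 0; an = 1; }
            ax /= an; ay /= an; az /= an;
            double bx = uy * az - uz * ay, by = uz * ax - ux * az,
                   bz = ux * ay - uy * ax;
            ux += t1 * ax + t2 * bx;
            uy += t1 * ay + t2 * by;
            uz += t1 * az + t2 * bz;
            double un = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= un; uy /= un; uz /= un;
          }
        }
      }
    }
  }

  (void)me;
  return List::create(
      _["dose"] = dose, _["slice_batch"] = slice_batch,
      _["fluence"] = fluence, _["crossings"] = crossings,
      _["sum_d"] = sum_d, _["sum_da"] = sum_da, _["sum_db"] = sum_db,
      _["ledger"] = List::create(
          _["input"] = led_input, _["deposited"] = led_dep,
          _["escaped_geometry"] = led_geom, _["nuclear_escaped"] = led_nucl,
          _["tail_escaped"] = led_tail));
}
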