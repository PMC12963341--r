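#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Euler-Maruyama stepper for point ions in a periodic box with a
// solid membrane slab pierced by a cylindrical pore on the box axis.
//
// Units: nm, ns, forces expressed as F/kT in 1/nm so that the drift per step
// is D * (F/kT) * dt. The axial electric force acts only inside the slab.
// The optional constriction is a Gaussian well in z for one species plus
// (optionally) single-occupancy exclusion of the window: while a well-bound
// ion sits inside the window, no other ion may enter it.
//
// Randomness comes from R's RNG (norm_rand), so set.seed() in R makes runs
// bitwise reproducible.

static inline bool in_interval(double v, double lo, double hi) {
  return v > lo && v < hi;
}

// [[Rcpp::export]]
List bd_core(int n_steps, int save_every,
             NumericVector x0, NumericVector y0, NumericVector z0,
             NumericVector D, NumericVector fE,
             NumericVector box,
             double slab_lo, double slab_hi, double pore_r,
             double dt,
             bool trap_on, double trap_z0, double trap_w, double trap_depth,
             LogicalVector trap_species, bool trap_exclusive) {
  const int n = x0.size();
  const double bx = box[0], by = box[1], bz = box[2];
  const double cx = bx / 2.0, cy = by / 2.0;
  const double win_lo = trap_z0 - trap_w, win_hi = trap_z0 + trap_w;

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> z(z0.begin(), z0.end());

  const int n_saved = n_steps / save_every + 1;
  NumericMatrix X(n_saved, n), Y(n_saved, n), Z(n_saved, n);
  for (int i = 0; i < n; ++i) { X(0, i) = x[i]; Y(0, i) = y[i]; Z(0, i) = z[i]; }

  // current occupant of the constriction window (-1 = empty)
  int occ = -1;
  if (trap_on && trap_exclusive) {
    for (int i = 0; i < n; ++i)
      if (trap_species[i] && in_interval(z[i], win_lo, win_hi)) { occ = i; break; }
  }

  std::vector<double> sig(n), drift_scale(n);
  for (int i = 0; i < n; ++i) {
    sig[i] = std::sqrt(2.0 * D[i] * dt);
    drift_scale[i] = D[i] * dt;
  }

  int save_row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      const double zi = z[i];
      const bool in_slab_old = in_interval(zi, slab_lo, slab_hi);

      // force/kT in 1/nm, evaluated at the current position
      double f = 0.0;
      if (in_slab_old) {
        f += fE[i];
        if (trap_on && trap_species[i] && trap_depth != 0.0) {
          const double dz = zi - trap_z0;
          f += -trap_depth * dz / (trap_w * trap_w) *
               std::exp(-dz * dz / (2.0 * trap_w * trap_w));
        }
      }

      double xn = x[i] + sig[i] * norm_rand();
      double yn = y[i] + sig[i] * norm_rand();
      double zn = zi + drift_scale[i] * f + sig[i] * norm_rand();

      // periodic wrap
      xn -= bx * std::floor(xn / bx);
      yn -= by * std::floor(yn / by);
      zn -= bz * std::floor(zn / bz);

      // membrane / pore-wall collisions
      if (in_interval(zn, slab_lo, slab_hi)) {
        const double dx = xn - cx, dy = yn - cy;
        const double r = std::sqrt(dx * dx + dy * dy);
        if (r > pore_r) {
          if (!in_slab_old) {
            // tried to enter the solid membrane from a reservoir: reflect z
            if (zi <= slab_lo) zn = 2.0 * slab_lo - zn;
            else               zn = 2.0 * slab_hi - zn;
          } else {
            // inside the pore, drifted into the wall: reflect radially
            const double rr = 2.0 * pore_r - r;
            if (rr > 0 && r > 0) {
              xn = cx + dx * rr / r;
              yn = cy + dy * rr / r;
            } else { xn = x[i]; yn = y[i]; }
          }
          // a pathological double violation: keep the old position
          if (in_interval(zn, slab_lo, slab_hi)) {
            const double dx2 = xn - cx, dy2 = yn - cy;
            if (std::sqrt(dx2 * dx2 + dy2 * dy2) > pore_r) {
              xn = x[i]; yn = y[i]; zn = zi;
            }
          }
        }
      }

      // single-occupancy exclusion of the constriction window
      if (trap_on && trap_exclusive && occ >= 0 && occ != i &&
          in_interval(zn, win_lo, win_hi)) {
        if (zi <= win_lo)      zn = 2.0 * win_lo - zn;
        else if (zi >= win_hi) zn = 2.0 * win_hi - zn;
        else                   zn = zi;  // started inside (initialization edge)
        if (in_interval(zn, win_lo, win_hi) &&
            !in_interval(zi, win_lo, win_hi)) zn = zi;
      }

      x[i] = xn; y[i] = yn; z[i] = zn;

      if (trap_on && trap_exclusive) {
        const bool inside_win = in_interval(zn, win_lo, win_hi);
        if (occ == i && !inside_win) occ = -1;
        if (occ == -1 && trap_species[i] && inside_win) occ = i;
      }
    }
    if (step % save_every == 0) {
      for (int i = 0; i < n; ++i) {
        X(save_row, i) = x[i]; Y(save_row, i) = y[i]; Z(save_row, i) = z[i];
      }
      ++save_row;
    }
  }

  return List::create(_["x"] = X, _["y"] = Y, _["z"] = Z);
}
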