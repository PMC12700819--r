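#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) dynamics of a typed bead chain
// in reduced units (monomer diameter a = 1, kT = 1). Nonbonded forces
// come from the smooth square-well potential (soft repulsive core of
// height E_repel for r < 1, homotypic attraction of depth eps between
// 1 and 1.5, zero beyond), evaluated through a linked-cell neighbor
// search with cell size 1.5. Chain and extruder-bridge bonds are
// harmonic with one shared stiffness. Confinement is a one-sided
// harmonic wall penalty for a sphere or a cylinder (axis z); two walls
// with independent stiffness ramps implement shape crossovers.

static const double A0 = std::sqrt(6.0 / 7.0);
static const double E0C = 46656.0 / 823543.0;
static const double RCUT = 1.5;

// Cell-sorted neighbor structure: particles are counting-sorted by
// cell so that per-cell particle data are contiguous; pair traversal
// visits each cell's own tail plus a half shell of 13 forward
// neighbor cells, so every pair is seen exactly once.
struct CellList {
  double x0, y0, z0, cs;
  int nx, ny, nz, n;
  std::vector<int> start, order, cell_id, cnt;
  std::vector<double> xs, ys, zs;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, int n_, double cellsize) {
    n = n_; cs = cellsize;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)((xmax - xmin) / cs) + 1);
    ny = std::max(1, (int)((ymax - ymin) / cs) + 1);
    nz = std::max(1, (int)((zmax - zmin) / cs) + 1);
    size_t nc = (size_t)nx * ny * nz;
    cell_id.resize(n);
    cnt.assign(nc + 1, 0);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(x[i], y[i], z[i]);
      cell_id[i] = c;
      cnt[c + 1]++;
    }
    for (size_t c = 0; c < nc; ++c) cnt[c + 1] += cnt[c];
    start = cnt;
    order.resize(n); xs.resize(n); ys.resize(n); zs.resize(n);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) {
      int pos = fill[cell_id[i]]++;
      order[pos] = i;
      xs[pos] = x[i]; ys[pos] = y[i]; zs[pos] = z[i];
    }
  }
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  inline int cell_of(double xi, double yi, double zi) const {
    int cx = clampi((int)((xi - x0) / cs), nx);
    int cy = clampi((int)((yi - y0) / cs), ny);
    int cz = clampi((int)((zi - z0) / cs), nz);
    return (cz * ny + cy) * nx + cx;
  }
};

// half-shell offsets: self handled separately; these 13 cover each
// unordered cell pair once
static const int HS[13][3] = {
  {1,0,0}, {0,1,0}, {0,0,1}, {1,1,0}, {1,-1,0}, {1,0,1}, {1,0,-1},
  {0,1,1}, {0,1,-1}, {1,1,1}, {1,1,-1}, {1,-1,1}, {1,-1,-1}};

// radial force magnitude over r: returns fr such that F = fr * dvec
// (dvec = xi - xj), i.e. fr = -(dU/dr)/r
static inline double pair_fr(double r2, double eps, double E_repel) {
  if (r2 >= RCUT * RCUT) return 0.0;
  double r = std::sqrt(r2);
  if (r < 1e-12) return 0.0;
  if (r < 1.0) {
    double x = A0 * r;
    double x2 = x * x, x4 = x2 * x2, x11 = x4 * x4 * x2 * x;
    double dUdr = E_repel / E0C * (14.0 * x2 * x11 - 12.0 * x11) * A0;
    return -dUdr / r;
  }
  if (eps == 0.0) return 0.0;
  double w = 0.25;                    // (a* - a) / 2
  double x = A0 * (r - 1.25) / w;     // midpoint (a + a*)/2 = 1.25
  double x2 = x * x, x4 = x2 * x2, x11 = x4 * x4 * x2 * x;
  double dUdr = -eps / E0C * (14.0 * x2 * x11 - 12.0 * x11) * A0 / w;
  return -dUdr / r;
}

// [[Rcpp::export]]
List run_polymer_cpp(NumericMatrix coords0, IntegerVector type,
                     NumericVector eps_type, double E_repel,
                     double k_bond, double r0,
                     double dt, double gamma,
                     int n_blocks, int steps_per_block,
                     List bridges, IntegerVector bridge_block,
                     NumericMatrix conf,
                     NumericVector tether_k, NumericVector tether_z,
                     int sample_every, bool pairs_on) {
  int n = coords0.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  // Leimkuhler-Matthews (BAOAB-limit) overdamped integrator: the
  // noise increment is the average of consecutive Gaussians, giving
  // O(dt^2) accuracy of configurational averages at Euler cost.
  std::vector<double> gx(n), gy(n), gz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
    gx[i] = norm_rand(); gy[i] = norm_rand(); gz[i] = norm_rand();
  }
  double mob = dt / gamma;
  double noise = std::sqrt(2.0 * dt / gamma) * 0.5;
  CellList cl;
  List frames;
  std::vector<int> frame_block;

  // current bridge set (0-based columns: left, right)
  std::vector<int> bl, br;
  int bridge_ptr = 0;

  for (int blk = 0; blk < n_blocks; ++blk) {
    // update bridges scheduled for this block
    while (bridge_ptr < bridge_block.size() &&
           bridge_block[bridge_ptr] == blk) {
      IntegerMatrix bm = bridges[bridge_ptr];
      bl.assign(bm.nrow(), 0); br.assign(bm.nrow(), 0);
      for (int k = 0; k < bm.nrow(); ++k) {
        bl[k] = bm(k, 0); br[k] = bm(k, 1);
        if (bl[k] < 0 || br[k] >= n)
          stop("bridge bond outside the chain");
      }
      bridge_ptr++;
    }
    // confinement parameters for this block:
    // columns: shapeA, RA, HA, kA, shapeB, RB, HB, kB  (shape 0 none,
    // 1 sphere, 2 cylinder)
    double wall[2][4];
    for (int wgrp = 0; wgrp < 2; ++wgrp)
      for (int c = 0; c < 4; ++c) wall[wgrp][c] = conf(blk, 4 * wgrp + c);
    double tk = tether_k[blk], tz = tether_z[blk];

    for (int s = 0; s < steps_per_block; ++s) {
      std::fill(fx.begin(), fx.end(), 0.0);
      std::fill(fy.begin(), fy.end(), 0.0);
      std::fill(fz.begin(), fz.end(), 0.0);
      // chain bonds
      for (int i = 0; i + 1 < n; ++i) {
        double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i],
               dz = z[i + 1] - z[i];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-12) continue;
        double f = k_bond * (r - r0) / r;
        fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
        fx[i + 1] -= f * dx; fy[i + 1] -= f * dy; fz[i + 1] -= f * dz;
      }
      // bridge bonds
      for (size_t k = 0; k < bl.size(); ++k) {
        int i = bl[k], j = br[k];
        if (i == j) continue;
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-12) continue;
        double f = k_bond * (r - r0) / r;
        fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
        fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
      }
      // nonbonded pairs via cell-sorted half-shell traversal
      if (pairs_on) {
        cl.build(x, y, z, n, RCUT);
        double rc2 = RCUT * RCUT;
        for (int cz2 = 0; cz2 < cl.nz; ++cz2)
        for (int cy2 = 0; cy2 < cl.ny; ++cy2)
        for (int cx2 = 0; cx2 < cl.nx; ++cx2) {
          int c = (cz2 * cl.ny + cy2) * cl.nx + cx2;
          int a0 = cl.start[c], a1 = cl.start[c + 1];
          if (a0 == a1) continue;
          // pairs within the cell
          for (int a = a0; a < a1; ++a) {
            int i = cl.order[a];
            double xi = cl.xs[a], yi = cl.ys[a], zi = cl.zs[a];
            for (int b = a + 1; b < a1; ++b) {
              double dx = cl.xs[b] - xi, dy = cl.ys[b] - yi,
                     dz = cl.zs[b] - zi;
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= rc2) continue;
              int j = cl.order[b];
              double eps = (type[i] == type[j]) ? eps_type[type[i]]
                                                : 0.0;
              double fr = pair_fr(r2, eps, E_repel);
              if (fr != 0.0) {
                fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
                fx[j] += fr * dx; fy[j] += fr * dy; fz[j] += fr * dz;
              }
            }
          }
          // pairs with the 13 forward neighbor cells
          for (int h = 0; h < 13; ++h) {
            int ax = cx2 + HS[h][0], ay = cy2 + HS[h][1],
                az = cz2 + HS[h][2];
            if (ax < 0 || ax >= cl.nx || ay < 0 || ay >= cl.ny ||
                az < 0 || az >= cl.nz) continue;
            int c2 = (az * cl.ny + ay) * cl.nx + ax;
            int b0 = cl.start[c2], b1 = cl.start[c2 + 1];
            for (int a = a0; a < a1; ++a) {
              int i = cl.order[a];
              double xi = cl.xs[a], yi = cl.ys[a], zi = cl.zs[a];
              for (int b = b0; b < b1; ++b) {
                double dx = cl.xs[b] - xi, dy = cl.ys[b] - yi,
                       dz = cl.zs[b] - zi;
                double r2 = dx * dx + dy * dy + dz * dz;
                if (r2 >= rc2) continue;
                int j = cl.order[b];
                double eps = (type[i] == type[j]) ? eps_type[type[i]]
                                                  : 0.0;
                double fr = pair_fr(r2, eps, E_repel);
                if (fr != 0.0) {
                  fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
                  fx[j] += fr * dx; fy[j] += fr * dy; fz[j] += fr * dz;
                }
              }
            }
          }
        }
      }
      // confinement walls
      for (int wgrp = 0; wgrp < 2; ++wgrp) {
        int shape = (int)wall[wgrp][0];
        double R = wall[wgrp][1], H = wall[wgrp][2], kw = wall[wgrp][3];
        if (shape == 0 || kw <= 0.0) continue;
        for (int i = 0; i < n; ++i) {
          if (shape == 1) {
            double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
            if (r > R && r > 1e-12) {
              double f = -kw * (r - R) / r;
              fx[i] += f * x[i]; fy[i] += f * y[i]; fz[i] += f * z[i];
            }
          } else {
            double rr = std::sqrt(x[i] * x[i] + y[i] * y[i]);
            if (rr > R && rr > 1e-12) {
              double f = -kw * (rr - R) / rr;
              fx[i] += f * x[i]; fy[i] += f * y[i];
            }
            if (z[i] > H) fz[i] += -kw * (z[i] - H);
            else if (z[i] < -H) fz[i] += -kw * (z[i] + H);
          }
        }
      }
      // end tethers (chain ends to cylinder poles on the z axis)
      if (tk > 0.0) {
        fx[0] += -tk * x[0]; fy[0] += -tk * y[0];
        fz[0] += -tk * (z[0] + tz);
        fx[n - 1] += -tk * x[n - 1]; fy[n - 1] += -tk * y[n - 1];
        fz[n - 1] += -tk * (z[n - 1] - tz);
      }
      // position update with averaged consecutive noises
      for (int i = 0; i < n; ++i) {
        double nx = norm_rand(), ny = norm_rand(), nz = norm_rand();
        x[i] += mob * fx[i] + noise * (gx[i] + nx);
        y[i] += mob * fy[i] + noise * (gy[i] + ny);
        z[i] += mob * fz[i] + noise * (gz[i] + nz);
        gx[i] = nx; gy[i] = ny; gz[i] = nz;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(z[i]))
        stop("non-finite coordinates at block %d (unstable timestep?)",
             blk + 1);
    }
    if (sample_every > 0 && ((blk + 1) % sample_every == 0)) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {
        fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
      }
      frames.push_back(fr);
      frame_block.push_back(blk + 1);
    }
  }
  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = x[i]; fin(i, 1) = y[i]; fin(i, 2) = z[i];
  }
  return List::create(_["frames"] = frames,
                      _["frame_block"] = wrap(frame_block),
                      _["final"] = fin);
}

// Count binned spatial contacts (distance <= radius) in one frame.
// [[Rcpp::export]]
NumericMatrix contact_count_cpp(NumericMatrix fr, double radius,
                                int bin, int nbins) {
  int n = fr.nrow();
  int nuse = nbins * bin;      // monomers beyond the last full bin dropped
  NumericMatrix m(nbins, nbins);
  std::vector<double> x(nuse), y(nuse), z(nuse);
  for (int i = 0; i < nuse; ++i) {
    x[i] = fr(i, 0); y[i] = fr(i, 1); z[i] = fr(i, 2);
  }
  CellList cl;
  cl.build(x, y, z, nuse, radius);
  double r2max = radius * radius;
  auto tally = [&](int i, int j) {
    int bi = i / bin, bj = j / bin;
    m(bi, bj) += 1.0;
    if (bi != bj) m(bj, bi) += 1.0;
  };
  for (int i = 0; i < nuse; ++i) m(i / bin, i / bin) += 1.0;  // self
  for (int cz2 = 0; cz2 < cl.nz; ++cz2)
  for (int cy2 = 0; cy2 < cl.ny; ++cy2)
  for (int cx2 = 0; cx2 < cl.nx; ++cx2) {
    int c = (cz2 * cl.ny + cy2) * cl.nx + cx2;
    int a0 = cl.start[c], a1 = cl.start[c + 1];
    if (a0 == a1) continue;
    for (int a = a0; a < a1; ++a) {
      double xi = cl.xs[a], yi = cl.ys[a], zi = cl.zs[a];
      for (int b = a + 1; b < a1; ++b) {
        double dx = cl.xs[b] - xi, dy = cl.ys[b] - yi,
               dz = cl.zs[b] - zi;
        if (dx * dx + dy * dy + dz * dz <= r2max)
          tally(cl.order[a], cl.order[b]);
      }
    }
    for (int h = 0; h < 13; ++h) {
      int ax = cx2 + HS[h][0], ay = cy2 + HS[h][1], az = cz2 + HS[h][2];
      if (ax < 0 || ax >= cl.nx || ay < 0 || ay >= cl.ny ||
          az < 0 || az >= cl.nz) continue;
      int c2 = (az * cl.ny + ay) * cl.nx + ax;
      int b0 = cl.start[c2], b1 = cl.start[c2 + 1];
      for (int a = a0; a < a1; ++a) {
        double xi = cl.xs[a], yi = cl.ys[a], zi = cl.zs[a];
        for (int b = b0; b < b1; ++b) {
          double dx = cl.xs[b] - xi, dy = cl.ys[b] - yi,
                 dz = cl.zs[b] - zi;
          if (dx * dx + dy * dy + dz * dz <= r2max)
            tally(cl.order[a], cl.order[b]);
        }
      }
    }
  }
  return m;
}
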