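#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 2D overdamped multi-agent dynamics: short-range polynomial
// adhesion/repulsion (PhysiCell-style potentials), Hooke elastic traction
// for pairs containing a microglia, and persistent random locomotion.
// Forward-Euler integration; uniform-grid neighbour search for the
// short-range terms. Uses R's RNG so seeded runs are reproducible.

struct Grid {
  double h, x0, y0;
  int ncx, ncy;
  std::vector<std::vector<int>> cells;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             double cell_size) {
    h = cell_size;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (size_t i = 1; i < x.size(); ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    x0 = xmin - h; y0 = ymin - h;
    ncx = (int)((xmax - x0) / h) + 2;
    ncy = (int)((ymax - y0) / h) + 2;
    cells.assign((size_t)ncx * ncy, {});
    for (size_t i = 0; i < x.size(); ++i)
      cells[idx(x[i], y[i])].push_back((int)i);
  }
  int idx(double px, double py) const {
    int cx = (int)((px - x0) / h), cy = (int)((py - y0) / h);
    if (cx < 0) cx = 0; if (cx >= ncx) cx = ncx - 1;
    if (cy < 0) cy = 0; if (cy >= ncy) cy = ncy - 1;
    return cy * ncx + cx;
  }
};

// [[Rcpp::export]]
List sim_run_cpp(NumericVector x_, NumericVector y_, IntegerVector kind,
                 NumericVector radius, NumericVector speed,
                 NumericVector tau, NumericVector crep, NumericVector cadh,
                 NumericVector dirx_, NumericVector diry_,
                 NumericVector timer_,
                 double k_elastic, double elastic_cutoff, double eta,
                 double adhesion_reach, double dt, int n_steps,
                 int snapshot_every) {
  int n = x_.size();
  std::vector<double> x(x_.begin(), x_.end()), y(y_.begin(), y_.end());
  std::vector<double> dirx(dirx_.begin(), dirx_.end()),
      diry(diry_.begin(), diry_.end()), timer(timer_.begin(), timer_.end());
  std::vector<double> fx(n), fy(n);
  std::vector<int> microglia;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (kind[i] == 2) microglia.push_back(i);
    rmax = std::max(rmax, radius[i]);
  }
  double reach_max = adhesion_reach * 2.0 * rmax;
  bool cutoff_finite = R_finite(elastic_cutoff);
  double cut2 = elastic_cutoff * elastic_cutoff;

  int n_snap = n_steps / snapshot_every + 1;
  NumericMatrix snap_x(n, n_snap), snap_y(n, n_snap);
  NumericVector snap_t(n_snap);
  for (int i = 0; i < n; ++i) { snap_x(i, 0) = x[i]; snap_y(i, 0) = y[i]; }
  snap_t[0] = 0.0;
  int isnap = 1;

  Grid grid;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);

    // short-range adhesion/repulsion via grid, pair i<j
    grid.build(x, y, reach_max);
    for (int i = 0; i < n; ++i) {
      int cx = (int)((x[i] - grid.x0) / grid.h);
      int cy = (int)((y[i] - grid.y0) / grid.h);
      for (int oy = -1; oy <= 1; ++oy) for (int ox = -1; ox <= 1; ++ox) {
        int ccx = cx + ox, ccy = cy + oy;
        if (ccx < 0 || ccx >= grid.ncx || ccy < 0 || ccy >= grid.ncy)
          continue;
        const std::vector<int>& cell = grid.cells[(size_t)ccy * grid.ncx + ccx];
        for (int j : cell) {
          if (j <= i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d2 = dx * dx + dy * dy;
          double R = radius[i] + radius[j];
          double RA = adhesion_reach * R;
          if (d2 > RA * RA) continue;
          double d = std::sqrt(d2);
          double ux, uy;
          if (d < 1e-12) {
            double th = unif_rand() * 2.0 * M_PI;
            ux = std::cos(th); uy = std::sin(th); d = 0.0;
          } else { ux = dx / d; uy = dy / d; }
          double f = 0.0;  // signed along u (towards j positive)
          if (d < R) {
            double cr = std::sqrt(crep[i] * crep[j]);
            double s = 1.0 - d / R;
            f -= cr * s * s;
          }
          double ca = std::sqrt(cadh[i] * cadh[j]);
          if (ca > 0.0 && d < RA) {
            double s = 1.0 - d / RA;
            f += ca * s * s;
          }
          fx[i] += f * ux; fy[i] += f * uy;
          fx[j] -= f * ux; fy[j] -= f * uy;
        }
      }
    }

    // elastic traction: every pair with at least one microglia member
    for (int m : microglia) {
      for (int j = 0; j < n; ++j) {
        if (j == m) continue;
        if (kind[j] == 2 && j < m) continue;  // microglia pair once
        double dx = x[j] - x[m], dy = y[j] - y[m];
        if (cutoff_finite && dx * dx + dy * dy > cut2) continue;
        double fxe = k_elastic * dx, fye = k_elastic * dy;
        fx[m] += fxe; fy[m] += fye;
        fx[j] -= fxe; fy[j] -= fye;
      }
    }

    // locomotion + integration
    for (int i = 0; i < n; ++i) {
      if (kind[i] == 3) continue;  // skin agents are immobile anchors
      if (speed[i] > 0.0 && tau[i] > 0.0) {
        timer[i] -= dt;
        if (timer[i] <= 0.0) {
          double th = unif_rand() * 2.0 * M_PI;
          dirx[i] = std::cos(th); diry[i] = std::sin(th);
          timer[i] = tau[i];
        }
      }
      double vx = (fx[i] + speed[i] * dirx[i]) / eta;
      double vy = (fy[i] + speed[i] * diry[i]) / eta;
      x[i] += vx * dt;
      y[i] += vy * dt;
      if (!R_finite(x[i]) || !R_finite(y[i]))
        stop("non-finite position for agent %d at step %d", i + 1, step);
    }

    if (step % snapshot_every == 0) {
      for (int i = 0; i < n; ++i) {
        snap_x(i, isnap) = x[i];
        snap_y(i, isnap) = y[i];
      }
      snap_t[isnap] = step * dt;
      ++isnap;
    }
  }

  return List::create(_["t"] = snap_t, _["x"] = snap_x, _["y"] = snap_y,
                      _["dirx"] = NumericVector(dirx.begin(), dirx.end()),
                      _["diry"] = NumericVector(diry.begin(), diry.end()),
                      _["timer"] = NumericVector(timer.begin(), timer.end()));
}
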