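#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline double wrap_coord(double v, double len) {
  // steps are far smaller than the box, so direct reduction is exact
  while (v >= len) v -= len;
  while (v < 0) v += len;
  if (v >= len) v = 0.0; // fp guard: keep the half-open convention [0, len)
  return v;
}

inline double torus_d2(double xi, double yi, double xj, double yj,
                       double w, double h) {
  double dx = std::fabs(xi - xj); if (dx > 0.5 * w) dx = w - dx;
  double dy = std::fabs(yi - yj); if (dy > 0.5 * h) dy = h - dy;
  return dx * dx + dy * dy;
}

// per-cell table of the <= 9 distinct wrapped neighbour cells
static void build_neigh_table(int ncx, int ncy, std::vector<int>& tab,
                              std::vector<int>& tabn) {
  tab.assign((size_t)ncx * ncy * 9, 0);
  tabn.assign((size_t)ncx * ncy, 0);
  for (int cy = 0; cy < ncy; ++cy) {
    for (int cx = 0; cx < ncx; ++cx) {
      int xl[3], yl[3]; int nx = 0, ny = 0;
      for (int d = -1; d <= 1; ++d) {
        int a = cx + d; if (a < 0) a += ncx; if (a >= ncx) a -= ncx;
        bool dup = false; for (int t = 0; t < nx; ++t) if (xl[t] == a) dup = true;
        if (!dup) xl[nx++] = a;
        int b = cy + d; if (b < 0) b += ncy; if (b >= ncy) b -= ncy;
        dup = false; for (int t = 0; t < ny; ++t) if (yl[t] == b) dup = true;
        if (!dup) yl[ny++] = b;
      }
      int c = cy * ncx + cx;
      int m = 0;
      for (int bi = 0; bi < ny; ++bi)
        for (int ai = 0; ai < nx; ++ai)
          tab[(size_t)c * 9 + m++] = yl[bi] * ncx + xl[ai];
      tabn[c] = m;
    }
  }
}

// Contiguous cell-list (counting sort). Cell width >= r so a 3x3 (wrapped,
// deduplicated) neighbourhood covers every disc of radius r.
struct SortedGrid {
  int ncx, ncy;
  double cw, ch, w, h;
  std::vector<int> start;       // per-cell offsets, length ncell+1
  std::vector<double> xs, ys;   // coordinates sorted by cell
  std::vector<int> ord;         // sorted position -> original index
  std::vector<int> cell_of;
  std::vector<int> ntab, ntabn; // precomputed neighbour-cell table

  void init(double w_, double h_, double r, int n) {
    w = w_; h = h_;
    ncx = std::max(1, (int)std::floor(w / r));
    ncy = std::max(1, (int)std::floor(h / r));
    cw = w / ncx; ch = h / ncy;
    start.assign((size_t)ncx * ncy + 1, 0);
    xs.resize(n); ys.resize(n); ord.resize(n); cell_of.resize(n);
    build_neigh_table(ncx, ncy, ntab, ntabn);
  }
  inline int cx_of(double x) const {
    int c = (int)(x / cw); if (c >= ncx) c = ncx - 1; if (c < 0) c = 0; return c;
  }
  inline int cy_of(double y) const {
    int c = (int)(y / ch); if (c >= ncy) c = ncy - 1; if (c < 0) c = 0; return c;
  }
  void build(const std::vector<double>& x, const std::vector<double>& y) {
    int n = (int)x.size();
    std::fill(start.begin(), start.end(), 0);
    for (int i = 0; i < n; ++i) {
      int c = cy_of(y[i]) * ncx + cx_of(x[i]);
      cell_of[i] = c;
      ++start[c + 1];
    }
    for (size_t c = 1; c < start.size(); ++c) start[c] += start[c - 1];
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) {
      int p = pos[cell_of[i]]++;
      xs[p] = x[i]; ys[p] = y[i]; ord[p] = i;
    }
  }
  // number of stored points within r of (px,py), coincident points included
  inline int count_around(double px, double py, double r2) const {
    int c0 = cy_of(py) * ncx + cx_of(px);
    const int* cells = &ntab[(size_t)c0 * 9];
    int m = ntabn[c0];
    int k = 0;
    for (int c = 0; c < m; ++c) {
      int lo = start[cells[c]], hi = start[cells[c] + 1];
      for (int p = lo; p < hi; ++p)
        if (torus_d2(px, py, xs[p], ys[p], w, h) <= r2) ++k;
    }
    return k;
  }
};

// Doubly-linked cell list supporting O(1) remove/insert, for the incremental
// neighbour-count updates once most of the pattern is frozen.
struct LinkedGrid {
  int ncx, ncy;
  double cw, ch, w, h;
  std::vector<int> head, nxt, prv, cell;
  std::vector<int> ntab, ntabn;

  void init(double w_, double h_, double r, int n) {
    w = w_; h = h_;
    ncx = std::max(1, (int)std::floor(w / r));
    ncy = std::max(1, (int)std::floor(h / r));
    cw = w / ncx; ch = h / ncy;
    head.assign((size_t)ncx * ncy, -1);
    nxt.assign(n, -1); prv.assign(n, -1); cell.assign(n, -1);
    build_neigh_table(ncx, ncy, ntab, ntabn);
  }
  inline int cx_of(double x) const {
    int c = (int)(x / cw); if (c >= ncx) c = ncx - 1; if (c < 0) c = 0; return c;
  }
  inline int cy_of(double y) const {
    int c = (int)(y / ch); if (c >= ncy) c = ncy - 1; if (c < 0) c = 0; return c;
  }
  void insert(int i, double x, double y) {
    int c = cy_of(y) * ncx + cx_of(x);
    cell[i] = c; prv[i] = -1; nxt[i] = head[c];
    if (head[c] >= 0) prv[head[c]] = i;
    head[c] = i;
  }
  void remove(int i) {
    int c = cell[i];
    if (prv[i] >= 0) nxt[prv[i]] = nxt[i]; else head[c] = nxt[i];
    if (nxt[i] >= 0) prv[nxt[i]] = prv[i];
    cell[i] = -1;
  }
  inline int neigh_cells(double px, double py, const int** cells) const {
    int c0 = cy_of(py) * ncx + cx_of(px);
    *cells = &ntab[(size_t)c0 * 9];
    return ntabn[c0];
  }
};

// Displacement-vs-L profile families (see displacement_profile() in R):
// 1 linear_converging, 2 linear_floor, 3 tent_nonconverging, 4 quadratic.
inline double prof_rate(int family, double dmax, double dmin,
                        double lt, double la, double L) {
  double den = lt - la;
  double s = (lt - L) / den;
  double c = s > 1.0 ? 1.0 : (s < 0.0 ? 0.0 : s);
  switch (family) {
    case 1: return dmax * c;
    case 2: { double v = dmax * c; return v < dmin ? dmin : v; }
    case 3: { double a = std::fabs(lt - L) / den; if (a > 1.0) a = 1.0;
              return dmax * a; }
    case 4: return dmax * c * c;
  }
  return dmax;
}

// Specular reflection of a proposed move off the grid lines bounding the
// mesh cell that contains the starting point (per-axis folding; exact for
// axis-aligned barriers when the step is shorter than the mesh pitch).
inline double fold_axis(double oldv, double nv, double spacing) {
  double lo = std::floor(oldv / spacing) * spacing;
  double hi = lo + spacing;
  for (int it = 0; it < 64; ++it) {
    if (nv > hi) nv = 2.0 * hi - nv;
    else if (nv < lo) nv = 2.0 * lo - nv;
    else break;
  }
  return nv;
}

} // namespace

// [[Rcpp::export]]
IntegerVector C_neighbour_counts(NumericVector x, NumericVector y,
                                 double w, double h, double r) {
  int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  SortedGrid g;
  g.init(w, h, r, n);
  g.build(xv, yv);
  double r2 = r * r;
  for (int i = 0; i < n; ++i)
    out[i] = g.count_around(xv[i], yv[i], r2) - 1; // subtract self
  return out;
}

// Full simulation loop. Synchronous update: per frame, all local densities
// (neighbour counts k_i) are taken from the pre-move snapshot, rates follow
// from the profile, every agent draws its direction (or Gaussian increments)
// in index order whether or not it moves, then barriers and the toroidal
// wrap are applied. Counts are refreshed either by a full recount or by an
// exact incremental remove/insert pass over the moving agents, whichever is
// cheaper (count_mode 0), or forced (1 full, 2 incremental) for validation.
// [[Rcpp::export]]
List C_run_sim(NumericVector x0, NumericVector y0,
               double w, double h, double r_density,
               double dt, int n_frames,
               int family, double dmax, double dmin,
               double l_target, double l_anchor,
               int step_mode, double mesh_spacing,
               int record_every, int count_mode) {
  int n = x0.size();
  if (n < 2) stop("need at least 2 agents");
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  double A = w * h;
  double r2 = r_density * r_density;
  double Lc = std::sqrt(A / (M_PI * (double)(n - 1)));

  // L and rate depend on position only through the integer count k
  std::vector<double> Ltab(n + 1), rate_tab(n + 1);
  for (int k = 0; k <= n; ++k) {
    Ltab[k] = Lc * std::sqrt((double)k);
    rate_tab[k] = prof_rate(family, dmax, dmin, l_target, l_anchor, Ltab[k]);
  }

  SortedGrid sg;
  sg.init(w, h, r_density, n);
  LinkedGrid lg;
  lg.init(w, h, r_density, n);
  for (int i = 0; i < n; ++i) lg.insert(i, x[i], y[i]);
  bool lg_valid = true; // linked grid is only maintained while it is in use

  std::vector<int> k(n);
  sg.build(x, y);
  for (int i = 0; i < n; ++i)
    k[i] = sg.count_around(x[i], y[i], r2) - 1;

  NumericVector l_series(n_frames + 1);
  std::vector<int> movers(n);
  std::vector<double> nx(n), ny(n);

  List snapshots;
  IntegerVector snap_frames;
  bool record = record_every > 0;

  for (int f = 0; f < n_frames; ++f) {
    if ((f & 1023) == 0) Rcpp::checkUserInterrupt();
    double suml = 0.0;
    for (int i = 0; i < n; ++i) suml += Ltab[k[i]];
    l_series[f] = suml / n;

    if (record && f % record_every == 0) {
      NumericMatrix snap(n, 2);
      for (int i = 0; i < n; ++i) { snap(i, 0) = x[i]; snap(i, 1) = y[i]; }
      snapshots.push_back(snap);
      snap_frames.push_back(f);
    }

    // propose steps; RNG consumed for every agent so the stream does not
    // depend on which agents happen to be mobile
    int nm = 0;
    // candidate-scan cost proxies for choosing the count-update path:
    // a neighbourhood scan touches ~k_i + background candidates
    long long cost_all = 0, cost_mov = 0;
    for (int i = 0; i < n; ++i) {
      double rate = rate_tab[k[i]];
      cost_all += k[i] + 20;
      double sx, sy;
      if (step_mode == 0) {
        double u = unif_rand();
        double len = rate * dt;
        double th = 2.0 * M_PI * u;
        sx = len * std::cos(th); sy = len * std::sin(th);
      } else {
        double sd = rate * dt * M_SQRT1_2;
        sx = norm_rand() * sd; sy = norm_rand() * sd;
      }
      if (rate > 0.0) {
        double px = x[i] + sx, py = y[i] + sy;
        if (mesh_spacing > 0.0) {
          px = fold_axis(x[i], px, mesh_spacing);
          py = fold_axis(y[i], py, mesh_spacing);
        }
        px = wrap_coord(px, w);
        py = wrap_coord(py, h);
        movers[nm] = i; nx[i] = px; ny[i] = py; ++nm;
        cost_mov += k[i] + 20;
      }
    }

    // incremental updating scans around every mover twice (detach +
    // re-attach); a full recount scans around everyone once
    bool full = (count_mode == 1) ||
                (count_mode == 0 && 2 * cost_mov > cost_all);
    if (count_mode == 2) full = false;

    if (full) {
      for (int m = 0; m < nm; ++m) {
        int a = movers[m];
        x[a] = nx[a]; y[a] = ny[a];
      }
      lg_valid = false;
      sg.build(x, y);
      for (int i = 0; i < n; ++i)
        k[i] = sg.count_around(x[i], y[i], r2) - 1;
    } else {
      if (!lg_valid) {
        std::fill(lg.head.begin(), lg.head.end(), -1);
        for (int i = 0; i < n; ++i) lg.insert(i, x[i], y[i]);
        lg_valid = true;
      }
      const int* cells;
      // phase 1: detach movers, cancelling pair counts at old positions
      for (int m = 0; m < nm; ++m) {
        int a = movers[m];
        double px = x[a], py = y[a];
        int mc = lg.neigh_cells(px, py, &cells);
        for (int c = 0; c < mc; ++c) {
          for (int j = lg.head[cells[c]]; j >= 0; j = lg.nxt[j]) {
            if (j == a) continue;
            if (torus_d2(px, py, x[j], y[j], w, h) <= r2) { --k[j]; --k[a]; }
          }
        }
        lg.remove(a);
      }
      // phase 2: re-attach at new positions, adding new pair counts
      for (int m = 0; m < nm; ++m) {
        int a = movers[m];
        x[a] = nx[a]; y[a] = ny[a];
        double px = x[a], py = y[a];
        int mc = lg.neigh_cells(px, py, &cells);
        for (int c = 0; c < mc; ++c) {
          for (int j = lg.head[cells[c]]; j >= 0; j = lg.nxt[j]) {
            if (torus_d2(px, py, x[j], y[j], w, h) <= r2) { ++k[j]; ++k[a]; }
          }
        }
        lg.insert(a, px, py);
      }
    }
  }

  double suml = 0.0;
  for (int i = 0; i < n; ++i) suml += Ltab[k[i]];
  l_series[n_frames] = suml / n;

  return List::create(_["l_series"] = l_series,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["counts"] = IntegerVector(k.begin(), k.end()),
                      _["snapshots"] = snapshots,
                      _["snap_frames"] = snap_frames);
}

// Density-connected components under toroidal distance (DBSCAN-style).
// Returns 0 for unassigned/noise, 1..K for raw components; minimum-size
// filtering and relabelling happen in R.
// [[Rcpp::export]]
IntegerVector C_dbscan_torus(NumericVector x, NumericVector y,
                             double w, double h,
                             double eps, int min_neighbors) {
  int n = x.size();
  IntegerVector labels(n);
  if (n == 0) return labels;
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  SortedGrid g;
  g.init(w, h, eps, n);
  g.build(xv, yv);
  double eps2 = eps * eps;

  std::vector<bool> core(n, false);
  for (int i = 0; i < n; ++i)
    core[i] = (g.count_around(xv[i], yv[i], eps2) - 1) >= min_neighbors;

  int cid = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] != 0) continue;
    ++cid;
    labels[i] = cid;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int c0 = g.cy_of(yv[p]) * g.ncx + g.cx_of(xv[p]);
      const int* cells = &g.ntab[(size_t)c0 * 9];
      int mc = g.ntabn[c0];
      for (int c = 0; c < mc; ++c) {
        int lo = g.start[cells[c]], hi = g.start[cells[c] + 1];
        for (int q = lo; q < hi; ++q) {
          int j = g.ord[q];
          if (j == p || labels[j] != 0) continue;
          if (torus_d2(xv[p], yv[p], xv[j], yv[j], w, h) <= eps2) {
            labels[j] = cid;
            if (core[j]) stack.push_back(j);
          }
        }
      }
    }
  }
  return labels;
}
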