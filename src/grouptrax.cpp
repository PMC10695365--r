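#include <Rcpp.h>
using namespace Rcpp;

// Fold an unbounded coordinate back into [0, w] by mirror reflection.
static inline double reflect(double u, double w) {
  if (w <= 0) return 0.0;
  const double period = 2.0 * w;
  double p = u - period * std::floor(u / period);
  return (p > w) ? period - p : p;
}

// Correlated random walk with social attraction for n agents in a
// rectangular arena with reflective walls. Each step direction is the angle
// of a drift vector mixing persistence (previous heading), home-base pull
// and unit-vector attraction toward each partner, perturbed by Gaussian
// angular noise; step length is exponential with the agent's mean step
// length ("activity"). Uses R's RNG, so results are governed by set.seed().
//
// Returns an n_frames x (2 n) matrix: columns x_1..x_n then y_1..y_n.
// [[Rcpp::export]]
NumericMatrix simulate_crw_cpp(int n_frames,
                               NumericMatrix attraction,   // n x n, row=agent
                               NumericVector activity,
                               NumericVector home_affinity,
                               NumericVector noise_sd,
                               NumericMatrix home,         // n x 2
                               NumericVector start_x,
                               NumericVector start_y,
                               double width, double height,
                               double persistence) {
  const int n = activity.size();
  NumericMatrix out(n_frames, 2 * n);
  std::vector<double> px(n), py(n), heading(n);
  for (int a = 0; a < n; ++a) {
    px[a] = start_x[a];
    py[a] = start_y[a];
    heading[a] = R::runif(0.0, 2.0 * M_PI);
    out(0, a) = px[a];
    out(0, n + a) = py[a];
  }
  std::vector<double> qx(n), qy(n);
  for (int f = 1; f < n_frames; ++f) {
    for (int a = 0; a < n; ++a) {
      double vx = persistence * std::cos(heading[a]);
      double vy = persistence * std::sin(heading[a]);
      // home-base pull
      double hx = home(a, 0) - px[a], hy = home(a, 1) - py[a];
      double hd = std::sqrt(hx * hx + hy * hy);
      if (hd > 1e-12) {
        vx += home_affinity[a] * hx / hd;
        vy += home_affinity[a] * hy / hd;
      }
      // social attraction toward partners
      for (int b = 0; b < n; ++b) {
        if (b == a) continue;
        double w = attraction(a, b);
        if (w <= 0) continue;
        double dx = px[b] - px[a], dy = py[b] - py[a];
        double dd = std::sqrt(dx * dx + dy * dy);
        if (dd > 1e-12) {
          vx += w * dx / dd;
          vy += w * dy / dd;
        }
      }
      double ang;
      if (vx * vx + vy * vy < 1e-20) ang = heading[a];
      else ang = std::atan2(vy, vx);
      ang += R::rnorm(0.0, noise_sd[a]);
      double len = R::exp_rand() * activity[a];
      double nx = reflect(px[a] + len * std::cos(ang), width);
      double ny = reflect(py[a] + len * std::sin(ang), height);
      // realized heading after any wall reflection
      double rdx = nx - px[a], rdy = ny - py[a];
      if (rdx * rdx + rdy * rdy > 1e-20) heading[a] = std::atan2(rdy, rdx);
      else heading[a] = ang;
      qx[a] = nx;
      qy[a] = ny;
    }
    for (int a = 0; a < n; ++a) {  // synchronous update
      px[a] = qx[a];
      py[a] = qy[a];
      out(f, a) = px[a];
      out(f, n + a) = py[a];
    }
  }
  return out;
}

static const int PERM2[2][2] = {{0, 1}, {1, 0}};
static const int PERM3[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
static const int PERM4[24][4] = {
  {0,1,2,3},{0,1,3,2},{0,2,1,3},{0,2,3,1},{0,3,1,2},{0,3,2,1},
  {1,0,2,3},{1,0,3,2},{1,2,0,3},{1,2,3,0},{1,3,0,2},{1,3,2,0},
  {2,0,1,3},{2,0,3,1},{2,1,0,3},{2,1,3,0},{2,3,0,1},{2,3,1,0},
  {3,0,1,2},{3,0,2,1},{3,1,0,2},{3,1,2,0},{3,2,0,1},{3,2,1,0}};

// Per-frame optimal label assignment for up to 4 animals: re-assigns the
// observed positions of the animals valid at each frame so that the total
// displacement from each slot's last resolved valid position is minimal.
// Incumbent labels are kept unless a permutation beats them by more than
// `margin` cm of total displacement: without that hysteresis, whenever two
// animals sit within a step length of each other, measurement noise makes
// the exchanged labels marginally cheaper and a spurious, persistent swap
// is introduced. Ties therefore always preserve incumbent labels.
// Returns a list with reordered x, y, valid and the count of animal-frames
// whose label changed.
// [[Rcpp::export]]
List resolve_swaps_cpp(NumericMatrix x, NumericMatrix y, LogicalMatrix valid,
                       double margin) {
  const int nf = x.nrow(), n = x.ncol();
  if (n > 4) stop("resolve_swaps_cpp supports at most 4 animals");
  NumericMatrix ox(clone(x)), oy(clone(y));
  LogicalMatrix ov(clone(valid));
  std::vector<double> lx(n), ly(n);
  std::vector<bool> seen(n, false);
  int n_changed = 0;
  for (int f = 0; f < nf; ++f) {
    std::vector<int> idx;  // slots valid at this frame
    for (int a = 0; a < n; ++a) if (ov(f, a)) idx.push_back(a);
    const int m = (int)idx.size();
    if (m >= 2) {
      // candidate observations at this frame (in incumbent label order)
      std::vector<double> cx(m), cy(m);
      for (int i = 0; i < m; ++i) { cx[i] = ox(f, idx[i]); cy[i] = oy(f, idx[i]); }
      int n_perm = (m == 2) ? 2 : (m == 3) ? 6 : 24;
      int best = 0;
      double best_cost = R_PosInf, id_cost = 0.0;
      for (int p = 0; p < n_perm; ++p) {
        double cost = 0.0;
        bool is_id = true;
        for (int i = 0; i < m; ++i) {
          int src = (m == 2) ? PERM2[p][i] : (m == 3) ? PERM3[p][i] : PERM4[p][i];
          if (src != i) is_id = false;
          int slot = idx[i];
          if (seen[slot]) {
            double dx = cx[src] - lx[slot], dy = cy[src] - ly[slot];
            cost += std::sqrt(dx * dx + dy * dy);
          }
        }
        if (is_id) id_cost = cost;
        if (cost < best_cost - 1e-12) { best_cost = cost; best = p; }
      }
      // prefer the incumbent labels unless better by more than the margin
      if (id_cost <= best_cost + margin) best = -1;
      if (best >= 0) {
        for (int i = 0; i < m; ++i) {
          int src = (m == 2) ? PERM2[best][i]
                  : (m == 3) ? PERM3[best][i] : PERM4[best][i];
          ox(f, idx[i]) = cx[src];
          oy(f, idx[i]) = cy[src];
          if (src != i) ++n_changed;
        }
      }
    }
    for (int a = 0; a < n; ++a) if (ov(f, a)) {
      lx[a] = ox(f, a); ly[a] = oy(f, a); seen[a] = true;
    }
  }
  return List::create(_["x"] = ox, _["y"] = oy, _["valid"] = ov,
                      _["n_changed"] = n_changed);
}
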