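#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Backward-in-time SLFV event loop.
//
// Lineages carry a current location and a genealogy node id. Events arrive as
// a Poisson process; each event selects nearby lineages independently
// (Bernoulli with the kernel's selection probability), merges any selected
// set of size >= 2 into a single ancestor placed by the replacement
// distribution, and moves a singleton selection in place. Movement never
// creates genealogy nodes.
//
// Two exact engines:
//  * naive: events sampled over the whole landscape (works for any kernel,
//    raster heterogeneity, and self-overlapping radii);
//  * thinned: homogeneous disc kernel with r < min(extent)/2 only. Thins
//    directly to the *effective* events (those selecting at least one
//    lineage), which over the landscape form a Poisson process with center
//    intensity lambda * (1 - (1-u)^m(e)), m(e) = lineages within r of e.
//    Candidates arrive at the dominating rate lambda*k*A_disc*u; a center is
//    proposed uniformly in the disc of a uniformly chosen lineage (proposal
//    intensity lambda*u*m(e)) and accepted with probability
//    (1 - (1-u)^m) / (u*m) <= 1; the affected set is then Bernoulli(u) on
//    the m in-range lineages conditioned on being non-empty. Empty and far
//    events, which leave the state unchanged, are never generated; by
//    memorylessness the law of the embedded effective-event chain is
//    identical to the naive engine's.
//
// All randomness flows from R's RNG so set.seed() governs reproducibility.

static inline double torus_diff(double a, double b, double L) {
  double d = b - a;
  d -= L * std::round(d / L);
  return d;
}

static inline double torus_dist2(const double *a, const double *b,
                                 const double *ext, int dim) {
  double s = 0.0;
  for (int j = 0; j < dim; ++j) {
    double d = torus_diff(a[j], b[j], ext[j]);
    s += d * d;
  }
  return s;
}

static inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard against floating rounding at the boundary
  return x;
}

// uniform draw inside a disc (2D) / interval (1D) of radius r around c
static void runif_disc(const double *c, double r, const double *ext, int dim,
                       double *out) {
  if (dim == 1) {
    out[0] = wrap1(c[0] + (2.0 * unif_rand() - 1.0) * r, ext[0]);
  } else {
    double rad = r * std::sqrt(unif_rand());
    double ang = 2.0 * M_PI * unif_rand();
    out[0] = wrap1(c[0] + rad * std::cos(ang), ext[0]);
    out[1] = wrap1(c[1] + rad * std::sin(ang), ext[1]);
  }
}

static void rgauss_around(const double *c, double r, const double *ext,
                          int dim, double *out) {
  for (int j = 0; j < dim; ++j) out[j] = wrap1(c[j] + r * norm_rand(), ext[j]);
}

// [[Rcpp::export(name = ".slfv_simulate_cpp")]]
List slfv_simulate_cpp(NumericMatrix loc0, NumericVector extent,
                       std::string family, double r, double u, double lambda,
                       Nullable<NumericMatrix> raster_, double max_events,
                       bool thin) {
  const int n = loc0.nrow();
  const int dim = extent.size();
  const double *ext = extent.begin();
  const bool disc = (family == "disc");

  // lineage state
  std::vector<double> lx(n * 2);
  std::vector<int> lnode(n);
  int k = n;
  for (int i = 0; i < n; ++i) {
    lx[2 * i] = loc0(i, 0);
    lx[2 * i + 1] = dim == 2 ? loc0(i, 1) : 0.0;
    lnode[i] = i;
  }

  // genealogy records (leaves are nodes 0..n-1 at time 0)
  std::vector<double> node_time(n, 0.0), node_x, node_y;
  node_x.reserve(2 * n); node_y.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    node_x.push_back(loc0(i, 0));
    node_y.push_back(dim == 2 ? loc0(i, 1) : 0.0);
  }
  std::vector<int> edge_child, edge_parent, merger_sizes;

  // raster tiles (naive engine); homogeneous default = single tile
  int nx = 1, ny = 1;
  std::vector<double> cumw(1, 1.0);
  double tile_dx = ext[0], tile_dy = dim == 2 ? ext[1] : 1.0;
  if (raster_.isNotNull()) {
    NumericMatrix h(raster_);
    nx = h.nrow();
    ny = dim == 2 ? h.ncol() : 1;
    tile_dx = ext[0] / nx;
    tile_dy = dim == 2 ? ext[1] / ny : 1.0;
    cumw.assign(nx * ny, 0.0);
    double acc = 0.0;
    for (int t = 0; t < nx * ny; ++t) {  // column-major over (x, y) tiles
      acc += h[t];
      cumw[t] = acc;
    }
  }
  const double wsum = cumw.back();
  const double area = dim == 2 ? ext[0] * ext[1] : ext[0];
  const double tile_area = tile_dx * (dim == 2 ? tile_dy : 1.0);
  const double naive_rate = lambda * (raster_.isNotNull()
                            ? wsum * tile_area : area);
  const double a_disc = dim == 2 ? M_PI * r * r : 2.0 * r;

  double t_now = 0.0;
  double n_iter = 0, n_events = 0, n_nonempty = 0;
  std::vector<int> sel; sel.reserve(n);
  double center[2], newloc[2];
  bool coalesced = false;

  while (k > 1) {
    if (n_iter >= max_events) break;
    n_iter += 1;
    if (n_iter == std::floor(n_iter / 65536.0) * 65536.0) checkUserInterrupt();

    bool have_event = false;
    bool conditioned_nonempty = false;
    int m_range = 0;
    if (thin) {
      t_now += exp_rand() / (lambda * k * a_disc * u);
      int i = (int)std::floor(unif_rand() * k);
      if (i == k) i = k - 1;
      runif_disc(&lx[2 * i], r, ext, dim, center);
      int m = 0;
      for (int j = 0; j < k; ++j)
        if (torus_dist2(center, &lx[2 * j], ext, dim) <= r * r) ++m;
      // accept w.p. (1 - (1-u)^m) / (u m); m >= 1 by construction
      double p_nonempty = 1.0 - std::pow(1.0 - u, (double)m);
      if (unif_rand() * (u * m) <= p_nonempty) {
        have_event = true;
        conditioned_nonempty = true;
        m_range = m;
      }
    } else {
      t_now += exp_rand() / naive_rate;
      // inverse-CDF on tile weights, then uniform within the tile
      double target = unif_rand() * wsum;
      int lo = 0, hi = (int)cumw.size() - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cumw[mid] < target) lo = mid + 1; else hi = mid;
      }
      int ix = lo % nx, iy = lo / nx;
      center[0] = (ix + unif_rand()) * tile_dx;
      if (dim == 2) center[1] = (iy + unif_rand()) * tile_dy;
      have_event = true;
    }
    if (!have_event) continue;
    n_events += 1;

    // independent Bernoulli selection of affected lineages; under the
    // effective-event thinning, conditioned on at least one selection
    sel.clear();
    if (conditioned_nonempty) {
      if (m_range == 1) {
        for (int j = 0; j < k; ++j)
          if (torus_dist2(center, &lx[2 * j], ext, dim) <= r * r) {
            sel.push_back(j);
            break;
          }
      } else {
        do {
          sel.clear();
          for (int j = 0; j < k; ++j) {
            if (torus_dist2(center, &lx[2 * j], ext, dim) <= r * r &&
                unif_rand() < u) {
              sel.push_back(j);
            }
          }
        } while (sel.empty());
      }
    } else {
      for (int j = 0; j < k; ++j) {
        double d2 = torus_dist2(center, &lx[2 * j], ext, dim);
        double p;
        if (disc) p = d2 <= r * r ? u : 0.0;
        else p = u * std::exp(-d2 / (2.0 * r * r));
        if (p > 0.0 && unif_rand() < p) sel.push_back(j);
      }
    }
    if (sel.empty()) continue;
    n_nonempty += 1;

    if (disc) runif_disc(center, r, ext, dim, newloc);
    else rgauss_around(center, r, ext, dim, newloc);

    if (sel.size() == 1) {  // movement only
      int i = sel[0];
      lx[2 * i] = newloc[0];
      lx[2 * i + 1] = newloc[1];
      continue;
    }

    // merger: single ancestor of all selected lineages
    int parent = (int)node_time.size();
    node_time.push_back(t_now);
    node_x.push_back(newloc[0]);
    node_y.push_back(newloc[1]);
    merger_sizes.push_back((int)sel.size());
    for (size_t s = 0; s < sel.size(); ++s) {
      edge_child.push_back(lnode[sel[s]]);
      edge_parent.push_back(parent);
    }
    // survivor slot takes the ancestor; drop the rest back-to-front
    int keep = sel[0];
    lnode[keep] = parent;
    lx[2 * keep] = newloc[0];
    lx[2 * keep + 1] = newloc[1];
    for (int s = (int)sel.size() - 1; s >= 1; --s) {
      int i = sel[s];
      lnode[i] = lnode[k - 1];
      lx[2 * i] = lx[2 * (k - 1)];
      lx[2 * i + 1] = lx[2 * (k - 1) + 1];
      --k;
    }
  }
  coalesced = (k == 1);

  IntegerVector roots(k);
  NumericVector root_x(k), root_y(k);
  for (int i = 0; i < k; ++i) {
    roots[i] = lnode[i];
    root_x[i] = lx[2 * i];
    root_y[i] = lx[2 * i + 1];
  }

  return List::create(
    _["node_time"] = wrap(node_time),
    _["node_x"] = wrap(node_x),
    _["node_y"] = wrap(node_y),
    _["edge_child"] = wrap(edge_child),
    _["edge_parent"] = wrap(edge_parent),
    _["merger_sizes"] = wrap(merger_sizes),
    _["coalesced"] = coalesced,
    _["n_iter"] = n_iter,
    _["n_events"] = n_events,
    _["n_nonempty"] = n_nonempty,
    _["final_time"] = t_now,
    _["roots"] = roots,
    _["root_x"] = root_x,
    _["root_y"] = root_y
  );
}
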