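#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// strict proper crossing of segments (p1,p2) and (q1,q2)
static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

static bool segments_cross(double p1x, double p1y, double p2x, double p2y,
                           double q1x, double q1y, double q2x, double q2y) {
  double d1 = cross2(q2x - q1x, q2y - q1y, p1x - q1x, p1y - q1y);
  double d2 = cross2(q2x - q1x, q2y - q1y, p2x - q1x, p2y - q1y);
  double d3 = cross2(p2x - p1x, p2y - p1y, q1x - p1x, q1y - p1y);
  double d4 = cross2(p2x - p1x, p2y - p1y, q2x - q1x, q2y - q1y);
  return (d1 * d2 < 0.0) && (d3 * d4 < 0.0);
}

// does the cell ring stay simple when the vertex at ring position `ip`
// moves to (nx,ny)? only the two edges incident to that vertex can create
// a new crossing, so test them against all non-adjacent edges.
static bool ring_stays_simple(const std::vector<int> &ring,
                              const std::vector<double> &px,
                              const std::vector<double> &py,
                              int ip, double nx, double ny) {
  int k = (int)ring.size();
  int vmov = ring[ip];
  int moved_edges[2] = { (ip - 1 + k) % k, ip };
  for (int em = 0; em < 2; ++em) {
    int e = moved_edges[em];
    int a = ring[e], b = ring[(e + 1) % k];
    double p1x = (a == vmov) ? nx : px[a];
    double p1y = (a == vmov) ? ny : py[a];
    double p2x = (b == vmov) ? nx : px[b];
    double p2y = (b == vmov) ? ny : py[b];
    for (int f = 0; f < k; ++f) {
      if (f == moved_edges[0] || f == moved_edges[1]) continue;
      int fa = ring[f], fb = ring[(f + 1) % k];
      if (fa == a || fa == b || fb == a || fb == b) continue;
      if (segments_cross(p1x, p1y, p2x, p2y, px[fa], py[fa], px[fb], py[fb]))
        return false;
    }
  }
  return true;
}

// Metropolis relaxation of the vertex-model energy
// H = sum_c lambda_a (a_c - A_c)^2 + sum_w lambda_m (l_w - L_w)^2
// [[Rcpp::export]]
List mc_relax_cpp(NumericMatrix pos, List rings, NumericVector rest_area,
                  IntegerMatrix walls, NumericVector wall_rest,
                  double lambda_a, double lambda_m,
                  double step, double kT, int n_trials,
                  double min_area) {
  int nv = pos.nrow();
  int nc = rings.size();
  int nw = walls.nrow();

  std::vector<double> px(nv), py(nv);
  for (int v = 0; v < nv; ++v) { px[v] = pos(v, 0); py[v] = pos(v, 1); }

  // rings as 0-based
  std::vector< std::vector<int> > R(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector r = rings[c];
    R[c].resize(r.size());
    for (int k = 0; k < r.size(); ++k) R[c][k] = r[k] - 1;
  }

  // vertex -> (cell, ring position) incidence
  std::vector< std::vector< std::pair<int,int> > > vcell(nv);
  for (int c = 0; c < nc; ++c)
    for (int k = 0; k < (int)R[c].size(); ++k)
      vcell[R[c][k]].push_back(std::make_pair(c, k));

  // vertex -> wall incidence
  std::vector< std::vector<int> > vwall(nv);
  for (int w = 0; w < nw; ++w) {
    vwall[walls(w, 0) - 1].push_back(w);
    vwall[walls(w, 1) - 1].push_back(w);
  }

  // cached areas and lengths
  std::vector<double> area(nc), wlen(nw);
  for (int c = 0; c < nc; ++c) {
    double s = 0.0; int k = (int)R[c].size();
    for (int i = 0; i < k; ++i) {
      int a = R[c][i], b = R[c][(i + 1) % k];
      s += px[a] * py[b] - px[b] * py[a];
    }
    area[c] = 0.5 * s;
  }
  for (int w = 0; w < nw; ++w) {
    int a = walls(w, 0) - 1, b = walls(w, 1) - 1;
    wlen[w] = std::sqrt((px[a]-px[b])*(px[a]-px[b]) + (py[a]-py[b])*(py[a]-py[b]));
  }

  int n_accept = 0;
  GetRNGstate();
  for (int t = 0; t < n_trials; ++t) {
    int v = (int)(unif_rand() * nv);
    if (v >= nv) v = nv - 1;
    double u1 = unif_rand(), u2 = unif_rand();
    double rad = step * std::sqrt(u1), th = 2.0 * M_PI * u2;
    double nx = px[v] + rad * std::cos(th);
    double ny = py[v] + rad * std::sin(th);

    // energy change from incident cells (incremental shoelace)
    double dH = 0.0;
    bool ok = true;
    std::vector<double> newA(vcell[v].size());
    for (size_t m = 0; m < vcell[v].size(); ++m) {
      int c = vcell[v][m].first, ip = vcell[v][m].second;
      int k = (int)R[c].size();
      int vp = R[c][(ip - 1 + k) % k], vn = R[c][(ip + 1) % k];
      double dA = 0.5 * ((nx - px[v]) * (py[vn] - py[vp]) -
                         (ny - py[v]) * (px[vn] - px[vp]));
      double a2 = area[c] + dA;
      if (a2 <= min_area) { ok = false; break; }   // inverted / collapsed
      newA[m] = a2;
      double d0 = area[c] - rest_area[c], d1 = a2 - rest_area[c];
      dH += lambda_a * (d1 * d1 - d0 * d0);
    }
    if (!ok) continue;
    std::vector<double> newL(vwall[v].size());
    for (size_t m = 0; m < vwall[v].size(); ++m) {
      int w = vwall[v][m];
      int a = walls(w, 0) - 1, b = walls(w, 1) - 1;
      int o = (a == v) ? b : a;
      double l2 = std::sqrt((nx-px[o])*(nx-px[o]) + (ny-py[o])*(ny-py[o]));
      newL[m] = l2;
      double d0 = wlen[w] - wall_rest[w], d1 = l2 - wall_rest[w];
      dH += lambda_m * (d1 * d1 - d0 * d0);
    }

    bool accept = dH < 0.0;
    if (!accept && kT > 0.0) accept = unif_rand() < std::exp(-dH / kT);
    if (!accept) continue;

    // geometric rejection: cells must remain simple polygons
    for (size_t m = 0; m < vcell[v].size() && ok; ++m) {
      int c = vcell[v][m].first, ip = vcell[v][m].second;
      if (!ring_stays_simple(R[c], px, py, ip, nx, ny)) ok = false;
    }
    if (!ok) continue;

    px[v] = nx; py[v] = ny;
    for (size_t m = 0; m < vcell[v].size(); ++m) area[vcell[v][m].first] = newA[m];
    for (size_t m = 0; m < vwall[v].size(); ++m) wlen[vwall[v][m]] = newL[m];
    ++n_accept;
  }
  PutRNGstate();

  NumericMatrix out(nv, 2);
  for (int v = 0; v < nv; ++v) { out(v, 0) = px[v]; out(v, 1) = py[v]; }
  return List::create(_["pos"] = out, _["accepted"] = n_accept);
}
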