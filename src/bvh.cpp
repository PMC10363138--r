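// Bounding volume hierarchy over triangle faces: top-down median split on the
// longest centroid axis, leaf size configurable (default 4). Queries:
//  * globally nearest surface point (best-first traversal with a priority
//    queue pruning boxes whose lower bound exceeds the current best), and
//  * first ray hit (smallest non-negative t, two-sided triangles).
// Ties on distance are broken toward the lowest face index so repeated runs
// are bit-identical.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Node {
  double lo[3], hi[3];
  int left, right;   // children; -1 for leaf
  int start, count;  // face range into `order` when leaf
};

struct BVH {
  std::vector<double> vx, vy, vz;      // vertex coordinates
  std::vector<int> f0, f1, f2;         // 0-based face indices
  std::vector<int> order;              // permutation of faces
  std::vector<Node> nodes;
  int leafSize;
};

inline double sq(double x) { return x * x; }

// squared distance from point to axis-aligned box (0 inside)
inline double boxDist2(const Node& nd, const double p[3]) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    if (p[k] < nd.lo[k]) d2 += sq(nd.lo[k] - p[k]);
    else if (p[k] > nd.hi[k]) d2 += sq(p[k] - nd.hi[k]);
  }
  return d2;
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection)
inline void closestPtTriangle(const double p[3], const double a[3],
                              const double b[3], const double c[3],
                              double out[3], double bary[3]) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1; bary[1] = 0; bary[2] = 0; return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0; bary[1] = 1; bary[2] = 0; return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0; return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0; bary[1] = 0; bary[2] = 1; return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

void faceVertex(const BVH& t, int f, int corner, double out[3]) {
  int vi = corner == 0 ? t.f0[f] : (corner == 1 ? t.f1[f] : t.f2[f]);
  out[0] = t.vx[vi]; out[1] = t.vy[vi]; out[2] = t.vz[vi];
}

int buildRec(BVH& t, std::vector<double>& cx, std::vector<double>& cy,
             std::vector<double>& cz, int start, int count) {
  Node nd;
  nd.lo[0] = nd.lo[1] = nd.lo[2] = std::numeric_limits<double>::infinity();
  nd.hi[0] = nd.hi[1] = nd.hi[2] = -std::numeric_limits<double>::infinity();
  for (int i = start; i < start + count; ++i) {
    int f = t.order[i];
    for (int c = 0; c < 3; ++c) {
      double v[3];
      faceVertex(t, f, c, v);
      for (int k = 0; k < 3; ++k) {
        nd.lo[k] = std::min(nd.lo[k], v[k]);
        nd.hi[k] = std::max(nd.hi[k], v[k]);
      }
    }
  }
  if (count <= t.leafSize) {
    nd.left = nd.right = -1;
    nd.start = start; nd.count = count;
    t.nodes.push_back(nd);
    return (int)t.nodes.size() - 1;
  }
  // split on longest axis of centroid bounds
  double clo[3] = {1e300, 1e300, 1e300}, chi[3] = {-1e300, -1e300, -1e300};
  for (int i = start; i < start + count; ++i) {
    int f = t.order[i];
    double c[3] = {cx[f], cy[f], cz[f]};
    for (int k = 0; k < 3; ++k) {
      clo[k] = std::min(clo[k], c[k]);
      chi[k] = std::max(chi[k], c[k]);
    }
  }
  int axis = 0;
  double ext = chi[0] - clo[0];
  for (int k = 1; k < 3; ++k)
    if (chi[k] - clo[k] > ext) { ext = chi[k] - clo[k]; axis = k; }
  int mid = start + count / 2;
  const std::vector<double>& cc = (axis == 0 ? cx : (axis == 1 ? cy : cz));
  std::nth_element(t.order.begin() + start, t.order.begin() + mid,
                   t.order.begin() + start + count,
                   [&cc](int a, int b) { return cc[a] < cc[b] || (cc[a] == cc[b] && a < b); });
  nd.start = start; nd.count = count;
  t.nodes.push_back(nd);
  int self = (int)t.nodes.size() - 1;
  int l = buildRec(t, cx, cy, cz, start, mid - start);
  int r = buildRec(t, cx, cy, cz, mid, start + count - mid);
  t.nodes[self].left = l;
  t.nodes[self].right = r;
  return self;
}

} // namespace

// [[Rcpp::export]]
SEXP bvh_build_cpp(NumericMatrix V, IntegerMatrix F, int leafSize) {
  BVH* t = new BVH();
  int n = V.nrow(), m = F.nrow();
  t->leafSize = leafSize;
  t->vx.resize(n); t->vy.resize(n); t->vz.resize(n);
  for (int i = 0; i < n; ++i) { t->vx[i] = V(i,0); t->vy[i] = V(i,1); t->vz[i] = V(i,2); }
  t->f0.resize(m); t->f1.resize(m); t->f2.resize(m);
  for (int i = 0; i < m; ++i) { t->f0[i] = F(i,0) - 1; t->f1[i] = F(i,1) - 1; t->f2[i] = F(i,2) - 1; }
  t->order.resize(m);
  for (int i = 0; i < m; ++i) t->order[i] = i;
  std::vector<double> cx(m), cy(m), cz(m);
  for (int i = 0; i < m; ++i) {
    cx[i] = (t->vx[t->f0[i]] + t->vx[t->f1[i]] + t->vx[t->f2[i]]) / 3.0;
    cy[i] = (t->vy[t->f0[i]] + t->vy[t->f1[i]] + t->vy[t->f2[i]]) / 3.0;
    cz[i] = (t->vz[t->f0[i]] + t->vz[t->f1[i]] + t->vz[t->f2[i]]) / 3.0;
  }
  if (m > 0) buildRec(*t, cx, cy, cz, 0, m);
  XPtr<BVH> ptr(t, true);
  return ptr;
}

// [[Rcpp::export]]
List bvh_closest_cpp(SEXP ptr, NumericMatrix Q) {
  XPtr<BVH> t(ptr);
  int nq = Q.nrow();
  NumericVector dist(nq);
  NumericMatrix foot(nq, 3), bary(nq, 3);
  IntegerVector face(nq);
  typedef std::pair<double, int> QE; // (lower bound, node)
  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q,0), Q(q,1), Q(q,2)};
    double best = std::numeric_limits<double>::infinity();
    int bestFace = -1;
    double bestPt[3] = {0,0,0}, bestBary[3] = {0,0,0};
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    if (!t->nodes.empty()) pq.push(QE(boxDist2(t->nodes[0], p), 0));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      if (top.first > best) break; // every remaining box is worse
      const Node& nd = t->nodes[top.second];
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int f = t->order[i];
          double a[3], b[3], c[3], out[3], bc[3];
          faceVertex(*t, f, 0, a); faceVertex(*t, f, 1, b); faceVertex(*t, f, 2, c);
          closestPtTriangle(p, a, b, c, out, bc);
          double d2 = sq(out[0]-p[0]) + sq(out[1]-p[1]) + sq(out[2]-p[2]);
          if (d2 < best || (d2 == best && f < bestFace)) {
            best = d2; bestFace = f;
            for (int k = 0; k < 3; ++k) { bestPt[k] = out[k]; bestBary[k] = bc[k]; }
          }
        }
      } else {
        double dl = boxDist2(t->nodes[nd.left], p);
        double dr = boxDist2(t->nodes[nd.right], p);
        if (dl <= best) pq.push(QE(dl, nd.left));
        if (dr <= best) pq.push(QE(dr, nd.right));
      }
    }
    dist[q] = std::sqrt(best);
    face[q] = bestFace + 1;
    for (int k = 0; k < 3; ++k) { foot(q,k) = bestPt[k]; bary(q,k) = bestBary[k]; }
  }
  return List::create(_["distance"] = dist, _["point"] = foot,
                      _["face"] = face, _["bary"] = bary);
}

// first hit along ray (two-sided Moller-Trumbore); t >= -1e-9 accepted so a
// ray started exactly on the surface reports the origin itself
// [[Rcpp::export]]
List bvh_ray_cpp(SEXP ptr, NumericMatrix O, NumericMatrix D) {
  XPtr<BVH> t(ptr);
  int nq = O.nrow();
  NumericVector tout(nq);
  NumericMatrix pt(nq, 3);
  IntegerVector face(nq);
  for (int q = 0; q < nq; ++q) {
    double o[3] = {O(q,0), O(q,1), O(q,2)};
    double d[3] = {D(q,0), D(q,1), D(q,2)};
    double inv[3];
    for (int k = 0; k < 3; ++k)
      inv[k] = d[k] != 0.0 ? 1.0 / d[k] : std::numeric_limits<double>::infinity();
    double bestT = std::numeric_limits<double>::infinity();
    int bestFace = -1;
    std::vector<int> stack;
    if (!t->nodes.empty()) stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back(); stack.pop_back();
      const Node& nd = t->nodes[ni];
      // slab test
      double t0 = 0.0, t1 = bestT;
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        double ta = (nd.lo[k] - o[k]) * inv[k];
        double tb = (nd.hi[k] - o[k]) * inv[k];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 > t1 + 1e-12) { miss = true; break; }
      }
      if (miss) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int f = t->order[i];
          double a[3], b[3], c[3];
          faceVertex(*t, f, 0, a); faceVertex(*t, f, 1, b); faceVertex(*t, f, 2, c);
          double e1[3], e2[3], pvec[3], tvec[3], qvec[3];
          for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
          pvec[0] = d[1]*e2[2] - d[2]*e2[1];
          pvec[1] = d[2]*e2[0] - d[0]*e2[2];
          pvec[2] = d[0]*e2[1] - d[1]*e2[0];
          double det = e1[0]*pvec[0] + e1[1]*pvec[1] + e1[2]*pvec[2];
          if (std::fabs(det) < 1e-14) continue;
          double invDet = 1.0 / det;
          for (int k = 0; k < 3; ++k) tvec[k] = o[k] - a[k];
          double u = (tvec[0]*pvec[0] + tvec[1]*pvec[1] + tvec[2]*pvec[2]) * invDet;
          if (u < -1e-9 || u > 1.0 + 1e-9) continue;
          qvec[0] = tvec[1]*e1[2] - tvec[2]*e1[1];
          qvec[1] = tvec[2]*e1[0] - tvec[0]*e1[2];
          qvec[2] = tvec[0]*e1[1] - tvec[1]*e1[0];
          double v = (d[0]*qvec[0] + d[1]*qvec[1] + d[2]*qvec[2]) * invDet;
          if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
          double th = (e2[0]*qvec[0] + e2[1]*qvec[1] + e2[2]*qvec[2]) * invDet;
          if (th < -1e-9) continue;
          if (th < 0.0) th = 0.0;
          if (th < bestT || (th == bestT && f < bestFace)) { bestT = th; bestFace = f; }
        }
      } else {
        stack.push_back(nd.right);
        stack.push_back(nd.left);
      }
    }
    if (bestFace >= 0) {
      tout[q] = bestT;
      face[q] = bestFace + 1;
      for (int k = 0; k < 3; ++k) pt(q,k) = o[k] + bestT * d[k];
    } else {
      tout[q] = NA_REAL;
      face[q] = NA_INTEGER;
      for (int k = 0; k < 3; ++k) pt(q,k) = NA_REAL;
    }
  }
  return List::create(_["t"] = tout, _["point"] = pt, _["face"] = face);
}

// leaf inventory for structural checks: boxes and the face ids inside each leaf
// [[Rcpp::export]]
List bvh_leaves_cpp(SEXP ptr) {
  XPtr<BVH> t(ptr);
  std::vector<int> leafIdx;
  for (size_t i = 0; i < t->nodes.size(); ++i)
    if (t->nodes[i].left < 0) leafIdx.push_back((int)i);
  int nl = (int)leafIdx.size();
  NumericMatrix lo(nl, 3), hi(nl, 3);
  List faces(nl);
  for (int i = 0; i < nl; ++i) {
    const Node& nd = t->nodes[leafIdx[i]];
    for (int k = 0; k < 3; ++k) { lo(i,k) = nd.lo[k]; hi(i,k) = nd.hi[k]; }
    IntegerVector fv(nd.count);
    for (int j = 0; j < nd.count; ++j) fv[j] = t->order[nd.start + j] + 1;
    faces[i] = fv;
  }
  NumericMatrix root(2, 3);
  if (!t->nodes.empty())
    for (int k = 0; k < 3; ++k) { root(0,k) = t->nodes[0].lo[k]; root(1,k) = t->nodes[0].hi[k]; }
  return List::create(_["lo"] = lo, _["hi"] = hi, _["faces"] = faces, _["root"] = root);
}
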