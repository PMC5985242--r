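// Geometry kernel: exact nearest point-on-triangle queries over an AABB
// tree, with signed distances via angle-weighted pseudo-normals
// (Baerentzen & Aanaes 2005).  All coordinates in mm.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(const V3& a, double s) { return V3(a.x*s, a.y*s, a.z*s); }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
static inline V3 normalize(const V3& a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : V3(0, 0, 0);
}

// Closest-point regions: 0 face, 1/2/3 vertex a/b/c, 4 edge ab, 5 edge bc, 6 edge ca
enum Region { FACE = 0, VA = 1, VB = 2, VC = 3, EAB = 4, EBC = 5, ECA = 6 };

// Ericson, Real-Time Collision Detection, 5.1.5, extended with region codes.
static V3 closest_on_triangle(const V3& p, const V3& a, const V3& b, const V3& c,
                              int& region) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { region = VA; return a; }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { region = VB; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    region = EAB; return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { region = VC; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    region = ECA; return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    region = EBC; return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  region = FACE;
  return a + ab * v + ac * w;
}

struct AABB {
  V3 lo, hi;
  AABB() : lo(1e300, 1e300, 1e300), hi(-1e300, -1e300, -1e300) {}
  void grow(const V3& p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
  }
  void grow(const AABB& b) { grow(b.lo); grow(b.hi); }
  double dist2(const V3& p) const {
    double dx = std::max({lo.x - p.x, 0.0, p.x - hi.x});
    double dy = std::max({lo.y - p.y, 0.0, p.y - hi.y});
    double dz = std::max({lo.z - p.z, 0.0, p.z - hi.z});
    return dx * dx + dy * dy + dz * dz;
  }
};

struct BVHNode {
  AABB box;
  int left, right;     // child node indices, -1 for leaf
  int start, count;    // triangle index range for leaves
};

class MeshBVH {
 public:
  std::vector<V3> va, vb, vc;      // per-triangle vertices
  std::vector<int> order;          // BVH leaf order -> original triangle index
  std::vector<BVHNode> nodes;

  MeshBVH(const NumericMatrix& V, const IntegerMatrix& F) {
    int m = F.nrow();
    va.resize(m); vb.resize(m); vc.resize(m);
    std::vector<V3> cent(m);
    order.resize(m);
    for (int i = 0; i < m; ++i) {
      order[i] = i;
      va[i] = V3(V(F(i,0)-1,0), V(F(i,0)-1,1), V(F(i,0)-1,2));
      vb[i] = V3(V(F(i,1)-1,0), V(F(i,1)-1,1), V(F(i,1)-1,2));
      vc[i] = V3(V(F(i,2)-1,0), V(F(i,2)-1,1), V(F(i,2)-1,2));
      cent[i] = (va[i] + vb[i] + vc[i]) * (1.0 / 3.0);
    }
    nodes.reserve(2 * m / 4 + 2);
    build(0, m, cent);
  }

  // nearest triangle to p; returns squared distance, sets tri (original index),
  // closest point and region code
  double nearest(const V3& p, int& tri, V3& cp, int& region) const {
    double best = 1e300;
    tri = -1; region = FACE;
    search(0, p, best, tri, cp, region);
    return best;
  }

 private:
  int build(int start, int count, std::vector<V3>& cent) {
    BVHNode node;
    node.start = start; node.count = count; node.left = node.right = -1;
    for (int i = start; i < start + count; ++i) {
      node.box.grow(va[order[i]]);
      node.box.grow(vb[order[i]]);
      node.box.grow(vc[order[i]]);
    }
    int idx = (int)nodes.size();
    nodes.push_back(node);
    if (count <= 8) return idx;
    // split on the longest axis of the centroid bounds
    AABB cb;
    for (int i = start; i < start + count; ++i) cb.grow(cent[order[i]]);
    V3 ext = cb.hi - cb.lo;
    int axis = (ext.x >= ext.y && ext.x >= ext.z) ? 0 : (ext.y >= ext.z ? 1 : 2);
    double lo = axis == 0 ? cb.lo.x : (axis == 1 ? cb.lo.y : cb.lo.z);
    double hi = axis == 0 ? cb.hi.x : (axis == 1 ? cb.hi.y : cb.hi.z);
    if (hi - lo < 1e-12) return idx;   // degenerate spread: keep as leaf
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int a, int b) {
                       const V3 &pa = cent[a], &pb = cent[b];
                       double xa = axis == 0 ? pa.x : (axis == 1 ? pa.y : pa.z);
                       double xb = axis == 0 ? pb.x : (axis == 1 ? pb.y : pb.z);
                       return xa < xb;
                     });
    int l = build(start, mid - start, cent);
    int r = build(mid, start + count - mid, cent);
    nodes[idx].left = l;
    nodes[idx].right = r;
    nodes[idx].start = nodes[idx].count = -1;
    return idx;
  }

  void search(int ni, const V3& p, double& best, int& tri, V3& cp, int& region) const {
    const BVHNode& n = nodes[ni];
    if (n.box.dist2(p) >= best) return;
    if (n.left < 0) {
      for (int i = n.start; i < n.start + n.count; ++i) {
        int t = order[i];
        int reg;
        V3 q = closest_on_triangle(p, va[t], vb[t], vc[t], reg);
        V3 d = p - q;
        double d2 = dot(d, d);
        if (d2 < best) { best = d2; tri = t; cp = q; region = reg; }
      }
      return;
    }
    double dl = nodes[n.left].box.dist2(p), dr = nodes[n.right].box.dist2(p);
    if (dl < dr) {
      search(n.left, p, best, tri, cp, region);
      search(n.right, p, best, tri, cp, region);
    } else {
      search(n.right, p, best, tri, cp, region);
      search(n.left, p, best, tri, cp, region);
    }
  }
};

// [[Rcpp::export]]
List cpp_nearest_on_mesh(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  MeshBVH bvh(V, F);
  int n = query.nrow();
  NumericMatrix pts(n, 3);
  NumericVector dist(n);
  IntegerVector tri(n), region(n);
  for (int i = 0; i < n; ++i) {
    V3 p(query(i,0), query(i,1), query(i,2));
    int t, reg;
    V3 cp;
    double d2 = bvh.nearest(p, t, cp, reg);
    pts(i,0) = cp.x; pts(i,1) = cp.y; pts(i,2) = cp.z;
    dist[i] = std::sqrt(d2);
    tri[i] = t + 1;
    region[i] = reg;
  }
  return List::create(_["point"] = pts, _["distance"] = dist,
                      _["triangle"] = tri, _["region"] = region);
}

// Angle-weighted pseudo-normals for faces, edges and vertices; the sign of a
// query point is the sign of dot(p - closest, pseudo-normal at the closest
// feature), which is exact for watertight consistently oriented meshes.
// [[Rcpp::export]]
List cpp_signed_distance(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  int m = F.nrow(), nv = V.nrow();
  std::vector<V3> fnorm(m);           // unnormalized face normals (2*area weight)
  std::vector<V3> vnorm(nv, V3());    // angle-weighted vertex normals
  std::map<std::pair<int,int>, V3> enorm;
  for (int i = 0; i < m; ++i) {
    int ia = F(i,0)-1, ib = F(i,1)-1, ic = F(i,2)-1;
    V3 a(V(ia,0), V(ia,1), V(ia,2));
    V3 b(V(ib,0), V(ib,1), V(ib,2));
    V3 c(V(ic,0), V(ic,1), V(ic,2));
    V3 nf = normalize(cross(b - a, c - a));
    fnorm[i] = nf;
    // incident angles at each corner
    V3 eab = normalize(b - a), eac = normalize(c - a);
    V3 eba = normalize(a - b), ebc = normalize(c - b);
    V3 eca = normalize(a - c), ecb = normalize(b - c);
    auto ang = [](const V3& u, const V3& v) {
      double d = std::max(-1.0, std::min(1.0, dot(u, v)));
      return std::acos(d);
    };
    vnorm[ia] = vnorm[ia] + nf * ang(eab, eac);
    vnorm[ib] = vnorm[ib] + nf * ang(eba, ebc);
    vnorm[ic] = vnorm[ic] + nf * ang(eca, ecb);
    int e[3][2] = {{ia, ib}, {ib, ic}, {ic, ia}};
    for (int k = 0; k < 3; ++k) {
      std::pair<int,int> key(std::min(e[k][0], e[k][1]), std::max(e[k][0], e[k][1]));
      auto it = enorm.find(key);
      if (it == enorm.end()) enorm[key] = nf; else it->second = it->second + nf;
    }
  }
  MeshBVH bvh(V, F);
  int n = query.nrow();
  NumericVector sd(n);
  NumericMatrix pts(n, 3);
  IntegerVector tri(n);
  for (int i = 0; i < n; ++i) {
    V3 p(query(i,0), query(i,1), query(i,2));
    int t, reg;
    V3 cp;
    double d = std::sqrt(bvh.nearest(p, t, cp, reg));
    V3 nrm;
    int ia = F(t,0)-1, ib = F(t,1)-1, ic = F(t,2)-1;
    switch (reg) {
      case VA: nrm = vnorm[ia]; break;
      case VB: nrm = vnorm[ib]; break;
      case VC: nrm = vnorm[ic]; break;
      case EAB: nrm = enorm[{std::min(ia,ib), std::max(ia,ib)}]; break;
      case EBC: nrm = enorm[{std::min(ib,ic), std::max(ib,ic)}]; break;
      case ECA: nrm = enorm[{std::min(ic,ia), std::max(ic,ia)}]; break;
      default: nrm = fnorm[t];
    }
    double s = dot(p - cp, nrm);
    sd[i] = (s >= 0) ? d : -d;
    pts(i,0) = cp.x; pts(i,1) = cp.y; pts(i,2) = cp.z;
    tri[i] = t + 1;
  }
  return List::create(_["distance"] = sd, _["point"] = pts, _["triangle"] = tri);
}
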