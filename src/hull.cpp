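// Exact 3D convex hull volume via incremental insertion with full
// visibility scans. Points are metres; volume returned in cubic metres
// (the R wrapper converts to cm^3). Degenerate inputs (fewer than 4
// affinely independent points) signal an error; the R wrapper attaches
// context. Re-projected container clouds put every point on a smooth
// surface, so the hull can have O(n) vertices; the full O(F) scan per
// insertion stays tractable to ~1e5 points and, unlike an adjacency
// walk, keeps the visible set consistent under floating point.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <utility>
#include <deque>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;   // vertices, oriented outward
  Vec3 n;        // unnormalised outward normal
  double off;    // dot(n, vertex a)
  double nn;     // cached |n|
};

}  // namespace

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(NumericMatrix points) {
  const int n = points.nrow();
  if (n < 4) stop("degenerate geometry: fewer than 4 points");
  std::vector<Vec3> pts(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    pts[i] = Vec3{points(i, 0), points(i, 1), points(i, 2)};
    scale = std::max(scale, std::max(std::fabs(pts[i].x),
                     std::max(std::fabs(pts[i].y), std::fabs(pts[i].z))));
  }
  if (scale == 0.0) stop("degenerate geometry: all points at origin");
  const double eps = 1e-9 * scale;

  // Initial simplex from extreme points.
  int i0 = 0, i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = norm(sub(pts[i], pts[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= eps) stop("degenerate geometry: all points coincide");
  int i2 = -1;
  best = -1.0;
  Vec3 d01 = sub(pts[i1], pts[i0]);
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(d01, sub(pts[i], pts[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps * norm(d01))
    stop("degenerate geometry: points are collinear");
  Vec3 nrm = cross(d01, sub(pts[i2], pts[i0]));
  int i3 = -1;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(pts[i], pts[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps * norm(nrm))
    stop("degenerate geometry: points are coplanar");

  Vec3 inside{(pts[i0].x + pts[i1].x + pts[i2].x + pts[i3].x) / 4,
              (pts[i0].y + pts[i1].y + pts[i2].y + pts[i3].y) / 4,
              (pts[i0].z + pts[i1].z + pts[i2].z + pts[i3].z) / 4};

  // raw face: orientation taken from the vertex order (used for cone
  // faces, whose order is inherited combinatorially from the horizon)
  auto makeFaceRaw = [&](int a, int b, int c) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    f.n = cross(sub(pts[b], pts[a]), sub(pts[c], pts[a]));
    f.off = dot(f.n, pts[a]);
    f.nn = norm(f.n);
    return f;
  };
  // seed face: flipped so the simplex interior lies on the negative side
  auto makeFace = [&](int a, int b, int c) {
    Face f = makeFaceRaw(a, b, c);
    if (dot(f.n, inside) - f.off > 0) {
      std::swap(f.b, f.c);
      f.n = Vec3{-f.n.x, -f.n.y, -f.n.z};
      f.off = -f.off;
    }
    return f;
  };

  std::vector<Face> faces;
  faces.reserve(1024);
  faces.push_back(makeFace(i0, i1, i2));
  faces.push_back(makeFace(i0, i1, i3));
  faces.push_back(makeFace(i0, i2, i3));
  faces.push_back(makeFace(i1, i2, i3));

  // Incremental insertion with a full visibility scan over live faces:
  // a point inside the current hull is skipped; otherwise all faces it
  // sees are replaced by the cone over their horizon. The full scan
  // (rather than an adjacency walk) keeps the visible set geometrically
  // consistent under floating point, at O(F) per insertion.
  std::vector<char> vis;
  std::vector<std::pair<int, int>> edges;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    const Vec3 &q = pts[p];
    vis.assign(faces.size(), 0);
    bool any = false;
    for (size_t f = 0; f < faces.size(); ++f) {
      const Face &fc = faces[f];
      double d = dot(fc.n, q) - fc.off;
      if (d > eps * fc.nn) any = true;    // strictly outside some face
      if (d > -eps * fc.nn) vis[f] = 1;   // outside or near-coplanar
    }
    if (!any) continue;
    // horizon: directed edges of visible faces whose reverse belongs to
    // a hidden face (each directed edge belongs to exactly one face)
    edges.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!vis[f]) continue;
      int e[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c},
                     {faces[f].c, faces[f].a}};
      for (auto &ed : e) edges.push_back({ed[0], ed[1]});
    }
    std::sort(edges.begin(), edges.end());
    std::vector<std::pair<int, int>> horizon;
    for (auto &ed : edges) {
      if (!std::binary_search(edges.begin(), edges.end(),
                              std::make_pair(ed.second, ed.first)))
        horizon.push_back(ed);
    }
    // the horizon must form closed vertex-disjoint cycles (each vertex
    // one outgoing, one incoming edge); a numerically inconsistent
    // horizon would corrupt the face structure, so such (necessarily
    // near-coplanar) points are skipped instead
    bool consistent = !horizon.empty();
    if (consistent) {
      std::vector<int> outs, ins;
      for (auto &ed : horizon) {
        outs.push_back(ed.first);
        ins.push_back(ed.second);
      }
      std::sort(outs.begin(), outs.end());
      std::sort(ins.begin(), ins.end());
      consistent = outs == ins &&
        std::adjacent_find(outs.begin(), outs.end()) == outs.end();
    }
    if (!consistent) continue;
    // drop visible faces (swap-compact), then add the cone; new faces
    // inherit the horizon edge direction, keeping orientation globally
    // consistent
    size_t w = 0;
    for (size_t f = 0; f < faces.size(); ++f)
      if (!vis[f]) faces[w++] = faces[f];
    faces.resize(w);
    for (auto &ed : horizon)
      faces.push_back(makeFaceRaw(ed.first, ed.second, p));
  }

  double vol6 = 0.0;
  for (auto &f : faces)
    vol6 += dot(sub(pts[f.a], inside),
                cross(sub(pts[f.b], inside), sub(pts[f.c], inside)));
  return vol6 / 6.0;
}

// CRC-32 (ISO 3309) over a raw vector, as used by PNG chunks.
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFu);
}
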