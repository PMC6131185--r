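// Laguerre (power) diagram construction by direct cell clipping.
//
// Each cell starts as the bounded region (axis-aligned box, optionally cut by
// extra fixed planes, e.g. a polyhedral ball) and is clipped by the radical
// plane against every other site that can possibly cut it.  Candidates are
// scanned in order of increasing distance with a security-radius early stop:
// once (|d|^2 + w_i - w_max) / (2|d|) exceeds the current max vertex distance
// from the site, no further site can cut the cell.  This is the algorithm of
// radical Voronoi codes (Voro++); it yields volumes, polygonal interface
// faces and the dual adjacency graph from a single primitive.

#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Cell {
  std::vector<double> px, py, pz;         // vertex coordinates
  std::vector< std::vector<int> > faces;  // ordered vertex indices per face
  std::vector<int> nb;                    // neighbour site (0-based) or wall code (< 0)
  bool empty;
  Cell() : empty(false) {}
  void clear() { px.clear(); py.clear(); pz.clear(); faces.clear(); nb.clear(); }
};

void initBox(Cell &c, const double *lo, const double *hi) {
  const double V[8][3] = {
    {lo[0], lo[1], lo[2]}, {hi[0], lo[1], lo[2]}, {hi[0], hi[1], lo[2]}, {lo[0], hi[1], lo[2]},
    {lo[0], lo[1], hi[2]}, {hi[0], lo[1], hi[2]}, {hi[0], hi[1], hi[2]}, {lo[0], hi[1], hi[2]}};
  for (int k = 0; k < 8; ++k) {
    c.px.push_back(V[k][0]); c.py.push_back(V[k][1]); c.pz.push_back(V[k][2]);
  }
  const int F[6][4] = {{0, 3, 2, 1}, {4, 5, 6, 7}, {0, 1, 5, 4},
                       {3, 7, 6, 2}, {0, 4, 7, 3}, {1, 2, 6, 5}};
  // wall codes: -1 x_lo, -2 x_hi, -3 y_lo, -4 y_hi, -5 z_lo, -6 z_hi
  const int NB[6] = {-5, -6, -3, -4, -1, -2};
  for (int f = 0; f < 6; ++f) {
    c.faces.push_back(std::vector<int>(F[f], F[f] + 4));
    c.nb.push_back(NB[f]);
  }
}

// Clip cell by half-space  n . x <= c0 ; nbid identifies the cutting plane.
void clipCell(Cell &cell, double nx, double ny, double nz, double c0,
              int nbid, double eps) {
  if (cell.empty) return;
  const size_t m = cell.px.size();
  if (m == 0) { cell.empty = true; return; }
  std::vector<double> d(m);
  int nOut = 0, nIn = 0;
  for (size_t k = 0; k < m; ++k) {
    d[k] = nx * cell.px[k] + ny * cell.py[k] + nz * cell.pz[k] - c0;
    if (d[k] > eps) ++nOut; else if (d[k] < -eps) ++nIn;
  }
  if (nOut == 0) return;                      // untouched (grazing contact ignored)
  if (nIn == 0) { cell.empty = true; cell.clear(); return; }

  std::vector<int> remap(m, -1);
  std::vector<double> qx, qy, qz;
  std::vector<char> onPlane;
  for (size_t k = 0; k < m; ++k) {
    if (d[k] <= eps) {
      remap[k] = (int) qx.size();
      qx.push_back(cell.px[k]); qy.push_back(cell.py[k]); qz.push_back(cell.pz[k]);
      onPlane.push_back(std::fabs(d[k]) <= eps ? 1 : 0);
    }
  }
  std::unordered_map<long long, int> cache;
  std::vector< std::vector<int> > nfaces;
  std::vector<int> nnb;

  for (size_t f = 0; f < cell.faces.size(); ++f) {
    const std::vector<int> &poly = cell.faces[f];
    const int L = (int) poly.size();
    std::vector<int> np;
    for (int k = 0; k < L; ++k) {
      const int a = poly[k], b = poly[(k + 1) % L];
      if (d[a] <= eps) np.push_back(remap[a]);
      if ((d[a] < -eps && d[b] > eps) || (d[a] > eps && d[b] < -eps)) {
        long long key = (long long) std::min(a, b) * (long long) m + std::max(a, b);
        std::unordered_map<long long, int>::iterator it = cache.find(key);
        int idx;
        if (it != cache.end()) idx = it->second;
        else {
          const double t = d[a] / (d[a] - d[b]);
          idx = (int) qx.size();
          qx.push_back(cell.px[a] + t * (cell.px[b] - cell.px[a]));
          qy.push_back(cell.py[a] + t * (cell.py[b] - cell.py[a]));
          qz.push_back(cell.pz[a] + t * (cell.pz[b] - cell.pz[a]));
          onPlane.push_back(1);
          cache[key] = idx;
        }
        np.push_back(idx);
      }
    }
    if ((int) np.size() >= 3) { nfaces.push_back(np); nnb.push_back(cell.nb[f]); }
  }

  // Cap face: all on-plane vertices of the (convex) cell, sorted by angle.
  std::vector<int> cap;
  for (size_t k = 0; k < qx.size(); ++k) if (onPlane[k]) cap.push_back((int) k);
  if (cap.size() >= 3) {
    double ax, ay, az;
    if (std::fabs(nx) < 0.9) { ax = 1; ay = 0; az = 0; } else { ax = 0; ay = 1; az = 0; }
    double ux = ay * nz - az * ny, uy = az * nx - ax * nz, uz = ax * ny - ay * nx;
    const double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    const double vx = ny * uz - nz * uy, vy = nz * ux - nx * uz, vz = nx * uy - ny * ux;
    double cx = 0, cy = 0, cz = 0;
    for (size_t k = 0; k < cap.size(); ++k) { cx += qx[cap[k]]; cy += qy[cap[k]]; cz += qz[cap[k]]; }
    cx /= cap.size(); cy /= cap.size(); cz /= cap.size();
    std::vector< std::pair<double, int> > ang;
    for (size_t k = 0; k < cap.size(); ++k) {
      const int id = cap[k];
      const double wx = qx[id] - cx, wy = qy[id] - cy, wz = qz[id] - cz;
      ang.push_back(std::make_pair(
        std::atan2(wx * vx + wy * vy + wz * vz, wx * ux + wy * uy + wz * uz), id));
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> cp;
    for (size_t k = 0; k < ang.size(); ++k) cp.push_back(ang[k].second);
    nfaces.push_back(cp); nnb.push_back(nbid);
  }

  cell.px.swap(qx); cell.py.swap(qy); cell.pz.swap(qz);
  cell.faces.swap(nfaces); cell.nb.swap(nnb);
  if (cell.faces.size() < 4) { cell.empty = true; cell.clear(); }
}

double faceArea(const Cell &c, const std::vector<int> &poly) {
  // vector area (robust for planar, possibly collinear-point polygons)
  double sx = 0, sy = 0, sz = 0;
  const int L = (int) poly.size();
  const double ox = c.px[poly[0]], oy = c.py[poly[0]], oz = c.pz[poly[0]];
  for (int k = 1; k + 1 < L; ++k) {
    const double ax = c.px[poly[k]] - ox, ay = c.py[poly[k]] - oy, az = c.pz[poly[k]] - oz;
    const double bx = c.px[poly[k + 1]] - ox, by = c.py[poly[k + 1]] - oy, bz = c.pz[poly[k + 1]] - oz;
    sx += ay * bz - az * by; sy += az * bx - ax * bz; sz += ax * by - ay * bx;
  }
  return 0.5 * std::sqrt(sx * sx + sy * sy + sz * sz);
}

double cellVolume(const Cell &c) {
  if (c.empty || c.px.empty()) return 0.0;
  const size_t m = c.px.size();
  double cx = 0, cy = 0, cz = 0;
  for (size_t k = 0; k < m; ++k) { cx += c.px[k]; cy += c.py[k]; cz += c.pz[k]; }
  cx /= m; cy /= m; cz /= m;
  double vol = 0;
  for (size_t f = 0; f < c.faces.size(); ++f) {
    const std::vector<int> &poly = c.faces[f];
    const double ox = c.px[poly[0]] - cx, oy = c.py[poly[0]] - cy, oz = c.pz[poly[0]] - cz;
    for (size_t k = 1; k + 1 < poly.size(); ++k) {
      const double ax = c.px[poly[k]] - cx, ay = c.py[poly[k]] - cy, az = c.pz[poly[k]] - cz;
      const double bx = c.px[poly[k + 1]] - cx, by = c.py[poly[k + 1]] - cy, bz = c.pz[poly[k + 1]] - cz;
      // |(o x a) . b| / 6  (tetra from interior centroid: always positive for convex cell)
      const double det = ox * (ay * bz - az * by) - oy * (ax * bz - az * bx) + oz * (ax * by - ay * bx);
      vol += std::fabs(det) / 6.0;
    }
  }
  return vol;
}

double maxVertexDist(const Cell &c, double x, double y, double z) {
  double r2 = 0;
  for (size_t k = 0; k < c.px.size(); ++k) {
    const double dx = c.px[k] - x, dy = c.py[k] - y, dz = c.pz[k] - z;
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > r2) r2 = d2;
  }
  return std::sqrt(r2);
}

}  // namespace

// [[Rcpp::export]]
List laguerre_cpp(NumericMatrix pts, NumericVector w, NumericVector boxlo,
                  NumericVector boxhi, NumericMatrix extraPlanes,
                  double epsScale, double sliverTol) {
  const int n = pts.nrow();
  if (n < 2) stop("at least 2 sites are required");
  const double lo[3] = {boxlo[0], boxlo[1], boxlo[2]};
  const double hi[3] = {boxhi[0], boxhi[1], boxhi[2]};
  const double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                                (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                                (hi[2] - lo[2]) * (hi[2] - lo[2]));
  const double eps = epsScale * diag;
  double wmax = 0;
  for (int i = 0; i < n; ++i) if (w[i] > wmax) wmax = w[i];

  NumericVector volumes(n);
  LogicalVector emptyFlag(n), boundaryFlag(n);
  std::vector<int> fi, fj;
  std::vector<double> farea;
  std::vector<NumericMatrix> polyStore;   // NumericMatrix self-protects its SEXP
  std::vector<int> ord(n);

  // distance-sorted candidate scan, cell by cell
  std::vector<double> dist2(n);
  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    Cell cell;
    initBox(cell, lo, hi);
    for (int p = 0; p < extraPlanes.nrow(); ++p)
      clipCell(cell, extraPlanes(p, 0), extraPlanes(p, 1), extraPlanes(p, 2),
               extraPlanes(p, 3), -(7 + p), eps);

    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      dist2[j] = dx * dx + dy * dy + dz * dz;
      ord[j] = j;
    }
    dist2[i] = -1.0;
    std::sort(ord.begin(), ord.end(),
              [&dist2](int a, int b) { return dist2[a] < dist2[b]; });

    double rmax = maxVertexDist(cell, xi, yi, zi);
    for (int q = 1; q < n; ++q) {           // ord[0] == i itself
      if (cell.empty) break;
      const int j = ord[q];
      const double d2 = dist2[j];
      if (d2 < 1e-24) {
        if (w[j] > w[i]) { cell.empty = true; cell.clear(); break; }
        if (w[j] == w[i])
          stop("coincident sites with identical weight (ids %d, %d)", i + 1, j + 1);
        continue;                            // heavier i swallows j, no plane
      }
      const double dd = std::sqrt(d2);
      if ((d2 + w[i] - wmax) / (2.0 * dd) > rmax) break;   // no later site can cut
      const double t = (d2 + w[i] - w[j]) / (2.0 * dd);
      if (t > rmax) continue;
      const double nx = (pts(j, 0) - xi) / dd, ny = (pts(j, 1) - yi) / dd,
                   nz = (pts(j, 2) - zi) / dd;
      const double c0 = nx * xi + ny * yi + nz * zi + t;
      const size_t before = cell.px.size();
      clipCell(cell, nx, ny, nz, c0, j, eps);
      if (cell.empty) break;
      if (cell.px.size() != before || true)  // cheap: recompute after any clip attempt
        rmax = maxVertexDist(cell, xi, yi, zi);
    }

    volumes[i] = cellVolume(cell);
    emptyFlag[i] = cell.empty;
    if (!cell.empty) {
      bool touchesWall = false;
      for (size_t f = 0; f < cell.faces.size(); ++f) {
        const double a = faceArea(cell, cell.faces[f]);
        if (a <= sliverTol) continue;
        const int nb = cell.nb[f];
        if (nb < 0) touchesWall = true;
        if (nb < 0 || nb > i) {              // emit each site pair once (from smaller id)
          const std::vector<int> &poly = cell.faces[f];
          NumericMatrix P((int) poly.size(), 3);
          for (size_t k = 0; k < poly.size(); ++k) {
            P(k, 0) = cell.px[poly[k]]; P(k, 1) = cell.py[poly[k]]; P(k, 2) = cell.pz[poly[k]];
          }
          fi.push_back(i + 1);
          fj.push_back(nb < 0 ? nb : nb + 1);
          farea.push_back(a);
          polyStore.push_back(P);
        }
      }
      boundaryFlag[i] = touchesWall;
    }
  }

  List polys(polyStore.size());
  for (size_t k = 0; k < polyStore.size(); ++k) polys[k] = polyStore[k];
  return List::create(_["volumes"] = volumes,
                      _["empty"] = emptyFlag,
                      _["boundary"] = boundaryFlag,
                      _["face_i"] = wrap(fi),
                      _["face_j"] = wrap(fj),
                      _["face_area"] = wrap(farea),
                      _["face_poly"] = polys);
}

// Volume of  box  intersected with half-spaces  n . x <= c  (rows of planes).
// [[Rcpp::export]]
double clip_polytope_volume_cpp(NumericVector boxlo, NumericVector boxhi,
                                NumericMatrix planes, double epsScale) {
  const double lo[3] = {boxlo[0], boxlo[1], boxlo[2]};
  const double hi[3] = {boxhi[0], boxhi[1], boxhi[2]};
  const double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                                (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                                (hi[2] - lo[2]) * (hi[2] - lo[2]));
  Cell cell;
  initBox(cell, lo, hi);
  for (int p = 0; p < planes.nrow(); ++p)
    clipCell(cell, planes(p, 0), planes(p, 1), planes(p, 2), planes(p, 3),
             -(7 + p), epsScale * diag);
  return cellVolume(cell);
}

// Merge 3D points closer than tol (grid hash + 27-neighbourhood union-find).
// Returns 1-based cluster id per point.
// [[Rcpp::export]]
IntegerVector dedup_points_cpp(NumericMatrix pts, double tol) {
  const int n = pts.nrow();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const double h = tol * 2.0;
  std::unordered_map<long long, std::vector<int> > grid;
  std::vector<long long> kx(n), ky(n), kz(n);
  for (int i = 0; i < n; ++i) {
    kx[i] = (long long) std::floor(pts(i, 0) / h);
    ky[i] = (long long) std::floor(pts(i, 1) / h);
    kz[i] = (long long) std::floor(pts(i, 2) / h);
    const long long key = (kx[i] * 73856093LL) ^ (ky[i] * 19349663LL) ^ (kz[i] * 83492791LL);
    grid[key].push_back(i);
  }
  const double tol2 = tol * tol;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) for (int dz = -1; dz <= 1; ++dz) {
      const long long key = ((kx[i] + dx) * 73856093LL) ^ ((ky[i] + dy) * 19349663LL) ^ ((kz[i] + dz) * 83492791LL);
      std::unordered_map<long long, std::vector<int> >::iterator it = grid.find(key);
      if (it == grid.end()) continue;
      const std::vector<int> &cand = it->second;
      for (size_t c = 0; c < cand.size(); ++c) {
        const int j = cand[c];
        if (j <= i) continue;
        const double ax = pts(i, 0) - pts(j, 0), ay = pts(i, 1) - pts(j, 1), az = pts(i, 2) - pts(j, 2);
        if (ax * ax + ay * ay + az * az <= tol2) {
          const int ri = find(i), rj = find(j);
          if (ri != rj) parent[rj] = ri;
        }
      }
    }
  }
  IntegerVector out(n);
  std::unordered_map<int, int> label;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const int r = find(i);
    std::unordered_map<int, int>::iterator it = label.find(r);
    if (it == label.end()) { label[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}

// For each query point, Euclidean distance to the nearest reference point.
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    const double x = query(i, 0), y = query(i, 1), z = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - x, dy = ref(j, 1) - y, dz = ref(j, 2) - z;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each query point, index (1-based) of the nearest reference point.
// [[Rcpp::export]]
IntegerVector nn_index_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf; int bj = 0;
    const double x = query(i, 0), y = query(i, 1), z = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = ref(j, 0) - x, dy = ref(j, 1) - y, dz = ref(j, 2) - z;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

// Check probe containment in an assigned cell given per-cell plane sets.
// planes: K x 4 (nx, ny, nz, c); cellStart/cellCount give each cell's slice
// (0-based start). Returns TRUE if probe satisfies n.x <= c + tol for all
// planes of its assigned cell.
// [[Rcpp::export]]
LogicalVector probe_in_cell_cpp(NumericMatrix probes, IntegerVector assign,
                                NumericMatrix planes, IntegerVector cellStart,
                                IntegerVector cellCount, double tol) {
  const int m = probes.nrow();
  LogicalVector out(m);
  for (int i = 0; i < m; ++i) {
    const int c = assign[i] - 1;
    const int s = cellStart[c], k = cellCount[c];
    bool ok = true;
    for (int p = s; p < s + k; ++p) {
      const double v = planes(p, 0) * probes(i, 0) + planes(p, 1) * probes(i, 1) +
                       planes(p, 2) * probes(i, 2) - planes(p, 3);
      if (v > tol) { ok = false; break; }
    }
    out[i] = ok;
  }
  return out;
}
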