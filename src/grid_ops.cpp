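#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel grids are passed flat in R's column-major order:
// index = x + nx * (y + ny * z), all 0-based here.

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (size_t)ny * z);
}

// ---- connected components (26-connectivity) --------------------------------

// [[Rcpp::export]]
List cpp_label_components(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<int> sizes;
  std::vector<int> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (mask[i] == 0 || labels[i] != 0) continue;
    cur++;
    int sz = 0;
    stack.clear();
    stack.push_back((int)i);
    labels[i] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      sz++;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            int w = vidx(xx, yy, zz, nx, ny);
            if (mask[w] != 0 && labels[w] == 0) {
              labels[w] = cur;
              stack.push_back(w);
            }
          }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// ---- Euclidean distance transform (Felzenszwalb-Huttenlocher) --------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h2) {
  // squared distances; f uses a large finite sentinel instead of Inf so the
  // parabola intersection arithmetic stays well defined
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * (double)v[k] * v[k])) /
               (2.0 * h2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * (double)v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = h2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Distance (mm) from each foreground voxel to the nearest background voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e20;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] != 0 ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) f[x] = g[vidx(x, y, zz, nx, ny)];
      dt1d(f, d, v, z, nx, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; x++) g[vidx(x, y, zz, nx, ny)] = d[x];
    }
  // y pass
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++) f[y] = g[vidx(x, y, zz, nx, ny)];
      dt1d(f, d, v, z, ny, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; y++) g[vidx(x, y, zz, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      for (int zz = 0; zz < nz; zz++) f[zz] = g[vidx(x, y, zz, nx, ny)];
      dt1d(f, d, v, z, nz, spacing[2] * spacing[2]);
      for (int zz = 0; zz < nz; zz++) g[vidx(x, y, zz, nx, ny)] = d[zz];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  return out;
}

// ---- Dijkstra on the foreground voxel graph --------------------------------

// Edge cost between 26-neighbours a, b: euclidean step length times the mean
// of the per-voxel weights (all-ones weights give geodesic distance in mm).
// [[Rcpp::export]]
List cpp_grid_dijkstra(IntegerVector mask, IntegerVector dims, NumericVector spacing,
                       int source, NumericVector weight) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  bool unit = weight.size() == 0;

  // precompute the 26 neighbour offsets and step lengths
  int offs[26][3]; double slen[26]; int m = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs[m][0] = dx; offs[m][1] = dy; offs[m][2] = dz;
        slen[m] = std::sqrt(dx * dx * spacing[0] * spacing[0] +
                            dy * dy * spacing[1] * spacing[1] +
                            dz * dz * spacing[2] * spacing[2]);
        m++;
      }

  std::vector<double> dist(n, INF);
  IntegerVector parent(n, -1);
  typedef std::pair<double, int> Q;
  std::priority_queue<Q, std::vector<Q>, std::greater<Q> > pq;
  dist[source] = 0.0;
  pq.push(Q(0.0, source));
  while (!pq.empty()) {
    Q top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    int x = u % nx, y = (u / nx) % ny, zc = u / (nx * ny);
    double wu = unit ? 1.0 : weight[u];
    for (int k = 0; k < 26; k++) {
      int xx = x + offs[k][0], yy = y + offs[k][1], zz = zc + offs[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int v = vidx(xx, yy, zz, nx, ny);
      if (mask[v] == 0) continue;
      double wv = unit ? 1.0 : weight[v];
      double nd = dist[u] + slen[k] * 0.5 * (wu + wv);
      if (nd < dist[v]) {
        dist[v] = nd;
        parent[v] = u;
        pq.push(Q(nd, v));
      }
    }
  }
  NumericVector dout(n);
  for (R_xlen_t i = 0; i < n; i++) dout[i] = dist[i];
  return List::create(_["dist"] = dout, _["parent"] = parent);
}

// ---- trilinear interpolation ------------------------------------------------

// pts: N x 3 continuous 0-based voxel coordinates; outside the grid -> 0.
// [[Rcpp::export]]
NumericVector cpp_interp_trilinear(NumericVector grid, IntegerVector dims,
                                   NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int npt = pts.nrow();
  NumericVector out(npt);
  for (int i = 0; i < npt; i++) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = 0.0; continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double c000 = grid[vidx(x0, y0, z0, nx, ny)], c100 = grid[vidx(x1, y0, z0, nx, ny)];
    double c010 = grid[vidx(x0, y1, z0, nx, ny)], c110 = grid[vidx(x1, y1, z0, nx, ny)];
    double c001 = grid[vidx(x0, y0, z1, nx, ny)], c101 = grid[vidx(x1, y0, z1, nx, ny)];
    double c011 = grid[vidx(x0, y1, z1, nx, ny)], c111 = grid[vidx(x1, y1, z1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// ---- nearest centerline sample assignment -----------------------------------

// Brute force nearest neighbour: pts N x 3 (mm), samples M x 3 (mm).
// Returns 1-based index of the nearest sample per point.
// [[Rcpp::export]]
IntegerVector cpp_nearest_sample(NumericMatrix pts, NumericMatrix samples) {
  const int n = pts.nrow(), m = samples.nrow();
  IntegerVector out(n);
  std::vector<double> sx(m), sy(m), sz(m);
  for (int j = 0; j < m; j++) { sx[j] = samples(j, 0); sy[j] = samples(j, 1); sz[j] = samples(j, 2); }
  for (int i = 0; i < n; i++) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < m; j++) {
      double dx = px - sx[j], dy = py - sy[j], dz = pz - sz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

// ---- phantom tube voxelization ----------------------------------------------

// Fill voxels within r(s) of a densely sampled curve; each voxel is assigned
// to its nearest curve sample, included when its distance is <= that sample's
// radius, and labelled TL / CFL / TH by the angular position of its radial
// vector in the sample's transported (normal, binormal) frame.
// Flat end caps: voxels projecting beyond the first/last sample are excluded.
// [[Rcpp::export]]
IntegerVector cpp_voxelize_tube(IntegerVector dims, NumericVector spacing,
                                NumericVector origin, NumericMatrix curve,
                                NumericMatrix tangents, NumericMatrix normals,
                                NumericMatrix binormals, NumericVector radii,
                                double ds, double fl_fraction, double th_fraction,
                                IntegerVector codes) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int m = curve.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<float> dist2(n, (float)INF);
  std::vector<int> arg(n, -1);

  for (int j = 0; j < m; j++) {
    double rstamp = radii[j] + ds + std::max(spacing[0], std::max(spacing[1], spacing[2]));
    double px = curve(j, 0), py = curve(j, 1), pz = curve(j, 2);
    int x0 = (int)std::floor((px - rstamp - origin[0]) / spacing[0]);
    int x1 = (int)std::ceil((px + rstamp - origin[0]) / spacing[0]);
    int y0 = (int)std::floor((py - rstamp - origin[1]) / spacing[1]);
    int y1 = (int)std::ceil((py + rstamp - origin[1]) / spacing[1]);
    int z0 = (int)std::floor((pz - rstamp - origin[2]) / spacing[2]);
    int z1 = (int)std::ceil((pz + rstamp - origin[2]) / spacing[2]);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 > nx - 1) x1 = nx - 1;
    if (y1 > ny - 1) y1 = ny - 1;
    if (z1 > nz - 1) z1 = nz - 1;
    double r2max = rstamp * rstamp;
    for (int zc = z0; zc <= z1; zc++) {
      double wz = origin[2] + zc * spacing[2] - pz;
      for (int y = y0; y <= y1; y++) {
        double wy = origin[1] + y * spacing[1] - py;
        double wyz = wy * wy + wz * wz;
        if (wyz > r2max) continue;
        for (int x = x0; x <= x1; x++) {
          double wx = origin[0] + x * spacing[0] - px;
          double d2 = wx * wx + wyz;
          if (d2 > r2max) continue;
          R_xlen_t v = vidx(x, y, zc, nx, ny);
          if (d2 < dist2[v]) { dist2[v] = (float)d2; arg[v] = j; }
        }
      }
    }
  }

  const double twopi = 2.0 * M_PI;
  IntegerVector labels(n, 0);
  for (R_xlen_t v = 0; v < n; v++) {
    int j = arg[v];
    if (j < 0) continue;
    double d = std::sqrt((double)dist2[v]);
    if (d > radii[j]) continue;
    int x = (int)(v % nx), y = (int)((v / nx) % ny), zc = (int)(v / ((R_xlen_t)nx * ny));
    double ex = origin[0] + x * spacing[0] - curve(j, 0);
    double ey = origin[1] + y * spacing[1] - curve(j, 1);
    double ez = origin[2] + zc * spacing[2] - curve(j, 2);
    double t = ex * tangents(j, 0) + ey * tangents(j, 1) + ez * tangents(j, 2);
    // flat caps at the curve extremities
    if (j == 0 && t < -0.5 * ds) continue;
    if (j == m - 1 && t > 0.5 * ds) continue;
    double cn = ex * normals(j, 0) + ey * normals(j, 1) + ez * normals(j, 2);
    double cb = ex * binormals(j, 0) + ey * binormals(j, 1) + ez * binormals(j, 2);
    double theta = std::atan2(cb, cn);
    if (theta < 0) theta += twopi;
    int lab;
    if (fl_fraction <= 0.0) lab = codes[0];            // all TL
    else if (theta < twopi * fl_fraction * th_fraction) lab = codes[2];  // TH
    else if (theta < twopi * fl_fraction) lab = codes[1];                // CFL
    else lab = codes[0];                                                  // TL
    labels[v] = lab;
  }
  return labels;
}
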