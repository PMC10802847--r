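// Geometry kernels: marching tetrahedra on a binary voxel field, 3-D
// connected-component labelling, and a z-buffer triangle rasterizer for
// deterministic scene snapshots.
#include <Rcpp.h>
#include <map>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 6-connectivity connected components; mask is an integer (0/1) 3-D array.
// [[Rcpp::export(name = ".cc_label3d_cpp")]]
IntegerVector cc_label3d_cpp(IntegerVector mask) {
  IntegerVector dm = mask.attr("dim");
  const int nr = dm[0], nc = dm[1], ns = dm[2];
  const size_t n = (size_t)nr * nc * ns;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dm;
  const int* m = mask.begin();
  int* L = lab.begin();
  const int d_off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int next = 0;
  std::queue<size_t> q;
  for (size_t s0 = 0; s0 < n; ++s0) {
    if (!m[s0] || L[s0]) continue;
    ++next;
    L[s0] = next;
    q.push(s0);
    while (!q.empty()) {
      size_t v = q.front(); q.pop();
      const int i = v % nr, j = (v / nr) % nc, k = v / ((size_t)nr * nc);
      for (int d = 0; d < 6; ++d) {
        const int ii = i + d_off[d][0], jj = j + d_off[d][1], kk = k + d_off[d][2];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || kk < 0 || kk >= ns) continue;
        const size_t w = ii + (size_t)jj * nr + (size_t)kk * nr * nc;
        if (m[w] && !L[w]) { L[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// --- marching tetrahedra -------------------------------------------------
// The cell between 8 neighbouring voxel centres is split into 6 tetrahedra
// around the (0,0,0)-(1,1,1) diagonal; surface vertices sit at edge
// midpoints of the binary field (iso-level 0.5). Triangles are oriented
// outward (from foreground to background). The decomposition is consistent
// across shared cell faces, so the surface of a padded field is watertight.

static const int TET[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
// corner offsets (x=col-like? no: we use (i,j,k) = array dims directly)
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};

struct MeshAcc {
  std::map<std::pair<size_t,size_t>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_vert(MeshAcc& M, size_t ga, size_t gb,
                     const double* px, const double* py, const double* pz) {
  if (ga > gb) std::swap(ga, gb);
  auto key = std::make_pair(ga, gb);
  auto it = M.edge_vertex.find(key);
  if (it != M.edge_vertex.end()) return it->second;
  const int id = (int)M.vx.size();
  M.vx.push_back(0.5 * (px[ga] + px[gb]));
  M.vy.push_back(0.5 * (py[ga] + py[gb]));
  M.vz.push_back(0.5 * (pz[ga] + pz[gb]));
  M.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MeshAcc& M, int a, int b, int c,
                     double rx, double ry, double rz) {
  // orient so the normal has positive dot with r (inside -> outside)
  const double ux = M.vx[b] - M.vx[a], uy = M.vy[b] - M.vy[a], uz = M.vz[b] - M.vz[a];
  const double wx = M.vx[c] - M.vx[a], wy = M.vy[c] - M.vy[a], wz = M.vz[c] - M.vz[a];
  const double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  if (nx * rx + ny * ry + nz * rz < 0) std::swap(b, c);
  M.f0.push_back(a); M.f1.push_back(b); M.f2.push_back(c);
}

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(IntegerVector field, NumericVector spacing,
                    NumericVector origin) {
  IntegerVector dm = field.attr("dim");
  const int nr = dm[0], nc = dm[1], ns = dm[2];
  const int* F = field.begin();
  // pre-compute physical coordinates of voxel centres along each axis:
  // x follows columns, y follows rows, z follows slices (image convention)
  std::vector<double> cy(nr), cx(nc), cz(ns);
  for (int i = 0; i < nr; ++i) cy[i] = (origin[1] + i) * spacing[1];
  for (int j = 0; j < nc; ++j) cx[j] = (origin[0] + j) * spacing[0];
  for (int k = 0; k < ns; ++k) cz[k] = (origin[2] + k) * spacing[2];

  const size_t npts = (size_t)nr * nc * ns;
  std::vector<double> px(npts), py(npts), pz(npts);
  for (int k = 0; k < ns; ++k)
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        const size_t g = i + (size_t)j * nr + (size_t)k * nr * nc;
        px[g] = cx[j]; py[g] = cy[i]; pz[g] = cz[k];
      }

  MeshAcc M;
  size_t gid[8];
  int val[8];
  for (int k = 0; k + 1 < ns; ++k)
    for (int j = 0; j + 1 < nc; ++j)
      for (int i = 0; i + 1 < nr; ++i) {
        int any1 = 0, any0 = 0;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + CORNER[c][0], jj = j + CORNER[c][1], kk = k + CORNER[c][2];
          gid[c] = ii + (size_t)jj * nr + (size_t)kk * nr * nc;
          val[c] = F[gid[c]] != 0;
          any1 |= val[c]; any0 |= !val[c];
        }
        if (!any1 || !any0) continue;
        for (int t = 0; t < 6; ++t) {
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            const int v = TET[t][c];
            if (val[v]) in_idx[nin++] = v; else out_idx[nout++] = v;
          }
          if (nin == 0 || nin == 4) continue;
          // reference direction: inside centroid -> outside centroid
          double ix = 0, iy = 0, iz = 0, ox = 0, oy = 0, oz = 0;
          for (int c = 0; c < nin; ++c) {
            ix += px[gid[in_idx[c]]]; iy += py[gid[in_idx[c]]]; iz += pz[gid[in_idx[c]]];
          }
          for (int c = 0; c < nout; ++c) {
            ox += px[gid[out_idx[c]]]; oy += py[gid[out_idx[c]]]; oz += pz[gid[out_idx[c]]];
          }
          const double rx = ox / nout - ix / nin, ry = oy / nout - iy / nin,
                       rz = oz / nout - iz / nin;
          if (nin == 1) {
            const int a = edge_vert(M, gid[in_idx[0]], gid[out_idx[0]], px.data(), py.data(), pz.data());
            const int b = edge_vert(M, gid[in_idx[0]], gid[out_idx[1]], px.data(), py.data(), pz.data());
            const int c = edge_vert(M, gid[in_idx[0]], gid[out_idx[2]], px.data(), py.data(), pz.data());
            emit_tri(M, a, b, c, rx, ry, rz);
          } else if (nin == 3) {
            const int a = edge_vert(M, gid[in_idx[0]], gid[out_idx[0]], px.data(), py.data(), pz.data());
            const int b = edge_vert(M, gid[in_idx[1]], gid[out_idx[0]], px.data(), py.data(), pz.data());
            const int c = edge_vert(M, gid[in_idx[2]], gid[out_idx[0]], px.data(), py.data(), pz.data());
            emit_tri(M, a, b, c, rx, ry, rz);
          } else {  // 2 in, 2 out: quad across four cut edges
            const int a = edge_vert(M, gid[in_idx[0]], gid[out_idx[0]], px.data(), py.data(), pz.data());
            const int b = edge_vert(M, gid[in_idx[0]], gid[out_idx[1]], px.data(), py.data(), pz.data());
            const int c = edge_vert(M, gid[in_idx[1]], gid[out_idx[1]], px.data(), py.data(), pz.data());
            const int d = edge_vert(M, gid[in_idx[1]], gid[out_idx[0]], px.data(), py.data(), pz.data());
            emit_tri(M, a, b, c, rx, ry, rz);
            emit_tri(M, a, c, d, rx, ry, rz);
          }
        }
      }

  const int nv = (int)M.vx.size(), nf = (int)M.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = M.vx[i]; V(i,1) = M.vy[i]; V(i,2) = M.vz[i]; }
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nf; ++i) { Fc(i,0) = M.f0[i] + 1; Fc(i,1) = M.f1[i] + 1; Fc(i,2) = M.f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// Orthographic z-buffer rasterizer. verts: n x 3 matrix of (u, v, depth)
// in pixel units; faces: m x 3 (1-based); shade: per-face grey in [0,1].
// Returns list(image = h x w grey matrix, depth = h x w depth buffer).
// [[Rcpp::export(name = ".zbuffer_render_cpp")]]
List zbuffer_render_cpp(NumericMatrix verts, IntegerMatrix faces,
                        NumericVector shade, int h, int w, double bg) {
  NumericMatrix img(h, w);
  NumericMatrix dep(h, w);
  std::fill(img.begin(), img.end(), bg);
  std::fill(dep.begin(), dep.end(), std::numeric_limits<double>::infinity());
  for (int f = 0; f < faces.nrow(); ++f) {
    const int a = faces(f,0) - 1, b = faces(f,1) - 1, c = faces(f,2) - 1;
    const double x0 = verts(a,0), y0 = verts(a,1), z0 = verts(a,2);
    const double x1 = verts(b,0), y1 = verts(b,1), z1 = verts(b,2);
    const double x2 = verts(c,0), y2 = verts(c,1), z2 = verts(c,2);
    const int umin = std::max(0, (int)std::floor(std::min({x0,x1,x2})));
    const int umax = std::min(w - 1, (int)std::ceil(std::max({x0,x1,x2})));
    const int vmin = std::max(0, (int)std::floor(std::min({y0,y1,y2})));
    const int vmax = std::min(h - 1, (int)std::ceil(std::max({y0,y1,y2})));
    const double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(det) < 1e-12) continue;
    for (int u = umin; u <= umax; ++u) {
      for (int v = vmin; v <= vmax; ++v) {
        const double pxu = u + 0.5, pyv = v + 0.5;
        const double l1 = ((pxu - x0) * (y2 - y0) - (x2 - x0) * (pyv - y0)) / det;
        const double l2 = ((x1 - x0) * (pyv - y0) - (pxu - x0) * (y1 - y0)) / det;
        const double l0 = 1.0 - l1 - l2;
        if (l0 < -1e-9 || l1 < -1e-9 || l2 < -1e-9) continue;
        const double z = l0 * z0 + l1 * z1 + l2 * z2;
        if (z < dep(v, u)) { dep(v, u) = z; img(v, u) = shade[f]; }
      }
    }
  }
  return List::create(_["image"] = img, _["depth"] = dep);
}
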