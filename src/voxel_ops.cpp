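#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <queue>

using namespace Rcpp;

// index helpers: volumes are R arrays in column-major order, 0-based here
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Resample a source volume onto an output grid.
// M maps output voxel index (0-based, homogeneous) to continuous source
// voxel index. mode 0 = trilinear, 1 = nearest neighbour.
// Out-of-field voxels are set to 0.
// [[Rcpp::export(name = ".cpp_resample")]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericMatrix M, IntegerVector odim, int mode) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double *s = src.begin();
  double *o = out.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      // start-of-row source coordinates, incremented along i
      double u = m01 * j + m02 * k + m03;
      double v = m11 * j + m12 * k + m13;
      double w = m21 * j + m22 * k + m23;
      R_xlen_t base = static_cast<R_xlen_t>(idx3(0, j, k, ox, oy));
      for (int i = 0; i < ox; ++i, u += m00, v += m10, w += m20) {
        double val = 0.0;
        if (mode == 1) {
          int ii = (int)std::lround(u), jj = (int)std::lround(v),
              kk = (int)std::lround(w);
          if (ii >= 0 && ii < sx && jj >= 0 && jj < sy && kk >= 0 && kk < sz)
            val = s[idx3(ii, jj, kk, sx, sy)];
        } else {
          int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
              k0 = (int)std::floor(w);
          double fu = u - i0, fv = v - j0, fw = w - k0;
          if (i0 >= 0 && i0 + 1 < sx && j0 >= 0 && j0 + 1 < sy &&
              k0 >= 0 && k0 + 1 < sz) {
            const double *p = s + idx3(i0, j0, k0, sx, sy);
            const R_xlen_t dx = 1, dy = sx, dz = static_cast<R_xlen_t>(sx) * sy;
            double c00 = p[0] * (1 - fu) + p[dx] * fu;
            double c10 = p[dy] * (1 - fu) + p[dy + dx] * fu;
            double c01 = p[dz] * (1 - fu) + p[dz + dx] * fu;
            double c11 = p[dz + dy] * (1 - fu) + p[dz + dy + dx] * fu;
            double c0 = c00 * (1 - fv) + c10 * fv;
            double c1 = c01 * (1 - fv) + c11 * fv;
            val = c0 * (1 - fw) + c1 * fw;
          } else if (u >= -0.5 && u <= sx - 0.5 && v >= -0.5 && v <= sy - 0.5 &&
                     w >= -0.5 && w <= sz - 0.5) {
            // border band: clamp-free partial interpolation using in-bounds corners
            double acc = 0.0, wsum = 0.0;
            for (int dk = 0; dk <= 1; ++dk)
              for (int dj = 0; dj <= 1; ++dj)
                for (int di = 0; di <= 1; ++di) {
                  int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                  double wt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) *
                              (dk ? fw : 1 - fw);
                  if (wt > 0 && ii >= 0 && ii < sx && jj >= 0 && jj < sy &&
                      kk >= 0 && kk < sz) {
                    acc += wt * s[idx3(ii, jj, kk, sx, sy)];
                    wsum += wt;
                  }
                }
            val = wsum > 0 ? acc / wsum : 0.0;
          }
        }
        o[base + i] = val;
      }
    }
  }
  return out;
}

// Per-voxel mean and sd of the cubic patch of radius pr (truncated at the
// volume border: statistics use only in-bounds patch voxels).
// [[Rcpp::export(name = ".cpp_patch_stats")]]
List cpp_patch_stats(NumericVector img, IntegerVector dim, int pr) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  // separable box sums along each axis
  NumericVector s1(n), s2(n), cnt(n);
  std::vector<double> ta(n), tb(n), tc(n);
  const double *p = img.begin();
  // axis x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double a = 0, b = 0, c = 0;
        int lo = std::max(0, i - pr), hi = std::min(nx - 1, i + pr);
        for (int q = lo; q <= hi; ++q) {
          double x = p[idx3(q, j, k, nx, ny)];
          a += x; b += x * x; c += 1;
        }
        R_xlen_t id = idx3(i, j, k, nx, ny);
        ta[id] = a; tb[id] = b; tc[id] = c;
      }
  std::vector<double> ua(n), ub(n), uc(n);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        double a = 0, b = 0, c = 0;
        int lo = std::max(0, j - pr), hi = std::min(ny - 1, j + pr);
        for (int q = lo; q <= hi; ++q) {
          R_xlen_t id = idx3(i, q, k, nx, ny);
          a += ta[id]; b += tb[id]; c += tc[id];
        }
        R_xlen_t id = idx3(i, j, k, nx, ny);
        ua[id] = a; ub[id] = b; uc[id] = c;
      }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) {
        double a = 0, b = 0, c = 0;
        int lo = std::max(0, k - pr), hi = std::min(nz - 1, k + pr);
        for (int q = lo; q <= hi; ++q) {
          R_xlen_t id = idx3(i, j, q, nx, ny);
          a += ua[id]; b += ub[id]; c += uc[id];
        }
        R_xlen_t id = idx3(i, j, k, nx, ny);
        s1[id] = a; s2[id] = b; cnt[id] = c;
      }
  NumericVector mu(n), sd(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    double m = s1[t] / cnt[t];
    double var = s2[t] / cnt[t] - m * m;
    mu[t] = m;
    sd[t] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// Patch-based label fusion. For each candidate voxel x: scan library entries
// and search offsets o (|o|_inf <= sr, x+o in bounds); preselect by the
// luminance-contrast similarity of the two patches' own statistics; for the
// survivors compute the squared patch distance over offsets valid in both
// patches; weight exp(-d / (min d + eps)); fused vote = weighted mean of the
// library centre labels. If no patch survives preselection the vote is the
// unweighted mean of all centre labels in the window.
// [[Rcpp::export(name = ".cpp_patch_fusion")]]
NumericVector cpp_patch_fusion(NumericVector target, List libImgs, List libLabs,
                               IntegerVector dim, LogicalVector cand,
                               int pr, int sr, double sigma, double eps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  const int L = libImgs.size();
  std::vector<const double*> imgs(L), labs(L);
  std::vector<NumericVector> keepI(L), keepL(L);
  for (int l = 0; l < L; ++l) {
    keepI[l] = as<NumericVector>(libImgs[l]);
    keepL[l] = as<NumericVector>(libLabs[l]);
    imgs[l] = keepI[l].begin();
    labs[l] = keepL[l].begin();
  }
  // patch statistics for target and library
  List ts = cpp_patch_stats(target, dim, pr);
  NumericVector tmu = ts["mean"], tsd = ts["sd"];
  std::vector<NumericVector> lmu(L), lsd(L);
  for (int l = 0; l < L; ++l) {
    List s = cpp_patch_stats(keepI[l], dim, pr);
    lmu[l] = as<NumericVector>(s["mean"]);
    lsd[l] = as<NumericVector>(s["sd"]);
  }
  const double *tp = target.begin();
  const double c1 = 1e-6, c2 = 1e-6;   // stabilizers for flat patches
  NumericVector vote(n);
  const int maxCand = L * (2 * sr + 1) * (2 * sr + 1) * (2 * sr + 1);
  std::vector<double> dist(maxCand), lab(maxCand);
  for (int zk = 0; zk < nz; ++zk)
    for (int yj = 0; yj < ny; ++yj)
      for (int xi = 0; xi < nx; ++xi) {
        R_xlen_t x = idx3(xi, yj, zk, nx, ny);
        if (!cand[x]) continue;
        double m1 = tmu[x], v1 = tsd[x];
        int nacc = 0;
        double dmin = R_PosInf;
        double fallbackSum = 0; int fallbackN = 0;
        int olo = std::max(-sr, -xi), ohi = std::min(sr, nx - 1 - xi);
        int plo = std::max(-sr, -yj), phi = std::min(sr, ny - 1 - yj);
        int qlo = std::max(-sr, -zk), qhi = std::min(sr, nz - 1 - zk);
        for (int oz = qlo; oz <= qhi; ++oz)
          for (int oy = plo; oy <= phi; ++oy)
            for (int ox = olo; ox <= ohi; ++ox) {
              int ci = xi + ox, cj = yj + oy, ck = zk + oz;
              R_xlen_t c = idx3(ci, cj, ck, nx, ny);
              for (int l = 0; l < L; ++l) {
                double lv = labs[l][c];
                fallbackSum += lv; fallbackN += 1;
                double m2 = lmu[l][c], v2 = lsd[l][c];
                double ss = ((2 * m1 * m2 + c1) / (m1 * m1 + m2 * m2 + c1)) *
                            ((2 * v1 * v2 + c2) / (v1 * v1 + v2 * v2 + c2));
                if (ss < sigma) continue;
                // squared distance over offsets in-bounds for both patches
                double d = 0;
                int alo = std::max({-pr, -xi, -ci});
                int ahi = std::min({pr, nx - 1 - xi, nx - 1 - ci});
                int blo = std::max({-pr, -yj, -cj});
                int bhi = std::min({pr, ny - 1 - yj, ny - 1 - cj});
                int glo = std::max({-pr, -zk, -ck});
                int ghi = std::min({pr, nz - 1 - zk, nz - 1 - ck});
                const double *li = imgs[l];
                for (int gz = glo; gz <= ghi; ++gz)
                  for (int gy = blo; gy <= bhi; ++gy) {
                    R_xlen_t xa = idx3(xi + alo, yj + gy, zk + gz, nx, ny);
                    R_xlen_t xb = idx3(ci + alo, cj + gy, ck + gz, nx, ny);
                    for (int gx = alo; gx <= ahi; ++gx, ++xa, ++xb) {
                      double df = tp[xa] - li[xb];
                      d += df * df;
                    }
                  }
                dist[nacc] = d;
                lab[nacc] = lv;
                nacc += 1;
                if (d < dmin) dmin = d;
              }
            }
        double v;
        if (nacc == 0) {
          v = fallbackN > 0 ? fallbackSum / fallbackN : 0.0;
        } else {
          double h2 = dmin + eps, wsum = 0, vsum = 0;
          for (int t = 0; t < nacc; ++t) {
            double w = std::exp(-dist[t] / h2);
            wsum += w;
            vsum += w * lab[t];
          }
          v = vsum / wsum;
        }
        vote[x] = v;
      }
  return vote;
}

// Binary dilation by a Euclidean ball of radius r voxels.
// [[Rcpp::export(name = ".cpp_dilate_ball")]]
LogicalVector cpp_dilate_ball(LogicalVector mask, IntegerVector dim, double r) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  LogicalVector out(n);
  if (r <= 0) { for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t]; return out; }
  int ir = (int)std::floor(r);
  std::vector<std::array<int,3>> offs;
  for (int dz = -ir; dz <= ir; ++dz)
    for (int dy = -ir; dy <= ir; ++dy)
      for (int dx = -ir; dx <= ir; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r * r)
          offs.push_back({dx, dy, dz});
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[idx3(i, j, k, nx, ny)]) continue;
        for (auto &o : offs) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            out[idx3(ii, jj, kk, nx, ny)] = true;
        }
      }
  return out;
}

// 6-connected component labelling of a binary mask (BFS).
// [[Rcpp::export(name = ".cpp_label6")]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n);
  int cur = 0;
  std::queue<R_xlen_t> q;
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t t = q.front(); q.pop();
      int i = t % nx, j = (t / nx) % ny, k = t / (static_cast<R_xlen_t>(nx) * ny);
      for (int d = 0; d < 6; ++d) {
        int ii = i + dxs[d], jj = j + dys[d], kk = k + dzs[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t u = idx3(ii, jj, kk, nx, ny);
        if (mask[u] && !lab[u]) { lab[u] = cur; q.push(u); }
      }
    }
  }
  lab.attr("ncomp") = cur;
  return lab;
}
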