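// Dense 3D kernels used by the warp layer, the convolutional network and the
// windowed-NCC loss. Arrays follow R's column-major layout with the x index
// fastest; tensors are (nx, ny, nz, channels); displacement fields are
// (nx, ny, nz, 3) in voxel units on the fixed grid.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// 3D convolution, cubic kernel, symmetric zero padding.
// x: (nx,ny,nz,ci); w: (k,k,k,ci,co); out: (ox,oy,oz,co) with
// o = floor((n + 2*pad - k)/stride) + 1.
// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int k = wd[0], co = wd[4];
  if (wd[3] != ci) stop("conv3d: channel mismatch");
  const int onx = (nx + 2 * pad - k) / stride + 1;
  const int ony = (ny + 2 * pad - k) / stride + 1;
  const int onz = (nz + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)onx * ony * onz * co);
  y.attr("dim") = IntegerVector::create(onx, ony, onz, co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  const R_xlen_t xch = (R_xlen_t)nx * ny * nz;
  const R_xlen_t ych = (R_xlen_t)onx * ony * onz;

  for (int c_o = 0; c_o < co; ++c_o) {
    for (int c_i = 0; c_i < ci; ++c_i) {
      const double* xc = xp + xch * c_i;
      double* yc = yp + ych * c_o;
      for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const double wv = wp[kx + k * (ky + k * (kz + k * (c_i + ci * c_o)))];
        if (wv == 0.0) continue;
        // valid output ranges so that input index stays in bounds
        // ix = ox*stride + kx - pad in [0, nx-1]
        int ox0 = 0, ox1 = onx - 1, oy0 = 0, oy1 = ony - 1, oz0 = 0, oz1 = onz - 1;
        while (ox0 <= ox1 && ox0 * stride + kx - pad < 0) ++ox0;
        while (ox1 >= ox0 && ox1 * stride + kx - pad > nx - 1) --ox1;
        while (oy0 <= oy1 && oy0 * stride + ky - pad < 0) ++oy0;
        while (oy1 >= oy0 && oy1 * stride + ky - pad > ny - 1) --oy1;
        while (oz0 <= oz1 && oz0 * stride + kz - pad < 0) ++oz0;
        while (oz1 >= oz0 && oz1 * stride + kz - pad > nz - 1) --oz1;
        for (int oz = oz0; oz <= oz1; ++oz) {
          const int iz = oz * stride + kz - pad;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int iy = oy * stride + ky - pad;
            const double* xrow = xc + idx3(0, iy, iz, nx, ny);
            double* yrow = yc + idx3(0, oy, oz, onx, ony);
            for (int ox = ox0; ox <= ox1; ++ox)
              yrow[ox] += wv * xrow[ox * stride + kx - pad];
          }
        }
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c_o = 0; c_o < co; ++c_o) {
      const double bv = b[c_o];
      double* yc = yp + ych * c_o;
      for (R_xlen_t t = 0; t < ych; ++t) yc[t] += bv;
    }
  }
  return y;
}

// Gradient of conv3d w.r.t. its input. gy: (ox,oy,oz,co); returns (nx,ny,nz,ci).
// [[Rcpp::export(name = ".conv3d_bwd_input_cpp")]]
NumericVector conv3d_bwd_input_cpp(NumericVector gy, NumericVector w,
                                   int stride, int pad,
                                   int nx, int ny, int nz) {
  IntegerVector gd = gy.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int onx = gd[0], ony = gd[1], onz = gd[2], co = gd[3];
  const int k = wd[0], ci = wd[3];
  if (wd[4] != co) stop("conv3d_bwd_input: channel mismatch");
  NumericVector gx((R_xlen_t)nx * ny * nz * ci);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  const double* gp = gy.begin();
  const double* wp = w.begin();
  double* xp = gx.begin();
  const R_xlen_t xch = (R_xlen_t)nx * ny * nz;
  const R_xlen_t ych = (R_xlen_t)onx * ony * onz;

  for (int c_o = 0; c_o < co; ++c_o) {
    for (int c_i = 0; c_i < ci; ++c_i) {
      double* xc = xp + xch * c_i;
      const double* gc = gp + ych * c_o;
      for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const double wv = wp[kx + k * (ky + k * (kz + k * (c_i + ci * c_o)))];
        if (wv == 0.0) continue;
        int ox0 = 0, ox1 = onx - 1, oy0 = 0, oy1 = ony - 1, oz0 = 0, oz1 = onz - 1;
        while (ox0 <= ox1 && ox0 * stride + kx - pad < 0) ++ox0;
        while (ox1 >= ox0 && ox1 * stride + kx - pad > nx - 1) --ox1;
        while (oy0 <= oy1 && oy0 * stride + ky - pad < 0) ++oy0;
        while (oy1 >= oy0 && oy1 * stride + ky - pad > ny - 1) --oy1;
        while (oz0 <= oz1 && oz0 * stride + kz - pad < 0) ++oz0;
        while (oz1 >= oz0 && oz1 * stride + kz - pad > nz - 1) --oz1;
        for (int oz = oz0; oz <= oz1; ++oz) {
          const int iz = oz * stride + kz - pad;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int iy = oy * stride + ky - pad;
            double* xrow = xc + idx3(0, iy, iz, nx, ny);
            const double* grow = gc + idx3(0, oy, oz, onx, ony);
            for (int ox = ox0; ox <= ox1; ++ox)
              xrow[ox * stride + kx - pad] += wv * grow[ox];
          }
        }
      }
    }
  }
  return gx;
}

// Gradient of conv3d w.r.t. the kernel. Returns (k,k,k,ci,co).
// [[Rcpp::export(name = ".conv3d_bwd_weight_cpp")]]
NumericVector conv3d_bwd_weight_cpp(NumericVector x, NumericVector gy,
                                    int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int onx = gd[0], ony = gd[1], onz = gd[2], co = gd[3];
  NumericVector gw((R_xlen_t)k * k * k * ci * co);
  gw.attr("dim") = IntegerVector::create(k, k, k, ci, co);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* wp = gw.begin();
  const R_xlen_t xch = (R_xlen_t)nx * ny * nz;
  const R_xlen_t ych = (R_xlen_t)onx * ony * onz;

  for (int c_o = 0; c_o < co; ++c_o) {
    for (int c_i = 0; c_i < ci; ++c_i) {
      const double* xc = xp + xch * c_i;
      const double* gc = gp + ych * c_o;
      for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        int ox0 = 0, ox1 = onx - 1, oy0 = 0, oy1 = ony - 1, oz0 = 0, oz1 = onz - 1;
        while (ox0 <= ox1 && ox0 * stride + kx - pad < 0) ++ox0;
        while (ox1 >= ox0 && ox1 * stride + kx - pad > nx - 1) --ox1;
        while (oy0 <= oy1 && oy0 * stride + ky - pad < 0) ++oy0;
        while (oy1 >= oy0 && oy1 * stride + ky - pad > ny - 1) --oy1;
        while (oz0 <= oz1 && oz0 * stride + kz - pad < 0) ++oz0;
        while (oz1 >= oz0 && oz1 * stride + kz - pad > nz - 1) --oz1;
        double acc = 0.0;
        for (int oz = oz0; oz <= oz1; ++oz) {
          const int iz = oz * stride + kz - pad;
          for (int oy = oy0; oy <= oy1; ++oy) {
            const int iy = oy * stride + ky - pad;
            const double* xrow = xc + idx3(0, iy, iz, nx, ny);
            const double* grow = gc + idx3(0, oy, oz, onx, ony);
            for (int ox = ox0; ox <= ox1; ++ox)
              acc += xrow[ox * stride + kx - pad] * grow[ox];
          }
        }
        wp[kx + k * (ky + k * (kz + k * (c_i + ci * c_o)))] = acc;
      }
    }
  }
  return gw;
}

// ---------------------------------------------------------------------------
// Trilinear warp: out(p) = vol(p + s(p)), sample coordinates clamped to the
// border. vol: (nx,ny,nz); field: (nx,ny,nz,3) voxel units.
// [[Rcpp::export(name = ".warp_trilinear_cpp")]]
NumericVector warp_trilinear_cpp(NumericVector vol, NumericVector field) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(Dimension(nx, ny, nz));
  const double* vp = vol.begin();
  const double* fp = field.begin();
  double* op = out.begin();
  R_xlen_t t = 0;
  for (int k = 0; k < nz; ++k)
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i, ++t) {
    double sx = i + fp[t];
    double sy = j + fp[t + nvox];
    double sz = k + fp[t + 2 * nvox];
    if (sx < 0) sx = 0; if (sx > nx - 1) sx = nx - 1;
    if (sy < 0) sy = 0; if (sy > ny - 1) sy = ny - 1;
    if (sz < 0) sz = 0; if (sz > nz - 1) sz = nz - 1;
    int x0 = (int)std::floor(sx); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    int y0 = (int)std::floor(sy); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    int z0 = (int)std::floor(sz); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
    const R_xlen_t b = idx3(x0, y0, z0, nx, ny);
    const R_xlen_t dy = nx, dz = (R_xlen_t)nx * ny;
    const double c000 = vp[b],            c100 = vp[b + 1];
    const double c010 = vp[b + dy],       c110 = vp[b + dy + 1];
    const double c001 = vp[b + dz],       c101 = vp[b + dz + 1];
    const double c011 = vp[b + dy + dz],  c111 = vp[b + dy + dz + 1];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    op[t] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Backward pass of the trilinear warp: given d(loss)/d(out), accumulate
// gradients w.r.t. the sampled volume and the displacement field. Where the
// sample coordinate is clamped at the border, its field gradient is zero.
// [[Rcpp::export(name = ".warp_trilinear_bwd_cpp")]]
List warp_trilinear_bwd_cpp(NumericVector vol, NumericVector field,
                            NumericVector gout) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gvol(Dimension(nx, ny, nz));
  NumericVector gfield(nvox * 3);
  gfield.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* vp = vol.begin();
  const double* fp = field.begin();
  const double* gp = gout.begin();
  double* gv = gvol.begin();
  double* gf = gfield.begin();
  R_xlen_t t = 0;
  for (int k = 0; k < nz; ++k)
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i, ++t) {
    const double g = gp[t];
    double sx = i + fp[t];
    double sy = j + fp[t + nvox];
    double sz = k + fp[t + 2 * nvox];
    const bool inx = (sx > 0.0 && sx < nx - 1);
    const bool iny = (sy > 0.0 && sy < ny - 1);
    const bool inz = (sz > 0.0 && sz < nz - 1);
    if (sx < 0) sx = 0; if (sx > nx - 1) sx = nx - 1;
    if (sy < 0) sy = 0; if (sy > ny - 1) sy = ny - 1;
    if (sz < 0) sz = 0; if (sz > nz - 1) sz = nz - 1;
    int x0 = (int)std::floor(sx); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    int y0 = (int)std::floor(sy); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    int z0 = (int)std::floor(sz); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
    const R_xlen_t b = idx3(x0, y0, z0, nx, ny);
    const R_xlen_t dy = nx, dz = (R_xlen_t)nx * ny;
    const double c000 = vp[b],            c100 = vp[b + 1];
    const double c010 = vp[b + dy],       c110 = vp[b + dy + 1];
    const double c001 = vp[b + dz],       c101 = vp[b + dz + 1];
    const double c011 = vp[b + dy + dz],  c111 = vp[b + dy + dz + 1];
    // volume gradient: scatter the 8 trilinear weights
    gv[b]           += g * (1 - fx) * (1 - fy) * (1 - fz);
    gv[b + 1]       += g * fx * (1 - fy) * (1 - fz);
    gv[b + dy]      += g * (1 - fx) * fy * (1 - fz);
    gv[b + dy + 1]  += g * fx * fy * (1 - fz);
    gv[b + dz]      += g * (1 - fx) * (1 - fy) * fz;
    gv[b + dz + 1]  += g * fx * (1 - fy) * fz;
    gv[b + dy + dz] += g * (1 - fx) * fy * fz;
    gv[b + dy + dz + 1] += g * fx * fy * fz;
    // field gradient: derivative of the interpolant w.r.t. sample coords
    const double dX = ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz)
                    + ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz;
    const double dY = ((c010 - c000) * (1 - fx) + (c110 - c100) * fx) * (1 - fz)
                    + ((c011 - c001) * (1 - fx) + (c111 - c101) * fx) * fz;
    const double dZ = ((c001 - c000) * (1 - fx) + (c101 - c100) * fx) * (1 - fy)
                    + ((c011 - c010) * (1 - fx) + (c111 - c110) * fx) * fy;
    if (inx) gf[t] = g * dX;
    if (iny) gf[t + nvox] = g * dY;
    if (inz) gf[t + 2 * nvox] = g * dZ;
  }
  return List::create(_["gvol"] = gvol, _["gfield"] = gfield);
}

// Nearest-neighbour warp for masks: out(p) = vol(round(p + s(p))), half-up
// rounding per axis, clamped.
// [[Rcpp::export(name = ".warp_nearest_cpp")]]
NumericVector warp_nearest_cpp(NumericVector vol, NumericVector field) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(Dimension(nx, ny, nz));
  const double* vp = vol.begin();
  const double* fp = field.begin();
  double* op = out.begin();
  R_xlen_t t = 0;
  for (int k = 0; k < nz; ++k)
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i, ++t) {
    int xi = (int)std::floor(i + fp[t] + 0.5);
    int yi = (int)std::floor(j + fp[t + nvox] + 0.5);
    int zi = (int)std::floor(k + fp[t + 2 * nvox] + 0.5);
    if (xi < 0) xi = 0; if (xi > nx - 1) xi = nx - 1;
    if (yi < 0) yi = 0; if (yi > ny - 1) yi = ny - 1;
    if (zi < 0) zi = 0; if (zi > nz - 1) zi = nz - 1;
    op[t] = vp[idx3(xi, yi, zi, nx, ny)];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sample a volume at arbitrary continuous 0-based voxel coordinates.
// method: 0 = trilinear, 1 = nearest (half-up). Coordinates clamp to border.
// [[Rcpp::export(name = ".sample_volume_cpp")]]
NumericVector sample_volume_cpp(NumericVector vol, NumericMatrix pts, int method) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int m = pts.nrow();
  NumericVector out(m);
  const double* vp = vol.begin();
  for (int r = 0; r < m; ++r) {
    double sx = pts(r, 0), sy = pts(r, 1), sz = pts(r, 2);
    if (sx < 0) sx = 0; if (sx > nx - 1) sx = nx - 1;
    if (sy < 0) sy = 0; if (sy > ny - 1) sy = ny - 1;
    if (sz < 0) sz = 0; if (sz > nz - 1) sz = nz - 1;
    if (method == 1) {
      int xi = (int)std::floor(sx + 0.5), yi = (int)std::floor(sy + 0.5),
          zi = (int)std::floor(sz + 0.5);
      if (xi > nx - 1) xi = nx - 1;
      if (yi > ny - 1) yi = ny - 1;
      if (zi > nz - 1) zi = nz - 1;
      out[r] = vp[idx3(xi, yi, zi, nx, ny)];
      continue;
    }
    int x0 = (int)std::floor(sx); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    int y0 = (int)std::floor(sy); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    int z0 = (int)std::floor(sz); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
    const R_xlen_t b = idx3(x0, y0, z0, nx, ny);
    const R_xlen_t dy = nx, dz = (R_xlen_t)nx * ny;
    const double c00 = vp[b] * (1 - fx) + vp[b + 1] * fx;
    const double c10 = vp[b + dy] * (1 - fx) + vp[b + dy + 1] * fx;
    const double c01 = vp[b + dz] * (1 - fx) + vp[b + dz + 1] * fx;
    const double c11 = vp[b + dy + dz] * (1 - fx) + vp[b + dy + dz + 1] * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[r] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable box sum with windows truncated at the borders: out(p) is the sum
// of vol over the cube of half-width `radius` centred at p, intersected with
// the grid. Three axis passes using per-line prefix sums.
// [[Rcpp::export(name = ".box_sum3_cpp")]]
NumericVector box_sum3_cpp(NumericVector vol, int radius) {
  IntegerVector vd = vol.attr("dim");
  const int n[3] = {vd[0], vd[1], vd[2]};
  NumericVector cur = clone(vol);
  const R_xlen_t strides[3] = {1, (R_xlen_t)n[0], (R_xlen_t)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = n[ax];
    const R_xlen_t st = strides[ax];
    NumericVector nxt(Dimension(n[0], n[1], n[2]));
    std::vector<double> pre(len + 1);
    // iterate over all lines along axis `ax`
    const int a1 = (ax == 0) ? 1 : 0;
    const int a2 = (ax == 2) ? 1 : 2;
    const R_xlen_t st1 = strides[a1], st2 = strides[a2];
    for (int j2 = 0; j2 < n[a2]; ++j2)
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      const R_xlen_t base = st1 * j1 + st2 * j2;
      pre[0] = 0.0;
      for (int i = 0; i < len; ++i) pre[i + 1] = pre[i] + cur[base + st * i];
      for (int i = 0; i < len; ++i) {
        const int lo = std::max(0, i - radius);
        const int hi = std::min(len - 1, i + radius);
        nxt[base + st * i] = pre[hi + 1] - pre[lo];
      }
    }
    cur = nxt;
  }
  return cur;
}
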