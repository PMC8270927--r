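#include <Rcpp.h>
using namespace Rcpp;

// Affine resampling of a 3D volume onto a target grid.
//
// For every target voxel centre (1-based index i,j,k) the world position is
//   x = torig + (i-1,j-1,k-1) * tvox
// which is mapped into the source frame by y = M x + off, converted to a
// continuous 0-based source index and interpolated (trilinear or nearest).
// Points outside the source grid get `fill`.
// [[Rcpp::export]]
NumericVector affine_resample_cpp(NumericVector src,
                                  IntegerVector sdim,
                                  NumericVector svox,
                                  NumericVector sorig,
                                  IntegerVector tdim,
                                  NumericVector tvox,
                                  NumericVector torig,
                                  NumericMatrix M,
                                  NumericVector off,
                                  int nearest,
                                  double fill) {
  const int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  const int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  NumericVector out(static_cast<R_xlen_t>(tnx) * tny * tnz);

  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);

  R_xlen_t idx = 0;
  for (int k = 0; k < tnz; ++k) {
    const double wz = torig[2] + k * tvox[2];
    for (int j = 0; j < tny; ++j) {
      const double wy = torig[1] + j * tvox[1];
      for (int i = 0; i < tnx; ++i, ++idx) {
        const double wx = torig[0] + i * tvox[0];
        const double sx = m00 * wx + m01 * wy + m02 * wz + off[0];
        const double sy = m10 * wx + m11 * wy + m12 * wz + off[1];
        const double sz = m20 * wx + m21 * wy + m22 * wz + off[2];
        // continuous 0-based source voxel index
        const double fx = (sx - sorig[0]) / svox[0];
        const double fy = (sy - sorig[1]) / svox[1];
        const double fz = (sz - sorig[2]) / svox[2];
        if (nearest) {
          const int ix = (int)std::lround(fx);
          const int iy = (int)std::lround(fy);
          const int iz = (int)std::lround(fz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= snx || iy >= sny || iz >= snz) {
            out[idx] = fill;
          } else {
            out[idx] = src[(R_xlen_t)iz * snx * sny + (R_xlen_t)iy * snx + ix];
          }
        } else {
          const int x0 = (int)std::floor(fx);
          const int y0 = (int)std::floor(fy);
          const int z0 = (int)std::floor(fz);
          if (x0 < 0 || y0 < 0 || z0 < 0 ||
              x0 + 1 > snx - 1 + 1e-9 || fx > snx - 1 ||
              fy > sny - 1 || fz > snz - 1) {
            // strict: require the full 8-neighbour cell inside unless exactly
            // on the upper face
            if (fx < 0 || fy < 0 || fz < 0 ||
                fx > snx - 1 || fy > sny - 1 || fz > snz - 1) {
              out[idx] = fill;
              continue;
            }
          }
          const int x1 = std::min(x0 + 1, snx - 1);
          const int y1 = std::min(y0 + 1, sny - 1);
          const int z1 = std::min(z0 + 1, snz - 1);
          const int xa = std::max(x0, 0), ya = std::max(y0, 0), za = std::max(z0, 0);
          const double dx = fx - x0, dy = fy - y0, dz = fz - z0;
          #define SRC(a,b,c) src[(R_xlen_t)(c) * snx * sny + (R_xlen_t)(b) * snx + (a)]
          const double c000 = SRC(xa, ya, za), c100 = SRC(x1, ya, za);
          const double c010 = SRC(xa, y1, za), c110 = SRC(x1, y1, za);
          const double c001 = SRC(xa, ya, z1), c101 = SRC(x1, ya, z1);
          const double c011 = SRC(xa, y1, z1), c111 = SRC(x1, y1, z1);
          #undef SRC
          const double c00 = c000 * (1 - dx) + c100 * dx;
          const double c10 = c010 * (1 - dx) + c110 * dx;
          const double c01 = c001 * (1 - dx) + c101 * dx;
          const double c11 = c011 * (1 - dx) + c111 * dx;
          const double c0 = c00 * (1 - dy) + c10 * dy;
          const double c1 = c01 * (1 - dy) + c11 * dy;
          out[idx] = c0 * (1 - dz) + c1 * dz;
        }
      }
    }
  }
  return out;
}

// Joint intensity histogram of two equal-length vectors over their finite
// pairs. Samples are spread linearly over the two adjacent bins per axis
// (first-order Parzen window), which makes downstream mutual information a
// smooth function of the registration parameters.
// [[Rcpp::export]]
NumericMatrix joint_histogram_cpp(NumericVector a, NumericVector b, int bins,
                                  double amin, double amax,
                                  double bmin, double bmax) {
  NumericMatrix H(bins, bins);
  const double aw = (amax > amin) ? (amax - amin) : 1.0;
  const double bw = (bmax > bmin) ? (bmax - bmin) : 1.0;
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double av = a[i], bv = b[i];
    if (!R_finite(av) || !R_finite(bv)) continue;
    double ua = (av - amin) / aw * (bins - 1);
    double ub = (bv - bmin) / bw * (bins - 1);
    if (ua < 0) ua = 0; if (ua > bins - 1) ua = bins - 1;
    if (ub < 0) ub = 0; if (ub > bins - 1) ub = bins - 1;
    const int ia = std::min((int)ua, bins - 2);
    const int ib = std::min((int)ub, bins - 2);
    const double wa = ua - ia, wb = ub - ib;
    H(ia,     ib)     += (1 - wa) * (1 - wb);
    H(ia + 1, ib)     += wa * (1 - wb);
    H(ia,     ib + 1) += (1 - wa) * wb;
    H(ia + 1, ib + 1) += wa * wb;
  }
  return H;
}
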