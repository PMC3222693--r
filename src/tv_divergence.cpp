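#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Discrete divergence of the normalized gradient, div(grad o / |grad o|),
// on an anisotropic voxel grid.  Corrected forward/central-difference
// scheme: along each axis a the numerator uses the forward difference
// D_a^+ o / h_a, normalized by the magnitude built from that forward
// difference and the central differences along the two remaining axes;
// the divergence then takes the backward difference of each normalized
// component.  Boundary values replicate the edge sample (zero-gradient
// closure); any residual ambiguity in the boundary relations is resolved
// by this replicate rule.
//
// Array layout matches R: dim = (nz, ny, nx), column-major, so the linear
// index of (z, y, x) is z + nz * (y + ny * x).  Spacings are passed in the
// caller's length units; eps regularizes the magnitude as
// sqrt(|grad|^2 + eps^2).

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// [[Rcpp::export(name = ".tv_divergence_cpp")]]
NumericVector tv_divergence_cpp(NumericVector o, IntegerVector dims,
                                double hx, double hy, double hz,
                                double eps) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double e2 = eps * eps;
  NumericVector px(o.size()), py(o.size()), pz(o.size()), out(o.size());
  const double *f = o.begin();

#define IDX(z, y, x) ((z) + (size_t)nz * ((y) + (size_t)ny * (x)))
#define AT(z, y, x) f[IDX(clampi(z, nz), clampi(y, ny), clampi(x, nx))]

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const double c = AT(z, y, x);
        const double fx = (AT(z, y, x + 1) - c) / hx;
        const double fy = (AT(z, y + 1, x) - c) / hy;
        const double fz = (AT(z + 1, y, x) - c) / hz;
        const double cx = (AT(z, y, x + 1) - AT(z, y, x - 1)) / (2.0 * hx);
        const double cy = (AT(z, y + 1, x) - AT(z, y - 1, x)) / (2.0 * hy);
        const double cz = (AT(z + 1, y, x) - AT(z - 1, y, x)) / (2.0 * hz);
        const size_t i = IDX(z, y, x);
        px[i] = fx / std::sqrt(fx * fx + cy * cy + cz * cz + e2);
        py[i] = fy / std::sqrt(cx * cx + fy * fy + cz * cz + e2);
        pz[i] = fz / std::sqrt(cx * cx + cy * cy + fz * fz + e2);
      }

  // Backward differences of the normalized components; at the low edge the
  // replicate closure makes the out-of-range component equal the edge one,
  // so the edge contribution of that axis is zero.
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const size_t i = IDX(z, y, x);
        double d = 0.0;
        if (x > 0) d += (px[i] - px[IDX(z, y, x - 1)]) / hx;
        if (y > 0) d += (py[i] - py[IDX(z, y - 1, x)]) / hy;
        if (z > 0) d += (pz[i] - pz[IDX(z - 1, y, x)]) / hz;
        out[i] = d;
      }

#undef AT
#undef IDX
  out.attr("dim") = dims;
  return out;
}
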