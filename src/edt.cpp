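#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Large finite sentinel instead of IEEE infinity: keeps the parabola
// intersection arithmetic free of NaN when whole scanlines are background.
static const double DT_BIG = 1e300;

// 1D squared-distance transform (lower envelope of parabolas) with samples at
// physical positions x = index * w.  Exact for arbitrary nonnegative input.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double w) {
    int k = 0;
    v[0] = 0;
    z[0] = -DT_BIG;
    z[1] = DT_BIG;
    for (int q = 1; q < n; ++q) {
        double xq = q * w;
        double s = 0.0;
        for (;;) {
            int p = v[k];
            double xp = p * w;
            s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
            if (k > 0 && s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = DT_BIG;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * w;
        while (z[k + 1] < xq) ++k;
        double dx = xq - v[k] * w;
        d[q] = dx * dx + f[v[k]];
    }
}

// Exact anisotropic squared Euclidean distance (mm^2) from every voxel to the
// nearest foreground voxel centre.  Separable: one 1D pass per axis.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    const R_xlen_t n = nxy * nz;
    NumericVector D(n);
    for (R_xlen_t i = 0; i < n; ++i) D[i] = fg[i] ? 0.0 : DT_BIG;

    const int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // x pass
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            const R_xlen_t base = (R_xlen_t)nx * j + nxy * k;
            for (int i = 0; i < nx; ++i) f[i] = D[base + i];
            dt1d(f, dd, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) D[base + i] = dd[i];
        }
    // y pass
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            const R_xlen_t base = (R_xlen_t)i + nxy * k;
            for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)nx * j];
            dt1d(f, dd, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)nx * j] = dd[j];
        }
    // z pass
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * j;
            for (int k = 0; k < nz; ++k) f[k] = D[base + nxy * k];
            dt1d(f, dd, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) D[base + nxy * k] = dd[k];
        }
    return D;
}
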