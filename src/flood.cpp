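#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Queue entry for the priority flood: higher distance pops first, ties broken
// first-in-first-out by a global insertion counter (bit-reproducible output).
struct QE {
    double d;
    long long c;
    R_xlen_t v;
};
struct QCmp {
    bool operator()(const QE &a, const QE &b) const {
        if (a.d != b.d) return a.d < b.d; // smaller distance = lower priority
        return a.c > b.c;                 // later insertion = lower priority
    }
};

// Marker-controlled watershed by priority flooding of the distance field.
// Labels: 0 = unlabeled, 1 = other, 2 = endocast.  Foreground voxels are never
// touched.  A voxel is claimed (labelled) the moment it is enqueued, by the
// voxel that enqueued it; the queue is seeded in lexicographic voxel order.
// fallback > 0 assigns that label to background voxels unreachable from any
// seed (disconnected components); fallback = 0 leaves them unlabeled.
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector d, IntegerVector seeds,
                            LogicalVector fg, IntegerVector dims,
                            int fallback) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    const R_xlen_t n = nxy * nz;
    IntegerVector lab = clone(seeds);
    std::priority_queue<QE, std::vector<QE>, QCmp> pq;
    long long ctr = 0;
    for (R_xlen_t v = 0; v < n; ++v)
        if (lab[v] != 0) pq.push(QE{d[v], ctr++, v});

    while (!pq.empty()) {
        const QE e = pq.top();
        pq.pop();
        const R_xlen_t v = e.v;
        const int k = (int)(v / nxy);
        const R_xlen_t r = v % nxy;
        const int j = (int)(r / nx);
        const int i = (int)(r % nx);
        const int lv = lab[v];
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                    if (dx == 0 && dy == 0 && dz == 0) continue;
                    const int ii = i + dx, jj = j + dy, kk = k + dz;
                    if (ii < 0 || jj < 0 || kk < 0 ||
                        ii >= nx || jj >= ny || kk >= nz) continue;
                    const R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx * jj + nxy * kk;
                    if (fg[w] || lab[w] != 0) continue;
                    lab[w] = lv;
                    pq.push(QE{d[w], ctr++, w});
                }
    }
    if (fallback > 0)
        for (R_xlen_t v = 0; v < n; ++v)
            if (!fg[v] && lab[v] == 0) lab[v] = fallback;
    return lab;
}

// 26-connected components of a boolean mask.  Component ids are assigned by
// discovery order during a lexicographic scan, so the labelling is
// deterministic: component 1 contains the lowest-index mask voxel.
// [[Rcpp::export]]
IntegerVector cc26_cpp(LogicalVector mask, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    const R_xlen_t n = nxy * nz;
    IntegerVector comp(n, 0);
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || comp[s] != 0) continue;
        ++next;
        comp[s] = next;
        stack.push_back(s);
        while (!stack.empty()) {
            const R_xlen_t v = stack.back();
            stack.pop_back();
            const int k = (int)(v / nxy);
            const R_xlen_t r = v % nxy;
            const int j = (int)(r / nx);
            const int i = (int)(r % nx);
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (dx == 0 && dy == 0 && dz == 0) continue;
                        const int ii = i + dx, jj = j + dy, kk = k + dz;
                        if (ii < 0 || jj < 0 || kk < 0 ||
                            ii >= nx || jj >= ny || kk >= nz) continue;
                        const R_xlen_t w =
                            (R_xlen_t)ii + (R_xlen_t)nx * jj + nxy * kk;
                        if (!mask[w] || comp[w] != 0) continue;
                        comp[w] = next;
                        stack.push_back(w);
                    }
        }
    }
    return comp;
}

// Border seeding: every background voxel on a face/edge/corner of the domain
// is marked, and so is every background voxel within physical distance
// s * d(b) of some border voxel b.  Literal per-border-voxel ball stamping;
// since s < 1 the stamped balls can never contain a foreground voxel.
// [[Rcpp::export]]
LogicalVector stamp_border_cpp(NumericVector d, LogicalVector fg,
                               IntegerVector dims, NumericVector spacing,
                               double s) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    const R_xlen_t n = nxy * nz;
    const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
    LogicalVector out(n, false);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                const bool border = (i == 0 || j == 0 || k == 0 ||
                                     i == nx - 1 || j == ny - 1 || k == nz - 1);
                if (!border) continue;
                const R_xlen_t b = (R_xlen_t)i + (R_xlen_t)nx * j + nxy * k;
                if (fg[b]) continue;
                out[b] = true;
                const double R = s * d[b];
                if (R <= 0.0) continue;
                const double R2 = R * R;
                const int ri = (int)std::floor(R / sx);
                const int rj = (int)std::floor(R / sy);
                const int rk = (int)std::floor(R / sz);
                const int k0 = std::max(0, k - rk), k1 = std::min(nz - 1, k + rk);
                const int j0 = std::max(0, j - rj), j1 = std::min(ny - 1, j + rj);
                const int i0 = std::max(0, i - ri), i1 = std::min(nx - 1, i + ri);
                for (int kk = k0; kk <= k1; ++kk) {
                    const double dz = (kk - k) * sz;
                    for (int jj = j0; jj <= j1; ++jj) {
                        const double dy = (jj - j) * sy;
                        const double dyz = dy * dy + dz * dz;
                        if (dyz > R2) continue;
                        const R_xlen_t rowbase = (R_xlen_t)nx * jj + nxy * kk;
                        for (int ii = i0; ii <= i1; ++ii) {
                            const R_xlen_t w = rowbase + ii;
                            if (out[w] || fg[w]) continue;
                            const double dxx = (ii - i) * sx;
                            if (dxx * dxx + dyz <= R2) out[w] = true;
                        }
                    }
                }
            }
    return out;
}
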