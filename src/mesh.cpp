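#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Squared distance from point p to triangle (a, b, c); Voronoi-region
// classification (closest feature may be a vertex, an edge or the interior).
static double pt_tri_sq(const double *p, const double *a, const double *b,
                        const double *c) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i];
        ac[i] = c[i] - a[i];
        ap[i] = p[i] - a[i];
    }
    auto dot = [](const double *u, const double *v) {
        return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
    };
    const double d1 = dot(ab, ap), d2 = dot(ac, ap);
    if (d1 <= 0.0 && d2 <= 0.0) return dot(ap, ap);

    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    const double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) return dot(bp, bp);

    const double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        const double v = d1 / (d1 - d3);
        double q[3] = {ap[0] - v * ab[0], ap[1] - v * ab[1], ap[2] - v * ab[2]};
        return dot(q, q);
    }

    double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
    const double d5 = dot(ab, cp), d6 = dot(ac, cp);
    if (d6 >= 0.0 && d5 <= d6) return dot(cp, cp);

    const double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        const double w = d2 / (d2 - d6);
        double q[3] = {ap[0] - w * ac[0], ap[1] - w * ac[1], ap[2] - w * ac[2]};
        return dot(q, q);
    }

    const double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        double q[3] = {bp[0] - w * (c[0] - b[0]), bp[1] - w * (c[1] - b[1]),
                       bp[2] - w * (c[2] - b[2])};
        return dot(q, q);
    }

    const double denom = 1.0 / (va + vb + vc);
    const double v = vb * denom, w = vc * denom;
    double q[3] = {ap[0] - v * ab[0] - w * ac[0], ap[1] - v * ab[1] - w * ac[1],
                   ap[2] - v * ab[2] - w * ac[2]};
    return dot(q, q);
}

// For each point, the distance (mm) to the closest point on the triangle
// surface (V, F).  Brute force over triangles with a bounding-sphere reject,
// seeded by the nearest mesh vertex as an initial upper bound.
// [[Rcpp::export]]
NumericVector mesh_point_dist_cpp(NumericMatrix pts, NumericMatrix V,
                                  IntegerMatrix F) {
    const int np = pts.nrow(), nv = V.nrow(), nf = F.nrow();
    std::vector<double> cen(3 * nf), rad(nf);
    std::vector<double> tv(9 * nf);
    for (int f = 0; f < nf; ++f) {
        for (int c = 0; c < 3; ++c) {
            const int vi = F(f, c) - 1;
            for (int d = 0; d < 3; ++d) tv[9 * f + 3 * c + d] = V(vi, d);
        }
        double r2 = 0.0;
        for (int d = 0; d < 3; ++d)
            cen[3 * f + d] = (tv[9 * f + d] + tv[9 * f + 3 + d] +
                              tv[9 * f + 6 + d]) / 3.0;
        for (int c = 0; c < 3; ++c) {
            double s = 0.0;
            for (int d = 0; d < 3; ++d) {
                const double dd = tv[9 * f + 3 * c + d] - cen[3 * f + d];
                s += dd * dd;
            }
            if (s > r2) r2 = s;
        }
        rad[f] = std::sqrt(r2);
    }
    NumericVector out(np);
    for (int pI = 0; pI < np; ++pI) {
        const double p[3] = {pts(pI, 0), pts(pI, 1), pts(pI, 2)};
        double best2 = R_PosInf;
        // initial bound: nearest mesh vertex
        for (int vI = 0; vI < nv; ++vI) {
            double s = 0.0;
            for (int d = 0; d < 3; ++d) {
                const double dd = p[d] - V(vI, d);
                s += dd * dd;
            }
            if (s < best2) best2 = s;
        }
        double best = std::sqrt(best2);
        for (int f = 0; f < nf; ++f) {
            double s = 0.0;
            for (int d = 0; d < 3; ++d) {
                const double dd = p[d] - cen[3 * f + d];
                s += dd * dd;
            }
            if (std::sqrt(s) - rad[f] >= best) continue;
            const double d2 = pt_tri_sq(p, &tv[9 * f], &tv[9 * f + 3],
                                        &tv[9 * f + 6]);
            if (d2 < best2) {
                best2 = d2;
                best = std::sqrt(best2);
            }
        }
        out[pI] = best;
    }
    return out;
}

// Number of connected components of the face-vertex incidence graph
// (components among vertices referenced by at least one face).
// [[Rcpp::export]]
int mesh_components_cpp(int nv, IntegerMatrix F) {
    std::vector<int> par(nv);
    for (int i = 0; i < nv; ++i) par[i] = i;
    std::vector<char> used(nv, 0);
    std::function<int(int)> find = [&](int x) {
        while (par[x] != x) {
            par[x] = par[par[x]];
            x = par[x];
        }
        return x;
    };
    const int nf = F.nrow();
    for (int f = 0; f < nf; ++f) {
        const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
        used[a] = used[b] = used[c] = 1;
        const int ra = find(a);
        const int rb = find(b);
        if (ra != rb) par[rb] = ra;
        const int rc = find(c);
        const int ra2 = find(a);
        if (ra2 != rc) par[rc] = ra2;
    }
    int ncomp = 0;
    for (int i = 0; i < nv; ++i)
        if (used[i] && find(i) == i) ++ncomp;
    return ncomp;
}
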