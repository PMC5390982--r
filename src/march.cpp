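#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Masked polygonization of the endocast region by marching tetrahedra on the
// Freudenthal 6-tet decomposition of each lattice cell.  The decomposition is
// face-consistent between neighbouring cells and has no ambiguous
// configurations, so the extracted isosurface is a closed two-manifold by
// construction whenever the air region (< t) is strictly interior to the
// domain.  Surface vertices are keyed by the global lattice edge they sit on,
// which makes watertightness combinatorial rather than numerical.
//
// The scalar field is the input value at ENDOCAST voxels (label 2) and
// max(value, fill) elsewhere, with fill one quantization step above the
// isovalue t: every non-endocast voxel reads as solid, so the only air region
// is the endocast itself.

static const int TETS[6][4] = {
    // paths 0 -> 7 of the Freudenthal subdivision (corner bits: 1=x,2=y,4=z)
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

struct Vec3 {
    double x, y, z;
};
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
    return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
    return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
                a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
    return a.x * b.x + a.y * b.y + a.z * b.z;
}

// [[Rcpp::export]]
List march_tets_cpp(NumericVector vals, IntegerVector labels,
                    IntegerVector dims, NumericVector spacing,
                    NumericVector origin, double t, double fill) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    const R_xlen_t ntot = nxy * nz;
    const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
    const double ox = origin[0], oy = origin[1], oz = origin[2];

    std::vector<double> F((size_t)ntot);
    for (R_xlen_t v = 0; v < ntot; ++v) {
        double x = vals[v];
        if (labels[v] != 2 && x < fill) x = fill;
        F[(size_t)v] = x;
    }

    std::unordered_map<uint64_t, int> vmap;
    std::vector<double> vx, vy, vz;
    std::vector<int> tri; // 0-based vertex ids, 3 per face

    auto centre = [&](R_xlen_t v, Vec3 &p) {
        const int k = (int)(v / nxy);
        const R_xlen_t r = v % nxy;
        const int j = (int)(r / nx);
        const int i = (int)(r % nx);
        p.x = ox + i * sx;
        p.y = oy + j * sy;
        p.z = oz + k * sz;
    };

    // Vertex on the lattice edge (a, b); interpolation computed from the
    // lower-index endpoint so shared edges yield bit-identical positions.
    auto edge_vertex = [&](R_xlen_t a, R_xlen_t b) -> int {
        R_xlen_t lo = a < b ? a : b, hi = a < b ? b : a;
        const uint64_t key = (uint64_t)lo * (uint64_t)ntot + (uint64_t)hi;
        auto it = vmap.find(key);
        if (it != vmap.end()) return it->second;
        const double flo = F[(size_t)lo], fhi = F[(size_t)hi];
        double fr = (t - flo) / (fhi - flo);
        if (fr < 1e-6) fr = 1e-6; // keep vertices off the corners so no
        if (fr > 1.0 - 1e-6) fr = 1.0 - 1e-6; // triangle degenerates
        Vec3 plo, phi;
        centre(lo, plo);
        centre(hi, phi);
        const int id = (int)vx.size();
        vx.push_back(plo.x + fr * (phi.x - plo.x));
        vy.push_back(plo.y + fr * (phi.y - plo.y));
        vz.push_back(plo.z + fr * (phi.z - plo.z));
        vmap.emplace(key, id);
        return id;
    };

    auto vpos = [&](int id) { return Vec3{vx[id], vy[id], vz[id]}; };

    // Append triangle (i1,i2,i3) oriented so its normal has positive dot
    // product with dir (from the air side towards the solid side).
    auto emit = [&](int i1, int i2, int i3, const Vec3 &dir) {
        const Vec3 p1 = vpos(i1), p2 = vpos(i2), p3 = vpos(i3);
        const Vec3 nrm = vcross(vsub(p2, p1), vsub(p3, p1));
        if (vdot(nrm, dir) >= 0) {
            tri.push_back(i1); tri.push_back(i2); tri.push_back(i3);
        } else {
            tri.push_back(i1); tri.push_back(i3); tri.push_back(i2);
        }
    };

    R_xlen_t ncells = 0;
    R_xlen_t corner[8];
    Vec3 cpos[8];
    for (int k = 0; k + 1 < nz; ++k)
        for (int j = 0; j + 1 < ny; ++j)
            for (int i = 0; i + 1 < nx; ++i) {
                bool any_endo = false;
                for (int c = 0; c < 8; ++c) {
                    const int ii = i + (c & 1);
                    const int jj = j + ((c >> 1) & 1);
                    const int kk = k + ((c >> 2) & 1);
                    const R_xlen_t v =
                        (R_xlen_t)ii + (R_xlen_t)nx * jj + nxy * kk;
                    corner[c] = v;
                    if (labels[v] == 2) any_endo = true;
                }
                if (!any_endo) continue;
                ++ncells;
                for (int c = 0; c < 8; ++c) centre(corner[c], cpos[c]);
                for (int tt = 0; tt < 6; ++tt) {
                    int solid[4], air[4];
                    int ns = 0, na = 0;
                    for (int c = 0; c < 4; ++c) {
                        const int cc = TETS[tt][c];
                        if (F[(size_t)corner[cc]] >= t) solid[ns++] = cc;
                        else air[na++] = cc;
                    }
                    if (ns == 0 || ns == 4) continue;
                    if (ns == 1) {
                        const int S = solid[0];
                        const int e1 = edge_vertex(corner[S], corner[air[0]]);
                        const int e2 = edge_vertex(corner[S], corner[air[1]]);
                        const int e3 = edge_vertex(corner[S], corner[air[2]]);
                        Vec3 ac{(cpos[air[0]].x + cpos[air[1]].x + cpos[air[2]].x) / 3.0,
                                (cpos[air[0]].y + cpos[air[1]].y + cpos[air[2]].y) / 3.0,
                                (cpos[air[0]].z + cpos[air[1]].z + cpos[air[2]].z) / 3.0};
                        emit(e1, e2, e3, vsub(cpos[S], ac));
                    } else if (ns == 3) {
                        const int A = air[0];
                        const int e1 = edge_vertex(corner[A], corner[solid[0]]);
                        const int e2 = edge_vertex(corner[A], corner[solid[1]]);
                        const int e3 = edge_vertex(corner[A], corner[solid[2]]);
                        Vec3 sc{(cpos[solid[0]].x + cpos[solid[1]].x + cpos[solid[2]].x) / 3.0,
                                (cpos[solid[0]].y + cpos[solid[1]].y + cpos[solid[2]].y) / 3.0,
                                (cpos[solid[0]].z + cpos[solid[1]].z + cpos[solid[2]].z) / 3.0};
                        emit(e1, e2, e3, vsub(sc, cpos[A]));
                    } else { // 2 solid, 2 air: one quad, two triangles
                        const int A1 = air[0], A2 = air[1];
                        const int S1 = solid[0], S2 = solid[1];
                        const int q1 = edge_vertex(corner[A1], corner[S1]);
                        const int q2 = edge_vertex(corner[A1], corner[S2]);
                        const int q3 = edge_vertex(corner[A2], corner[S2]);
                        const int q4 = edge_vertex(corner[A2], corner[S1]);
                        Vec3 dir{(cpos[S1].x + cpos[S2].x - cpos[A1].x - cpos[A2].x) / 2.0,
                                 (cpos[S1].y + cpos[S2].y - cpos[A1].y - cpos[A2].y) / 2.0,
                                 (cpos[S1].z + cpos[S2].z - cpos[A1].z - cpos[A2].z) / 2.0};
                        // shared flip decision from the quad normal keeps the
                        // two sub-triangles consistently oriented even when
                        // the quad is slightly non-planar
                        const Vec3 nq = vcross(vsub(vpos(q3), vpos(q1)),
                                               vsub(vpos(q4), vpos(q2)));
                        if (vdot(nq, dir) >= 0) {
                            tri.push_back(q1); tri.push_back(q2); tri.push_back(q3);
                            tri.push_back(q1); tri.push_back(q3); tri.push_back(q4);
                        } else {
                            tri.push_back(q1); tri.push_back(q3); tri.push_back(q2);
                            tri.push_back(q1); tri.push_back(q4); tri.push_back(q3);
                        }
                    }
                }
            }

    const int nv = (int)vx.size();
    const int nf = (int)(tri.size() / 3);
    NumericMatrix V(nv, 3);
    for (int a = 0; a < nv; ++a) {
        V(a, 0) = vx[a];
        V(a, 1) = vy[a];
        V(a, 2) = vz[a];
    }
    IntegerMatrix Fm(nf, 3);
    for (int a = 0; a < nf; ++a) {
        Fm(a, 0) = tri[3 * a] + 1;
        Fm(a, 1) = tri[3 * a + 1] + 1;
        Fm(a, 2) = tri[3 * a + 2] + 1;
    }
    return List::create(_["vertices"] = V, _["faces"] = Fm,
                        _["ncells"] = (double)ncells);
}
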