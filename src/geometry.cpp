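#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra on a regular grid (Kuhn 6-tet subdivision of each cube,
// all tets sharing the 0-7 main diagonal, which tiles consistently across the
// lattice).  Returns an iso-surface at `level` with vertices in continuous
// 0-based index coordinates; the R side maps to world mm via the affine.
// ---------------------------------------------------------------------------

struct MTState {
    std::unordered_map<uint64_t, int> edge_vertex;
    std::vector<double> vx, vy, vz;
    std::vector<int> tri;
};

static int edge_point(MTState &st, uint64_t ga, uint64_t gb,
                      const double *pa, const double *pb,
                      double fa, double fb, double level) {
    uint64_t lo = ga < gb ? ga : gb, hi = ga < gb ? gb : ga;
    uint64_t key = lo * 0x100000000ULL + hi;
    auto it = st.edge_vertex.find(key);
    if (it != st.edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    if (t < 1e-6) t = 1e-6;
    if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
    int id = (int)st.vx.size();
    st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    st.edge_vertex[key] = id;
    return id;
}

// emit triangle (i0,i1,i2), flipping if needed so the normal points away
// from the inside reference point (inside = field above level)
static void emit_tri(MTState &st, int i0, int i1, int i2, const double ref[3]) {
    double ax = st.vx[i0], ay = st.vy[i0], az = st.vz[i0];
    double bx = st.vx[i1] - ax, by = st.vy[i1] - ay, bz = st.vz[i1] - az;
    double cx = st.vx[i2] - ax, cy = st.vy[i2] - ay, cz = st.vz[i2] - az;
    double nx = by * cz - bz * cy;
    double ny = bz * cx - bx * cz;
    double nz = bx * cy - by * cx;
    double gx = (st.vx[i0] + st.vx[i1] + st.vx[i2]) / 3.0 - ref[0];
    double gy = (st.vy[i0] + st.vy[i1] + st.vy[i2]) / 3.0 - ref[1];
    double gz = (st.vz[i0] + st.vz[i1] + st.vz[i2]) / 3.0 - ref[2];
    if (nx * gx + ny * gy + nz * gz < 0.0) { int t = i1; i1 = i2; i2 = t; }
    st.tri.push_back(i0); st.tri.push_back(i1); st.tri.push_back(i2);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double level) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double *f = REAL(field);
    MTState st;

    // corner offsets, local id c = dx + 2*dy + 4*dz
    static const int off[8][3] = {
        {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
    static const int tets[6][4] = {
        {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};

    for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
    for (int x = 0; x < nx - 1; ++x) {
        double cf[8]; uint64_t gid[8]; double pos[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
            int cx = x + off[c][0], cy = y + off[c][1], cz = z + off[c][2];
            gid[c] = (uint64_t)cx + (uint64_t)nx * (cy + (uint64_t)ny * cz);
            cf[c] = f[gid[c]];
            pos[c][0] = cx; pos[c][1] = cy; pos[c][2] = cz;
            if (cf[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
            int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
            int ins[4], nin = 0, outs[4], nout = 0;
            for (int m = 0; m < 4; ++m) {
                if (cf[vi[m]] > level) ins[nin++] = vi[m];
                else outs[nout++] = vi[m];
            }
            if (nin == 0 || nin == 4) continue;
            double ref[3] = {0, 0, 0};
            for (int m = 0; m < nin; ++m)
                for (int d = 0; d < 3; ++d) ref[d] += pos[ins[m]][d] / nin;
            if (nin == 1 || nin == 3) {
                int a = (nin == 1) ? ins[0] : outs[0];
                int o[3]; int k = 0;
                for (int m = 0; m < 4; ++m) if (vi[m] != a) o[k++] = vi[m];
                int e0 = edge_point(st, gid[a], gid[o[0]], pos[a], pos[o[0]], cf[a], cf[o[0]], level);
                int e1 = edge_point(st, gid[a], gid[o[1]], pos[a], pos[o[1]], cf[a], cf[o[1]], level);
                int e2 = edge_point(st, gid[a], gid[o[2]], pos[a], pos[o[2]], cf[a], cf[o[2]], level);
                emit_tri(st, e0, e1, e2, ref);
            } else { // 2 in, 2 out
                int p = ins[0], q = ins[1], r = outs[0], s = outs[1];
                int epr = edge_point(st, gid[p], gid[r], pos[p], pos[r], cf[p], cf[r], level);
                int eps = edge_point(st, gid[p], gid[s], pos[p], pos[s], cf[p], cf[s], level);
                int eqr = edge_point(st, gid[q], gid[r], pos[q], pos[r], cf[q], cf[r], level);
                int eqs = edge_point(st, gid[q], gid[s], pos[q], pos[s], cf[q], cf[s], level);
                emit_tri(st, epr, eps, eqs, ref);
                emit_tri(st, epr, eqs, eqr, ref);
            }
        }
    }

    int nv = (int)st.vx.size(), nt = (int)st.tri.size() / 3;
    NumericMatrix V(nv, 3);
    for (int i = 0; i < nv; ++i) {
        V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
    }
    IntegerMatrix Fm(nt, 3);
    for (int i = 0; i < nt; ++i) {
        Fm(i, 0) = st.tri[3 * i];
        Fm(i, 1) = st.tri[3 * i + 1];
        Fm(i, 2) = st.tri[3 * i + 2];
    }
    return List::create(_["vertices"] = V, _["triangles"] = Fm);
}

// ---------------------------------------------------------------------------
// Point-to-triangle distance (Ericson, Real-Time Collision Detection) and
// brute-force nearest distance to a triangle soup.
// ---------------------------------------------------------------------------

static double dist2_point_tri(const double p[3], const double a[3],
                              const double b[3], const double c[3]) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
    }
    double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
    double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
    auto sq = [](const double v[3]) { return v[0]*v[0]+v[1]*v[1]+v[2]*v[2]; };
    if (d1 <= 0.0 && d2 <= 0.0) return sq(ap);
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) return sq(bp);
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double t = d1 / (d1 - d3);
        double e[3] = {ap[0]-t*ab[0], ap[1]-t*ab[1], ap[2]-t*ab[2]};
        return sq(e);
    }
    double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) return sq(cp);
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double t = d2 / (d2 - d6);
        double e[3] = {ap[0]-t*ac[0], ap[1]-t*ac[1], ap[2]-t*ac[2]};
        return sq(e);
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        double e[3] = {bp[0]-t*(c[0]-b[0]), bp[1]-t*(c[1]-b[1]), bp[2]-t*(c[2]-b[2])};
        return sq(e);
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    double e[3] = {ap[0]-v*ab[0]-w*ac[0], ap[1]-v*ab[1]-w*ac[1], ap[2]-v*ab[2]-w*ac[2]};
    return sq(e);
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix V, IntegerMatrix Fm,
                                  NumericMatrix P) {
    int np = P.nrow(), nt = Fm.nrow();
    NumericVector out(np);
    std::vector<double> tx(nt * 9), bb(nt * 6);
    for (int t = 0; t < nt; ++t) {
        for (int c = 0; c < 3; ++c) {
            int vi = Fm(t, c);
            for (int d = 0; d < 3; ++d) tx[9 * t + 3 * c + d] = V(vi, d);
        }
        for (int d = 0; d < 3; ++d) {
            double lo = tx[9*t+d], hi = lo;
            for (int c = 1; c < 3; ++c) {
                double v = tx[9*t+3*c+d];
                if (v < lo) lo = v;
                if (v > hi) hi = v;
            }
            bb[6*t+d] = lo; bb[6*t+3+d] = hi;
        }
    }
    for (int i = 0; i < np; ++i) {
        double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
        double best = R_PosInf;
        for (int t = 0; t < nt; ++t) {
            // cheap lower bound from the triangle's AABB
            double lb = 0.0;
            for (int d = 0; d < 3; ++d) {
                double v = p[d];
                if (v < bb[6*t+d]) { double e = bb[6*t+d]-v; lb += e*e; }
                else if (v > bb[6*t+3+d]) { double e = v-bb[6*t+3+d]; lb += e*e; }
            }
            if (lb >= best) continue;
            double d2 = dist2_point_tri(p, &tx[9*t], &tx[9*t+3], &tx[9*t+6]);
            if (d2 < best) best = d2;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}

// ---------------------------------------------------------------------------
// Even-odd inside test: ray cast along +x.  Degenerate hits (barycentric
// coordinate too close to an edge) trigger a deterministic perturbation of
// the ray origin in y/z and a retry.
// ---------------------------------------------------------------------------

static int ray_parity_try(const std::vector<double> &tx, int nt,
                          double px, double py, double pz, bool &degenerate) {
    int crossings = 0;
    const double tol = 1e-10;
    for (int t = 0; t < nt; ++t) {
        const double *a = &tx[9 * t], *b = &tx[9 * t + 3], *c = &tx[9 * t + 6];
        // solve a_yz + u*(b-a)_yz + v*(c-a)_yz = p_yz
        double e1y = b[1] - a[1], e1z = b[2] - a[2];
        double e2y = c[1] - a[1], e2z = c[2] - a[2];
        double det = e1y * e2z - e1z * e2y;
        if (std::fabs(det) < 1e-14) continue; // triangle parallel to ray
        double ry = py - a[1], rz = pz - a[2];
        double u = (ry * e2z - rz * e2y) / det;
        double v = (e1y * rz - e1z * ry) / det;
        double w = 1.0 - u - v;
        if (u > tol && v > tol && w > tol) {
            double hx = w * a[0] + u * b[0] + v * c[0];
            if (hx > px) crossings++;
            else if (std::fabs(hx - px) < 1e-12) { degenerate = true; return 0; }
        } else if (u > -tol && v > -tol && w > -tol) {
            degenerate = true; // on or too near an edge in the yz projection
            return 0;
        }
    }
    return crossings;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix Fm,
                                 NumericMatrix P) {
    int np = P.nrow(), nt = Fm.nrow();
    std::vector<double> tx(nt * 9);
    double scale = 0.0;
    for (int t = 0; t < nt; ++t)
        for (int c = 0; c < 3; ++c) {
            int vi = Fm(t, c);
            for (int d = 0; d < 3; ++d) {
                double v = V(vi, d);
                tx[9 * t + 3 * c + d] = v;
                if (std::fabs(v) > scale) scale = std::fabs(v);
            }
        }
    if (scale == 0.0) scale = 1.0;
    LogicalVector out(np);
    for (int i = 0; i < np; ++i) {
        double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
        int parity = 0;
        for (int attempt = 0; attempt < 32; ++attempt) {
            bool degen = false;
            double dy = attempt * 1.31e-7 * scale;
            double dz = attempt * 2.71e-7 * scale;
            int cr = ray_parity_try(tx, nt, px, py + dy, pz + dz, degen);
            if (!degen) { parity = cr & 1; break; }
            if (attempt == 31) stop("inside test failed: persistent degenerate ray hits");
        }
        out[i] = parity == 1;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Grid rasterization: one +x ray per (y, z) row of voxel centers.  Vertices
// are given in continuous voxel-index coordinates (the R side applies the
// inverse affine; even-odd parity is affine invariant).  Degenerate hits
// trigger a deterministic per-row perturbation retry.
// ---------------------------------------------------------------------------

static bool row_crossings(const std::vector<double> &tx, int nt,
                          double py, double pz, std::vector<double> &xs) {
    xs.clear();
    const double tol = 1e-10;
    for (int t = 0; t < nt; ++t) {
        const double *a = &tx[9 * t], *b = &tx[9 * t + 3], *c = &tx[9 * t + 6];
        double loy = std::min({a[1], b[1], c[1]}), hiy = std::max({a[1], b[1], c[1]});
        double loz = std::min({a[2], b[2], c[2]}), hiz = std::max({a[2], b[2], c[2]});
        if (py < loy - 1e-6 || py > hiy + 1e-6 || pz < loz - 1e-6 || pz > hiz + 1e-6)
            continue;
        double e1y = b[1] - a[1], e1z = b[2] - a[2];
        double e2y = c[1] - a[1], e2z = c[2] - a[2];
        double det = e1y * e2z - e1z * e2y;
        if (std::fabs(det) < 1e-14) continue;
        double ry = py - a[1], rz = pz - a[2];
        double u = (ry * e2z - rz * e2y) / det;
        double v = (e1y * rz - e1z * ry) / det;
        double w = 1.0 - u - v;
        if (u > tol && v > tol && w > tol) {
            xs.push_back(w * a[0] + u * b[0] + v * c[0]);
        } else if (u > -tol && v > -tol && w > -tol) {
            return false; // degenerate: ray grazes an edge in projection
        }
    }
    std::sort(xs.begin(), xs.end());
    return true;
}

// [[Rcpp::export]]
LogicalVector cpp_rasterize_grid(NumericMatrix V, IntegerMatrix Fm,
                                 IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2], nt = Fm.nrow();
    std::vector<double> tx(nt * 9);
    for (int t = 0; t < nt; ++t)
        for (int c = 0; c < 3; ++c) {
            int vi = Fm(t, c);
            for (int d = 0; d < 3; ++d) tx[9 * t + 3 * c + d] = V(vi, d);
        }
    LogicalVector out((R_xlen_t)nx * ny * nz);
    std::vector<double> xs;
    // bounding box in index space to skip empty rows
    double loy = R_PosInf, hiy = R_NegInf, loz = R_PosInf, hiz = R_NegInf;
    for (int i = 0; i < V.nrow(); ++i) {
        loy = std::min(loy, V(i, 1)); hiy = std::max(hiy, V(i, 1));
        loz = std::min(loz, V(i, 2)); hiz = std::max(hiz, V(i, 2));
    }
    for (int k = 0; k < nz; ++k) {
        if (k < loz - 1 || k > hiz + 1) continue;
        for (int j = 0; j < ny; ++j) {
            if (j < loy - 1 || j > hiy + 1) continue;
            bool ok = false;
            for (int attempt = 0; attempt < 32 && !ok; ++attempt) {
                double py = j + (attempt + 1) * 1.31e-7;
                double pz = k + (attempt + 1) * 2.71e-7;
                ok = row_crossings(tx, nt, py, pz, xs);
            }
            if (!ok) stop("rasterization failed: persistent degenerate ray hits");
            // centers at integer i are inside iff an odd number of
            // crossings lie to their right
            size_t m = xs.size();
            for (size_t s = 0; s + 1 < m; s += 2) {
                int i0 = (int)std::ceil(xs[s]);
                int i1 = (int)std::floor(xs[s + 1]);
                if (std::floor(xs[s]) == xs[s]) i0 = (int)xs[s] + 1; // strict
                for (int i = std::max(i0, 0); i <= std::min(i1, nx - 1); ++i) {
                    if ((double)i == xs[s + 1]) continue; // strictly inside
                    out[(R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = true;
                }
            }
        }
    }
    return out;
}

// ---------------------------------------------------------------------------
// Mesh-based TFCE: enhancement(v) = sum_h area(component of v at h)^E * h^H * dh
// over thresholds h = dh, 2dh, ... up to max(stat).  Components are computed
// per threshold with a union-find over mesh edges; component "area" is the
// sum of per-vertex one-ring areas (mm^2).  Only the positive part of `stat`
// is enhanced; the caller handles the negative tail on -stat.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
}

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, IntegerMatrix edges,
                       NumericVector areas, double H, double E, double dh) {
    int nv = stat.size(), ne = edges.nrow();
    NumericVector out(nv);
    double mx = 0.0;
    for (int i = 0; i < nv; ++i) if (stat[i] > mx) mx = stat[i];
    if (mx <= 0.0 || dh <= 0.0) return out;
    std::vector<int> parent(nv);
    std::vector<double> carea(nv);
    for (double h = dh; h <= mx + 1e-12; h += dh) {
        for (int i = 0; i < nv; ++i) { parent[i] = i; carea[i] = 0.0; }
        for (int e = 0; e < ne; ++e) {
            int a = edges(e, 0), b = edges(e, 1);
            if (stat[a] >= h && stat[b] >= h) {
                int ra = uf_find(parent, a), rb = uf_find(parent, b);
                if (ra != rb) parent[ra] = rb;
            }
        }
        for (int i = 0; i < nv; ++i)
            if (stat[i] >= h) carea[uf_find(parent, i)] += areas[i];
        double hh = std::pow(h, H) * dh;
        for (int i = 0; i < nv; ++i)
            if (stat[i] >= h)
                out[i] += std::pow(carea[uf_find(parent, i)], E) * hh;
    }
    return out;
}
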