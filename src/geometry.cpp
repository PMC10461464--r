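#include <Rcpp.h>
#include <vector>
#include <array>
#include <set>
#include <utility>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Point-to-triangle distance, region-based closed form (Eberly).
// Returns the squared Euclidean distance from P to the closed triangle ABC.
// ---------------------------------------------------------------------------
static double pt_tri_dist_sq(const double* P, const double* A,
                             const double* B, const double* C) {
    const double E0[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    const double E1[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
    const double D0[3] = {A[0] - P[0], A[1] - P[1], A[2] - P[2]};
    const double a = E0[0]*E0[0] + E0[1]*E0[1] + E0[2]*E0[2];
    const double b = E0[0]*E1[0] + E0[1]*E1[1] + E0[2]*E1[2];
    const double c = E1[0]*E1[0] + E1[1]*E1[1] + E1[2]*E1[2];
    const double d = E0[0]*D0[0] + E0[1]*D0[1] + E0[2]*D0[2];
    const double e = E1[0]*D0[0] + E1[1]*D0[1] + E1[2]*D0[2];
    const double f = D0[0]*D0[0] + D0[1]*D0[1] + D0[2]*D0[2];
    const double det = a*c - b*b;
    double s = b*e - c*d;
    double t = b*d - a*e;

    if (s + t <= det) {
        if (s < 0.0) {
            if (t < 0.0) {                       // region 4
                if (d < 0.0) {
                    t = 0.0;
                    s = (-d >= a) ? 1.0 : -d/a;
                } else {
                    s = 0.0;
                    t = (e >= 0.0) ? 0.0 : ((-e >= c) ? 1.0 : -e/c);
                }
            } else {                             // region 3
                s = 0.0;
                t = (e >= 0.0) ? 0.0 : ((-e >= c) ? 1.0 : -e/c);
            }
        } else if (t < 0.0) {                    // region 5
            t = 0.0;
            s = (d >= 0.0) ? 0.0 : ((-d >= a) ? 1.0 : -d/a);
        } else {                                 // region 0 (interior)
            const double inv = 1.0 / det;
            s *= inv;
            t *= inv;
        }
    } else {
        if (s < 0.0) {                           // region 2
            const double tmp0 = b + d, tmp1 = c + e;
            if (tmp1 > tmp0) {
                const double numer = tmp1 - tmp0;
                const double denom = a - 2.0*b + c;
                s = (numer >= denom) ? 1.0 : numer/denom;
                t = 1.0 - s;
            } else {
                s = 0.0;
                t = (tmp1 <= 0.0) ? 1.0 : ((e >= 0.0) ? 0.0 : -e/c);
            }
        } else if (t < 0.0) {                    // region 6
            const double tmp0 = b + e, tmp1 = a + d;
            if (tmp1 > tmp0) {
                const double numer = tmp1 - tmp0;
                const double denom = a - 2.0*b + c;
                t = (numer >= denom) ? 1.0 : numer/denom;
                s = 1.0 - t;
            } else {
                t = 0.0;
                s = (tmp1 <= 0.0) ? 1.0 : ((d >= 0.0) ? 0.0 : -d/a);
            }
        } else {                                 // region 1
            const double numer = (c + e) - (b + d);
            if (numer <= 0.0) {
                s = 0.0;
            } else {
                const double denom = a - 2.0*b + c;
                s = (numer >= denom) ? 1.0 : numer/denom;
            }
            t = 1.0 - s;
        }
    }
    const double d2 = a*s*s + 2.0*b*s*t + c*t*t + 2.0*d*s + 2.0*e*t + f;
    return d2 > 0.0 ? d2 : 0.0;
}

// [[Rcpp::export(name = ".pt_tri_dist_cpp")]]
double pt_tri_dist_cpp(NumericVector p, NumericVector a,
                       NumericVector b, NumericVector c) {
    return std::sqrt(pt_tri_dist_sq(REAL(p), REAL(a), REAL(b), REAL(c)));
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull.
// Faces are oriented outwards; a point is added over its strictly visible
// faces only, so points coplanar with a face never create degenerate faces.
// ---------------------------------------------------------------------------
struct HFace {
    int a, b, c;
    double n[3];   // unit outward normal
    double off;    // plane offset: dot(n, x) == off on the face plane
    bool alive;
};

static void face_plane(const std::vector<double>& X, HFace& f) {
    const double* A = &X[3*f.a];
    const double* B = &X[3*f.b];
    const double* C = &X[3*f.c];
    const double u[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
    const double v[3] = {C[0]-A[0], C[1]-A[1], C[2]-A[2]};
    f.n[0] = u[1]*v[2] - u[2]*v[1];
    f.n[1] = u[2]*v[0] - u[0]*v[2];
    f.n[2] = u[0]*v[1] - u[1]*v[0];
    const double nn = std::sqrt(f.n[0]*f.n[0] + f.n[1]*f.n[1] + f.n[2]*f.n[2]);
    if (nn > 0.0) { f.n[0] /= nn; f.n[1] /= nn; f.n[2] /= nn; }
    f.off = f.n[0]*A[0] + f.n[1]*A[1] + f.n[2]*A[2];
}

// [[Rcpp::export(name = ".convex_hull_cpp")]]
List convex_hull_cpp(NumericMatrix pts) {
    const int n = pts.nrow();
    if (n < 4) stop("insufficient points: a 3D convex hull needs at least 4 points");

    std::vector<double> X(3 * (size_t)n);
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i) {
        for (int k = 0; k < 3; ++k) {
            const double val = pts(i, k);
            if (!R_finite(val)) stop("all coordinates must be finite");
            X[3*i + k] = val;
            if (val < lo[k]) lo[k] = val;
            if (val > hi[k]) hi[k] = val;
        }
    }
    const double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) +
                                  (hi[1]-lo[1])*(hi[1]-lo[1]) +
                                  (hi[2]-lo[2])*(hi[2]-lo[2]));
    if (diag <= 0.0) stop("degenerate geometry: all points coincide");
    const double eps = 1e-9 * diag;

    // Initial simplex: the most separated axis-extreme pair, the point
    // farthest from their line, then the point farthest from that plane.
    int i0 = 0, i1 = 0;
    {
        int kbest = 0;
        double ebest = -1.0;
        for (int k = 0; k < 3; ++k)
            if (hi[k] - lo[k] > ebest) { ebest = hi[k] - lo[k]; kbest = k; }
        double best_lo = R_PosInf, best_hi = R_NegInf;
        for (int i = 0; i < n; ++i) {
            if (X[3*i + kbest] < best_lo) { best_lo = X[3*i + kbest]; i0 = i; }
            if (X[3*i + kbest] > best_hi) { best_hi = X[3*i + kbest]; i1 = i; }
        }
    }
    const double* P0 = &X[3*i0];
    const double* P1 = &X[3*i1];
    const double L[3] = {P1[0]-P0[0], P1[1]-P0[1], P1[2]-P0[2]};
    const double Lnorm = std::sqrt(L[0]*L[0] + L[1]*L[1] + L[2]*L[2]);
    if (Lnorm <= eps) stop("degenerate geometry: all points coincide");

    int i2 = -1;
    double best = eps;
    for (int i = 0; i < n; ++i) {
        const double w[3] = {X[3*i]-P0[0], X[3*i+1]-P0[1], X[3*i+2]-P0[2]};
        const double cx = L[1]*w[2] - L[2]*w[1];
        const double cy = L[2]*w[0] - L[0]*w[2];
        const double cz = L[0]*w[1] - L[1]*w[0];
        const double d = std::sqrt(cx*cx + cy*cy + cz*cz) / Lnorm;
        if (d > best) { best = d; i2 = i; }
    }
    if (i2 < 0) stop("degenerate geometry: points are collinear");

    HFace base{ i0, i1, i2, {0,0,0}, 0.0, true };
    face_plane(X, base);
    int i3 = -1;
    best = eps;
    for (int i = 0; i < n; ++i) {
        const double d = std::fabs(base.n[0]*X[3*i] + base.n[1]*X[3*i+1] +
                                   base.n[2]*X[3*i+2] - base.off);
        if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) stop("degenerate geometry: points are coplanar");

    const double O[3] = {
        (X[3*i0]   + X[3*i1]   + X[3*i2]   + X[3*i3])   / 4.0,
        (X[3*i0+1] + X[3*i1+1] + X[3*i2+1] + X[3*i3+1]) / 4.0,
        (X[3*i0+2] + X[3*i1+2] + X[3*i2+2] + X[3*i3+2]) / 4.0
    };

    std::vector<HFace> faces;
    faces.reserve((size_t)(2*n));
    auto add_face = [&](int a, int b, int c) {
        HFace f{ a, b, c, {0,0,0}, 0.0, true };
        face_plane(X, f);
        // orient outward w.r.t. the interior reference point
        if (f.n[0]*O[0] + f.n[1]*O[1] + f.n[2]*O[2] - f.off > 0.0) {
            std::swap(f.b, f.c);
            face_plane(X, f);
        }
        faces.push_back(f);
    };
    add_face(i0, i1, i2);
    add_face(i0, i1, i3);
    add_face(i0, i2, i3);
    add_face(i1, i2, i3);

    std::vector<bool> done((size_t)n, false);
    done[i0] = done[i1] = done[i2] = done[i3] = true;

    for (int p = 0; p < n; ++p) {
        if (done[p]) continue;
        const double* P = &X[3*p];
        std::vector<int> vis;
        for (int fi = 0; fi < (int)faces.size(); ++fi) {
            if (!faces[fi].alive) continue;
            const HFace& f = faces[fi];
            if (f.n[0]*P[0] + f.n[1]*P[1] + f.n[2]*P[2] - f.off > eps)
                vis.push_back(fi);
        }
        if (vis.empty()) continue;  // inside (or on) the current hull

        std::set<std::pair<int,int>> edges;
        for (int fi : vis) {
            const HFace& f = faces[fi];
            edges.insert({f.a, f.b});
            edges.insert({f.b, f.c});
            edges.insert({f.c, f.a});
        }
        std::vector<std::pair<int,int>> horizon;
        for (const auto& e : edges)
            if (!edges.count({e.second, e.first}))
                horizon.push_back(e);
        for (int fi : vis) faces[fi].alive = false;
        for (const auto& h : horizon) add_face(h.first, h.second, p);
    }

    int nf = 0;
    for (const HFace& f : faces) if (f.alive) ++nf;
    IntegerMatrix fmat(nf, 3);
    std::set<int> vset;
    int row = 0;
    for (const HFace& f : faces) {
        if (!f.alive) continue;
        fmat(row, 0) = f.a + 1;
        fmat(row, 1) = f.b + 1;
        fmat(row, 2) = f.c + 1;
        vset.insert(f.a); vset.insert(f.b); vset.insert(f.c);
        ++row;
    }
    IntegerVector verts(vset.size());
    row = 0;
    for (int v : vset) verts[row++] = v + 1;

    return List::create(_["vertices"] = verts, _["faces"] = fmat);
}

// ---------------------------------------------------------------------------
// Distances from query points to every triangular hull face.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".face_distances_cpp")]]
NumericVector face_distances_cpp(NumericVector p, NumericMatrix cloud,
                                 IntegerMatrix faces) {
    const int nf = faces.nrow();
    const int n = cloud.nrow();
    std::vector<double> X(3 * (size_t)n);
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) X[3*i + k] = cloud(i, k);
    const double P[3] = {p[0], p[1], p[2]};
    NumericVector out(nf);
    for (int f = 0; f < nf; ++f) {
        out[f] = std::sqrt(pt_tri_dist_sq(P, &X[3*(faces(f,0)-1)],
                                          &X[3*(faces(f,1)-1)],
                                          &X[3*(faces(f,2)-1)]));
    }
    return out;
}

// Per-point minimum and population variance of face distances.
// [[Rcpp::export(name = ".distance_profile_cpp")]]
List distance_profile_cpp(NumericMatrix query, NumericMatrix cloud,
                          IntegerMatrix faces) {
    const int nq = query.nrow();
    const int nf = faces.nrow();
    const int n = cloud.nrow();
    std::vector<double> X(3 * (size_t)n);
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) X[3*i + k] = cloud(i, k);

    NumericVector m(nq), v(nq);
    for (int q = 0; q < nq; ++q) {
        const double P[3] = {query(q,0), query(q,1), query(q,2)};
        double mn = R_PosInf, s = 0.0, s2 = 0.0;
        for (int f = 0; f < nf; ++f) {
            const double d = std::sqrt(pt_tri_dist_sq(P, &X[3*(faces(f,0)-1)],
                                                      &X[3*(faces(f,1)-1)],
                                                      &X[3*(faces(f,2)-1)]));
            if (d < mn) mn = d;
            s += d;
            s2 += d * d;
        }
        m[q] = mn;
        const double mean = s / nf;
        double var = s2 / nf - mean * mean;   // population variance over faces
        v[q] = var > 0.0 ? var : 0.0;
    }
    return List::create(_["m"] = m, _["v"] = v);
}
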