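#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3-D grid (column-major, R array layout) at a
// world-mm point. Points outside the grid bounding box evaluate to zero.
static inline double trilinear(const double *v, const int *dim,
                               const double *origin, const double *spacing,
                               double x, double y, double z) {
    double u0 = (x - origin[0]) / spacing[0];
    double u1 = (y - origin[1]) / spacing[1];
    double u2 = (z - origin[2]) / spacing[2];
    if (u0 < 0 || u1 < 0 || u2 < 0 ||
        u0 > dim[0] - 1 || u1 > dim[1] - 1 || u2 > dim[2] - 1)
        return 0.0;
    int i = (int)std::floor(u0), j = (int)std::floor(u1), k = (int)std::floor(u2);
    if (i == dim[0] - 1) i--;
    if (j == dim[1] - 1) j--;
    if (k == dim[2] - 1) k--;
    double fx = u0 - i, fy = u1 - j, fz = u2 - k;
    const int d0 = dim[0], d01 = dim[0] * dim[1];
#define V(ii, jj, kk) v[(ii) + d0 * (jj) + d01 * (kk)]
    double c00 = V(i, j, k) * (1 - fx) + V(i + 1, j, k) * fx;
    double c10 = V(i, j + 1, k) * (1 - fx) + V(i + 1, j + 1, k) * fx;
    double c01 = V(i, j, k + 1) * (1 - fx) + V(i + 1, j, k + 1) * fx;
    double c11 = V(i, j + 1, k + 1) * (1 - fx) + V(i + 1, j + 1, k + 1) * fx;
#undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
}

// Peak interpolated grid value along each polyline. `pts` holds the
// pre-resampled points of all streamlines stacked row-wise; `offsets` is the
// 0-based start index of each streamline plus a terminal sentinel (length
// n_streamlines + 1).
// [[Rcpp::export]]
NumericVector cppPeaksGrid(NumericMatrix pts, IntegerVector offsets,
                           NumericVector values, IntegerVector dim,
                           NumericVector origin, NumericVector spacing) {
    const int ns = offsets.size() - 1;
    NumericVector out(ns);
    const double *v = REAL(values);
    const double *px = &pts(0, 0);
    const int n = pts.nrow();
    const int idim[3] = {dim[0], dim[1], dim[2]};
    const double org[3] = {origin[0], origin[1], origin[2]};
    const double spc[3] = {spacing[0], spacing[1], spacing[2]};
    for (int s = 0; s < ns; s++) {
        double peak = 0.0;
        for (int p = offsets[s]; p < offsets[s + 1]; p++) {
            double val = trilinear(v, idim, org, spc,
                                   px[p], px[p + n], px[p + 2 * n]);
            if (val > peak) peak = val;
        }
        out[s] = peak;
    }
    return out;
}

// Field magnitude (V/mm) of superposed point current sources at one point.
// Inputs in mm and mA; conductivity sigma in S/m. Distances below
// clampRadius are clamped so contact-adjacent voxels stay finite.
static inline double sourceMagnitude(const double *sx, const double *sy,
                                     const double *sz, const double *cur,
                                     int nsrc, double sigma, double clampR,
                                     double x, double y, double z) {
    double ex = 0.0, ey = 0.0, ez = 0.0;
    const double k = 1.0 / (4.0 * M_PI * sigma);
    for (int c = 0; c < nsrc; c++) {
        double dx = (x - sx[c]) * 1e-3, dy = (y - sy[c]) * 1e-3,
               dz = (z - sz[c]) * 1e-3;
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double rc = clampR * 1e-3;
        double ux, uy, uz;
        if (r < 1e-12) { ux = 0.0; uy = 0.0; uz = 1.0; r = rc; }
        else { ux = dx / r; uy = dy / r; uz = dz / r; if (r < rc) r = rc; }
        double mag = cur[c] * 1e-3 * k / (r * r); // V/m
        ex += mag * ux; ey += mag * uy; ez += mag * uz;
    }
    return std::sqrt(ex * ex + ey * ey + ez * ez) * 1e-3; // V/mm
}

// Evaluate the point-source field magnitude over a regular grid.
// [[Rcpp::export]]
NumericVector cppPointSourceGrid(IntegerVector dim, NumericVector origin,
                                 NumericVector spacing, NumericMatrix sources,
                                 NumericVector currents, double sigma,
                                 double clampRadius) {
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    NumericVector out((R_xlen_t)d0 * d1 * d2);
    const int nsrc = sources.nrow();
    std::vector<double> sx(nsrc), sy(nsrc), sz(nsrc);
    for (int c = 0; c < nsrc; c++) {
        sx[c] = sources(c, 0); sy[c] = sources(c, 1); sz[c] = sources(c, 2);
    }
    R_xlen_t idx = 0;
    for (int k = 0; k < d2; k++) {
        double z = origin[2] + k * spacing[2];
        for (int j = 0; j < d1; j++) {
            double y = origin[1] + j * spacing[1];
            for (int i = 0; i < d0; i++, idx++) {
                double x = origin[0] + i * spacing[0];
                out[idx] = sourceMagnitude(sx.data(), sy.data(), sz.data(),
                                           REAL(currents), nsrc, sigma,
                                           clampRadius, x, y, z);
            }
        }
    }
    return out;
}

// Peak analytic point-source field magnitude along each polyline (no grid).
// [[Rcpp::export]]
NumericVector cppPeaksSources(NumericMatrix pts, IntegerVector offsets,
                              NumericMatrix sources, NumericVector currents,
                              double sigma, double clampRadius) {
    const int ns = offsets.size() - 1;
    NumericVector out(ns);
    const int nsrc = sources.nrow();
    std::vector<double> sx(nsrc), sy(nsrc), sz(nsrc);
    for (int c = 0; c < nsrc; c++) {
        sx[c] = sources(c, 0); sy[c] = sources(c, 1); sz[c] = sources(c, 2);
    }
    const double *px = &pts(0, 0);
    const int n = pts.nrow();
    for (int s = 0; s < ns; s++) {
        double peak = 0.0;
        for (int p = offsets[s]; p < offsets[s + 1]; p++) {
            double val = sourceMagnitude(sx.data(), sy.data(), sz.data(),
                                         REAL(currents), nsrc, sigma,
                                         clampRadius, px[p], px[p + n],
                                         px[p + 2 * n]);
            if (val > peak) peak = val;
        }
        out[s] = peak;
    }
    return out;
}

// Average ranks (ties averaged) of v into r.
static void avgRanks(const std::vector<double> &v, std::vector<double> &r) {
    const int n = v.size();
    std::vector<int> idx(n);
    for (int i = 0; i < n; i++) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    r.resize(n);
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) j++;
        double avg = (i + j) / 2.0 + 1.0;
        for (int k = i; k <= j; k++) r[idx[k]] = avg;
        i = j + 1;
    }
}

// Per-row Spearman correlation of peak rows against improvements, deleting
// zero-peak samples pairwise (fields that never reach the streamline carry
// no dose information for it). Returns a 2-column matrix (rho, n); rows
// with fewer than minN covered samples or zero variance give rho = NA.
// [[Rcpp::export]]
NumericMatrix cppMaskedSpearman(NumericMatrix P, NumericVector y, int minN) {
    const int nr = P.nrow(), nc = P.ncol();
    NumericMatrix out(nr, 2);
    std::vector<double> xs, ys, rx, ry;
    for (int i = 0; i < nr; i++) {
        xs.clear(); ys.clear();
        for (int j = 0; j < nc; j++) {
            double pij = P(i, j), yj = y[j];
            if (pij > 0 && !ISNAN(yj)) { xs.push_back(pij); ys.push_back(yj); }
        }
        const int n = xs.size();
        out(i, 1) = n;
        if (n < minN) { out(i, 0) = NA_REAL; continue; }
        avgRanks(xs, rx);
        avgRanks(ys, ry);
        double mx = 0, my = 0;
        for (int k = 0; k < n; k++) { mx += rx[k]; my += ry[k]; }
        mx /= n; my /= n;
        double sxy = 0, sxx = 0, syy = 0;
        for (int k = 0; k < n; k++) {
            double dx = rx[k] - mx, dy = ry[k] - my;
            sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
        }
        if (sxx <= 0 || syy <= 0) { out(i, 0) = NA_REAL; continue; }
        out(i, 0) = sxy / std::sqrt(sxx * syy);
    }
    return out;
}
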