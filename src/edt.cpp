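#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope-of-parabolas form, generalised to anisotropic
// voxel spacing: the 1-D cost along an axis with spacing s is (s*(q-p))^2.
// INF is represented by a large finite value so parabola intersections
// stay well-defined.

static const double DT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s2) {
    int k = 0;
    v[0] = 0;
    z[0] = -DT_INF;
    z[1] = DT_INF;
    for (int q = 1; q < n; q++) {
        double fq = f[q] + s2 * (double)q * (double)q;
        double s;
        for (;;) {
            int p = v[k];
            s = (fq - (f[p] + s2 * (double)p * (double)p)) /
                (2.0 * s2 * (double)(q - p));
            if (s <= z[k] && k > 0) { k--; } else break;
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = DT_INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < (double)q) k++;
        int p = v[k];
        double dq = (double)(q - p);
        d[q] = s2 * dq * dq + f[p];
    }
}

static void dt_axis(std::vector<double>& g, int nx, int ny, int nz,
                    int axis, double spacing) {
    double s2 = spacing * spacing;
    int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    if (n < 2) return;
    std::vector<double> f(n), d(n), z(n + 1);
    std::vector<int> v(n);
    long stride, n1, n2, str1, str2;
    if (axis == 0) {
        stride = 1;  n1 = ny; str1 = nx;           n2 = nz; str2 = (long)nx * ny;
    } else if (axis == 1) {
        stride = nx; n1 = nx; str1 = 1;            n2 = nz; str2 = (long)nx * ny;
    } else {
        stride = (long)nx * ny; n1 = nx; str1 = 1; n2 = ny; str2 = nx;
    }
    for (long j2 = 0; j2 < n2; j2++) {
        for (long j1 = 0; j1 < n1; j1++) {
            long base = j1 * str1 + j2 * str2;
            for (int q = 0; q < n; q++) f[q] = g[base + q * stride];
            dt1d(f, d, v, z, n, s2);
            for (int q = 0; q < n; q++) g[base + q * stride] = d[q];
        }
    }
}

// [[Rcpp::export(name = ".cv_edt_sq")]]
NumericVector cv_edt_sq(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    long nvox = (long)nx * ny * nz;
    std::vector<double> g(nvox);
    for (long i = 0; i < nvox; i++) g[i] = mask[i] ? 0.0 : DT_INF;
    dt_axis(g, nx, ny, nz, 0, spacing[0]);
    dt_axis(g, nx, ny, nz, 1, spacing[1]);
    dt_axis(g, nx, ny, nz, 2, spacing[2]);
    NumericVector out(nvox);
    for (long i = 0; i < nvox; i++)
        out[i] = (g[i] >= DT_INF) ? R_PosInf : g[i];
    return out;
}

// Trilinear resampling of a scalar field from one regular grid to another.
// Both grids use voxel-centre sampling: physical = origin + index * spacing
// (0-based). Target points outside the source extent get `fill`.

// [[Rcpp::export(name = ".cv_resample_grid")]]
NumericVector cv_resample_grid(NumericVector src, IntegerVector sdim,
                               NumericVector sspacing, NumericVector sorigin,
                               IntegerVector tdim, NumericVector tspacing,
                               NumericVector torigin, double fill) {
    int sx = sdim[0], sy = sdim[1], sz = sdim[2];
    int tx = tdim[0], ty = tdim[1], tz = tdim[2];
    long sxy = (long)sx * sy;
    NumericVector out((long)tx * ty * tz);
    long o = 0;
    for (int k = 0; k < tz; k++) {
        double pz = (torigin[2] + k * tspacing[2] - sorigin[2]) / sspacing[2];
        for (int j = 0; j < ty; j++) {
            double py = (torigin[1] + j * tspacing[1] - sorigin[1]) / sspacing[1];
            for (int i = 0; i < tx; i++, o++) {
                double px = (torigin[0] + i * tspacing[0] - sorigin[0]) / sspacing[0];
                if (px < 0 || py < 0 || pz < 0 ||
                    px > sx - 1 || py > sy - 1 || pz > sz - 1) {
                    out[o] = fill;
                    continue;
                }
                int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                    z0 = (int)std::floor(pz);
                if (x0 == sx - 1) x0--;
                if (y0 == sy - 1) y0--;
                if (z0 == sz - 1) z0--;
                if (sx == 1) x0 = 0;
                if (sy == 1) y0 = 0;
                if (sz == 1) z0 = 0;
                double wx = px - x0, wy = py - y0, wz = pz - z0;
                if (sx == 1) wx = 0;
                if (sy == 1) wy = 0;
                if (sz == 1) wz = 0;
                int x1 = (sx == 1) ? x0 : x0 + 1;
                int y1 = (sy == 1) ? y0 : y0 + 1;
                int z1 = (sz == 1) ? z0 : z0 + 1;
                long b000 = x0 + (long)sx * y0 + sxy * z0;
                long b100 = x1 + (long)sx * y0 + sxy * z0;
                long b010 = x0 + (long)sx * y1 + sxy * z0;
                long b110 = x1 + (long)sx * y1 + sxy * z0;
                long b001 = x0 + (long)sx * y0 + sxy * z1;
                long b101 = x1 + (long)sx * y0 + sxy * z1;
                long b011 = x0 + (long)sx * y1 + sxy * z1;
                long b111 = x1 + (long)sx * y1 + sxy * z1;
                double c00 = src[b000] * (1 - wx) + src[b100] * wx;
                double c10 = src[b010] * (1 - wx) + src[b110] * wx;
                double c01 = src[b001] * (1 - wx) + src[b101] * wx;
                double c11 = src[b011] * (1 - wx) + src[b111] * wx;
                double c0 = c00 * (1 - wy) + c10 * wy;
                double c1 = c01 * (1 - wy) + c11 * wy;
                out[o] = c0 * (1 - wz) + c1 * wz;
            }
        }
    }
    return out;
}
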