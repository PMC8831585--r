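#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// with physical sampling step w. f holds squared distances (or 0/INF seeds).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, double w)
{
    const int n = (int)f.size();
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    const double w2 = w * w;
    for (int q = 1; q < n; ++q) {
        int p = v[k];
        double s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
                   (2.0 * w2 * (q - p));
        while (s <= z[k]) {
            --k;
            p = v[k];
            s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
                (2.0 * w2 * (q - p));
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int p = v[k];
        d[q] = w2 * (double)(q - p) * (double)(q - p) + f[p];
    }
}

// Anisotropic 3D Euclidean distance transform of a binary mask.
// Returns, for every voxel, the physical distance (same units as voxel_size)
// to the nearest zero (background) voxel. Array layout is R's column-major
// with dim = (ny, nx, nz); voxel_size = (dy, dx, dz).
// [[Rcpp::export]]
NumericVector cpp_edt_aniso(LogicalVector mask, IntegerVector dims,
                            NumericVector voxel_size)
{
    const int ny = dims[0], nx = dims[1], nz = dims[2];
    const double dy = voxel_size[0], dx = voxel_size[1], dz = voxel_size[2];
    const double BIG = 1e30;
    const R_xlen_t ntot = (R_xlen_t)ny * nx * nz;
    std::vector<double> g(ntot);
    for (R_xlen_t i = 0; i < ntot; ++i)
        g[i] = mask[i] ? BIG : 0.0;

    std::vector<double> f, d;

    // pass along y (fastest-varying index)
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)x * ny;
            for (int y = 0; y < ny; ++y) f[y] = g[base + y];
            dt1d(f, d, dy);
            for (int y = 0; y < ny; ++y) g[base + y] = d[y];
        }
    // pass along x
    f.resize(nx); d.resize(nx);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + y;
            for (int x = 0; x < nx; ++x) f[x] = g[base + (R_xlen_t)x * ny];
            dt1d(f, d, dx);
            for (int x = 0; x < nx; ++x) g[base + (R_xlen_t)x * ny] = d[x];
        }
    // pass along z
    f.resize(nz); d.resize(nz);
    for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = (R_xlen_t)x * ny + y;
            for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nx * ny];
            dt1d(f, d, dz);
            for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = d[z];
        }

    NumericVector out(ntot);
    for (R_xlen_t i = 0; i < ntot; ++i)
        out[i] = std::sqrt(g[i]);
    out.attr("dim") = dims;
    return out;
}

// 26-connected component labelling of a 3D binary mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims)
{
    const int ny = dims[0], nx = dims[1], nz = dims[2];
    const R_xlen_t ntot = (R_xlen_t)ny * nx * nz;
    IntegerVector lab(ntot, 0);
    int current = 0;
    std::vector<R_xlen_t> stack;
    stack.reserve(1024);

    for (R_xlen_t i = 0; i < ntot; ++i) {
        if (!mask[i] || lab[i] != 0) continue;
        ++current;
        lab[i] = current;
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int z = (int)(v / ((R_xlen_t)nx * ny));
            int rem = (int)(v - (R_xlen_t)z * nx * ny);
            int x = rem / ny;
            int y = rem % ny;
            for (int dz = -1; dz <= 1; ++dz)
                for (int dx = -1; dx <= 1; ++dx)
                    for (int dy = -1; dy <= 1; ++dy) {
                        if (dz == 0 && dx == 0 && dy == 0) continue;
                        int yy = y + dy, xx = x + dx, zz = z + dz;
                        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
                            zz < 0 || zz >= nz) continue;
                        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)xx * ny + yy;
                        if (mask[w] && lab[w] == 0) {
                            lab[w] = current;
                            stack.push_back(w);
                        }
                    }
        }
    }
    lab.attr("dim") = dims;
    return lab;
}

// Fill holes plane by plane: background pixels not reachable (4-connectivity)
// from the plane border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_2d(LogicalVector mask, IntegerVector dims)
{
    const int ny = dims[0], nx = dims[1], nz = dims[2];
    LogicalVector out = clone(mask);
    std::vector<char> reach((size_t)ny * nx);
    std::vector<int> stack;
    stack.reserve(1024);

    for (int z = 0; z < nz; ++z) {
        R_xlen_t base = (R_xlen_t)z * nx * ny;
        std::fill(reach.begin(), reach.end(), 0);
        // seed from border background pixels
        for (int x = 0; x < nx; ++x)
            for (int y = 0; y < ny; ++y) {
                if (y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
                int idx = x * ny + y;
                if (!mask[base + idx]) {
                    reach[idx] = 1;
                    stack.push_back(idx);
                }
            }
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            int x = v / ny, y = v % ny;
            const int offs[4][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1}};
            for (int k = 0; k < 4; ++k) {
                int yy = y + offs[k][0], xx = x + offs[k][1];
                if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
                int w = xx * ny + yy;
                if (!mask[base + w] && !reach[w]) {
                    reach[w] = 1;
                    stack.push_back(w);
                }
            }
        }
        for (int idx = 0; idx < nx * ny; ++idx)
            if (!mask[base + idx] && !reach[idx]) out[base + idx] = true;
    }
    return out;
}

// Strict 6-connectivity local maxima of a 3D array; border voxels are
// compared against existing neighbors only. Returns 1-based (y, x, z) rows.
// [[Rcpp::export]]
IntegerMatrix cpp_local_max6(NumericVector a, IntegerVector dims)
{
    const int ny = dims[0], nx = dims[1], nz = dims[2];
    std::vector<int> ys, xs, zs;
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x)
            for (int y = 0; y < ny; ++y) {
                R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)x * ny + y;
                double v = a[i];
                bool ok = true;
                if (y > 0 && a[i - 1] >= v) ok = false;
                if (ok && y < ny - 1 && a[i + 1] >= v) ok = false;
                if (ok && x > 0 && a[i - ny] >= v) ok = false;
                if (ok && x < nx - 1 && a[i + ny] >= v) ok = false;
                if (ok && z > 0 && a[i - (R_xlen_t)nx * ny] >= v) ok = false;
                if (ok && z < nz - 1 && a[i + (R_xlen_t)nx * ny] >= v) ok = false;
                if (ok) { ys.push_back(y + 1); xs.push_back(x + 1); zs.push_back(z + 1); }
            }
    IntegerMatrix out(ys.size(), 3);
    for (size_t r = 0; r < ys.size(); ++r) {
        out(r, 0) = ys[r]; out(r, 1) = xs[r]; out(r, 2) = zs[r];
    }
    return out;
}
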