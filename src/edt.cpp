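#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb & Huttenlocher lower-envelope 1-D squared distance transform,
// with parabola abscissae at physical positions i*step (anisotropic spacing).
// Points with f == INF carry no parabola and are skipped when building the
// envelope; they still receive a distance from the finite ones.
static void dt1d(std::vector<double>& f, int n, double step) {
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; i++)
        if (f[i] < INF) idx.push_back(i);
    if (idx.empty()) return;
    std::vector<int> v(idx.size());
    std::vector<double> z(idx.size() + 1), d(n);
    int k = 0;
    v[0] = idx[0]; z[0] = -INF; z[1] = INF;
    for (size_t m = 1; m < idx.size(); m++) {
        int q = idx[m];
        double qq = q * step, s;
        while (true) {
            double vv = v[k] * step;
            s = ((f[q] + qq*qq) - (f[v[k]] + vv*vv)) / (2*qq - 2*vv);
            if (s <= z[k]) k--; else break; // s finite, so never pops past z[0]
        }
        k++; v[k] = q; z[k] = s; z[k+1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double qq = q * step;
        while (z[k+1] < qq) k++;
        double vv = v[k] * step;
        d[q] = (qq - vv)*(qq - vv) + f[v[k]];
    }
    for (int q = 0; q < n; q++) f[q] = d[q];
}

// Squared Euclidean distance (world mm) from every voxel to the nearest
// voxel where seed == TRUE. Voxels with seed TRUE get 0. Passing a
// non-finite z spacing restricts the transform to in-plane distances.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector seed, IntegerVector dim,
                         NumericVector spacing) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t n = (size_t)nx * ny * nz;
    NumericVector out(n);
    for (size_t i = 0; i < n; i++) out[i] = seed[i] ? 0.0 : INF;
    std::vector<double> line;
    line.resize(nx);
    for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++) {
            size_t base = (size_t)nx * (j + (size_t)ny * k);
            for (int i = 0; i < nx; i++) line[i] = out[base + i];
            dt1d(line, nx, spacing[0]);
            for (int i = 0; i < nx; i++) out[base + i] = line[i];
        }
    line.assign(ny, 0.0);
    for (int k = 0; k < nz; k++)
        for (int i = 0; i < nx; i++) {
            size_t base = (size_t)i + (size_t)nx * ny * k;
            for (int j = 0; j < ny; j++) line[j] = out[base + (size_t)nx * j];
            dt1d(line, ny, spacing[1]);
            for (int j = 0; j < ny; j++) out[base + (size_t)nx * j] = line[j];
        }
    if (R_finite(spacing[2])) {
        line.assign(nz, 0.0);
        size_t stride = (size_t)nx * ny;
        for (int j = 0; j < ny; j++)
            for (int i = 0; i < nx; i++) {
                size_t base = (size_t)i + (size_t)nx * j;
                for (int k = 0; k < nz; k++) line[k] = out[base + stride * k];
                dt1d(line, nz, spacing[2]);
                for (int k = 0; k < nz; k++) out[base + stride * k] = line[k];
            }
    }
    return out;
}
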