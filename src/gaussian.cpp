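#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur along one axis, reflecting at the boundary.
static void blurAxis(std::vector<double>& v, int nx, int ny, int nz,
                     int axis, double sigmaVox) {
    if (sigmaVox <= 0) return;
    int radius = (int)std::ceil(3.0 * sigmaVox);
    int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
    if (radius < 1 || n == 1) return;
    std::vector<double> kern(2 * radius + 1);
    double s = 0;
    for (int t = -radius; t <= radius; t++) {
        kern[t + radius] = std::exp(-0.5 * t * t / (sigmaVox * sigmaVox));
        s += kern[t + radius];
    }
    for (double& k : kern) k /= s;
    size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx : (size_t)nx * ny);
    int n1 = axis == 0 ? ny : nx;
    int n2 = axis == 2 ? ny : nz;
    size_t s1 = axis == 0 ? (size_t)nx : 1;
    size_t s2 = axis == 2 ? (size_t)nx : (size_t)nx * ny;
    std::vector<double> line(n);
    for (int b = 0; b < n2; b++)
        for (int a = 0; a < n1; a++) {
            size_t base = s1 * a + s2 * b;
            for (int i = 0; i < n; i++) line[i] = v[base + stride * i];
            for (int i = 0; i < n; i++) {
                double acc = 0;
                for (int t = -radius; t <= radius; t++) {
                    int j = i + t;
                    if (j < 0) j = -j - 1;          // reflect
                    if (j >= n) j = 2 * n - 1 - j;
                    if (j < 0) j = 0; if (j >= n) j = n - 1;
                    acc += kern[t + radius] * line[j];
                }
                v[base + stride * i] = acc;
            }
        }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector values, IntegerVector dim,
                                NumericVector sigmaVox) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    std::vector<double> v(values.begin(), values.end());
    blurAxis(v, nx, ny, nz, 0, sigmaVox[0]);
    blurAxis(v, nx, ny, nz, 1, sigmaVox[1]);
    blurAxis(v, nx, ny, nz, 2, sigmaVox[2]);
    return NumericVector(v.begin(), v.end());
}
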