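#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "interp.h"
using namespace Rcpp;

NumericVector cpp_gaussian_blur(NumericVector values, IntegerVector dim,
                                NumericVector sigmaVox);

// One resolution level of Thirion-style demons with Gaussian field
// regularisation. Displacements are in mm, pull-back convention:
// warped(x) = moving(x + u(x)). Stops early (keeping the best field) if the
// MSE rises for three consecutive iterations.
// [[Rcpp::export]]
List cpp_demons(NumericVector fixed, NumericVector moving, IntegerVector dim,
                NumericVector spacing, NumericVector ux0, NumericVector uy0,
                NumericVector uz0, int niter, double sigmaVox, double fill) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t n = (size_t)nx * ny * nz;
    NumericVector ux = clone(ux0), uy = clone(uy0), uz = clone(uz0);
    NumericVector bx = clone(ux0), by = clone(uy0), bz = clone(uz0);
    const double* mv = moving.begin();
    std::vector<double> warped(n), gx(n), gy(n), gz(n);
    double meanSp = (spacing[0] + spacing[1] + spacing[2]) / 3.0;
    double K = meanSp * meanSp;
    double maxStep = meanSp; // cap per-iteration update
    double bestMse = R_PosInf;
    int rises = 0;
    NumericVector sig(3, sigmaVox);
    std::vector<double> mseHist;
    for (int it = 0; it < niter; it++) {
        // warp moving by current field
        size_t idx = 0;
        for (int k = 0; k < nz; k++)
            for (int j = 0; j < ny; j++)
                for (int i = 0; i < nx; i++, idx++) {
                    double x = i + ux[idx] / spacing[0];
                    double y = j + uy[idx] / spacing[1];
                    double z = k + uz[idx] / spacing[2];
                    warped[idx] = sampleTrilinear(mv, nx, ny, nz, x, y, z, fill);
                }
        double mse = 0;
        for (size_t s = 0; s < n; s++) {
            double d = fixed[s] - warped[s];
            mse += d * d;
        }
        mse /= (double)n;
        mseHist.push_back(mse);
        if (mse < bestMse) {
            bestMse = mse;
            bx = clone(ux); by = clone(uy); bz = clone(uz);
            rises = 0;
        } else if (mse > bestMse + 1e-12 * (bestMse > 1.0 ? bestMse : 1.0)) {
            if (++rises >= 3) break; // diverging: keep the best field
        } // plateau: neither an improvement nor a rise
        // central-difference gradient of the warped image (per mm)
        idx = 0;
        for (int k = 0; k < nz; k++)
            for (int j = 0; j < ny; j++)
                for (int i = 0; i < nx; i++, idx++) {
                    int ip = i < nx-1 ? i+1 : i, im = i > 0 ? i-1 : i;
                    int jp = j < ny-1 ? j+1 : j, jm = j > 0 ? j-1 : j;
                    int kp = k < nz-1 ? k+1 : k, km = k > 0 ? k-1 : k;
                    size_t nxy = (size_t)nx * ny;
                    gx[idx] = (warped[(size_t)ip + (size_t)nx*j + nxy*k] -
                               warped[(size_t)im + (size_t)nx*j + nxy*k]) /
                              ((ip - im) * spacing[0]);
                    gy[idx] = (warped[(size_t)i + (size_t)nx*jp + nxy*k] -
                               warped[(size_t)i + (size_t)nx*jm + nxy*k]) /
                              ((jp - jm) * spacing[1]);
                    gz[idx] = (warped[(size_t)i + (size_t)nx*j + nxy*kp] -
                               warped[(size_t)i + (size_t)nx*j + nxy*km]) /
                              ((kp - km) * spacing[2]);
                }
        // demons update
        for (size_t s = 0; s < n; s++) {
            double diff = fixed[s] - warped[s];
            double g2 = gx[s]*gx[s] + gy[s]*gy[s] + gz[s]*gz[s];
            double denom = g2 + diff * diff / K;
            if (denom < 1e-9) continue;
            double f = diff / denom;
            double dx = f * gx[s], dy = f * gy[s], dz = f * gz[s];
            double norm = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (norm > maxStep) {
                double sc = maxStep / norm;
                dx *= sc; dy *= sc; dz *= sc;
            }
            ux[s] += dx; uy[s] += dy; uz[s] += dz;
        }
        ux = cpp_gaussian_blur(ux, dim, sig);
        uy = cpp_gaussian_blur(uy, dim, sig);
        uz = cpp_gaussian_blur(uz, dim, sig);
    }
    return List::create(_["ux"] = bx, _["uy"] = by, _["uz"] = bz,
                        _["mse"] = NumericVector(mseHist.begin(), mseHist.end()),
                        _["bestMse"] = bestMse);
}
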