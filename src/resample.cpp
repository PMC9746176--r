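#include <Rcpp.h>
#include "interp.h"
using namespace Rcpp;

// Resample a volume onto a target grid. Grids are axis-aligned; a voxel
// (i,j,k) (0-based here) has world position origin + idx * spacing.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector values, IntegerVector sdim,
                           NumericVector sspacing, NumericVector sorigin,
                           IntegerVector tdim, NumericVector tspacing,
                           NumericVector torigin, int nearest, double fill) {
    int nx = sdim[0], ny = sdim[1], nz = sdim[2];
    int tx = tdim[0], ty = tdim[1], tz = tdim[2];
    NumericVector out((size_t)tx * ty * tz);
    const double* v = values.begin();
    size_t idx = 0;
    for (int k = 0; k < tz; k++) {
        double wz = torigin[2] + k * tspacing[2];
        double z = (wz - sorigin[2]) / sspacing[2];
        for (int j = 0; j < ty; j++) {
            double wy = torigin[1] + j * tspacing[1];
            double y = (wy - sorigin[1]) / sspacing[1];
            for (int i = 0; i < tx; i++, idx++) {
                double wx = torigin[0] + i * tspacing[0];
                double x = (wx - sorigin[0]) / sspacing[0];
                out[idx] = nearest ?
                    sampleNearest(v, nx, ny, nz, x, y, z, fill) :
                    sampleTrilinear(v, nx, ny, nz, x, y, z, fill);
            }
        }
    }
    return out;
}

// Pull-back warp: out(x) = vol(index of (world(x) + disp(x))).
// Displacements are in mm on the same grid as the output.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector values, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       NumericVector dx, NumericVector dy, NumericVector dz,
                       int nearest, double fill) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector out((size_t)nx * ny * nz);
    const double* v = values.begin();
    size_t idx = 0;
    for (int k = 0; k < nz; k++)
        for (int j = 0; j < ny; j++)
            for (int i = 0; i < nx; i++, idx++) {
                double x = i + dx[idx] / spacing[0];
                double y = j + dy[idx] / spacing[1];
                double z = k + dz[idx] / spacing[2];
                out[idx] = nearest ?
                    sampleNearest(v, nx, ny, nz, x, y, z, fill) :
                    sampleTrilinear(v, nx, ny, nz, x, y, z, fill);
            }
    return out;
}

// Rigid pull-back onto a target grid: sample moving at R (w - c) + c + t.
// [[Rcpp::export]]
NumericVector cpp_rigid_resample(NumericVector values, IntegerVector sdim,
                                 NumericVector sspacing, NumericVector sorigin,
                                 IntegerVector tdim, NumericVector tspacing,
                                 NumericVector torigin, NumericMatrix rot,
                                 NumericVector center, NumericVector trans,
                                 int nearest, double fill) {
    int nx = sdim[0], ny = sdim[1], nz = sdim[2];
    int tx = tdim[0], ty = tdim[1], tz = tdim[2];
    NumericVector out((size_t)tx * ty * tz);
    const double* v = values.begin();
    double R[9];
    for (int r = 0; r < 3; r++)
        for (int c = 0; c < 3; c++) R[3*r + c] = rot(r, c);
    size_t idx = 0;
    for (int k = 0; k < tz; k++)
        for (int j = 0; j < ty; j++)
            for (int i = 0; i < tx; i++, idx++) {
                double w0 = torigin[0] + i * tspacing[0] - center[0];
                double w1 = torigin[1] + j * tspacing[1] - center[1];
                double w2 = torigin[2] + k * tspacing[2] - center[2];
                double m0 = R[0]*w0 + R[1]*w1 + R[2]*w2 + center[0] + trans[0];
                double m1 = R[3]*w0 + R[4]*w1 + R[5]*w2 + center[1] + trans[1];
                double m2 = R[6]*w0 + R[7]*w1 + R[8]*w2 + center[2] + trans[2];
                double x = (m0 - sorigin[0]) / sspacing[0];
                double y = (m1 - sorigin[1]) / sspacing[1];
                double z = (m2 - sorigin[2]) / sspacing[2];
                out[idx] = nearest ?
                    sampleNearest(v, nx, ny, nz, x, y, z, fill) :
                    sampleTrilinear(v, nx, ny, nz, x, y, z, fill);
            }
    return out;
}
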