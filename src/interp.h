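#ifndef CBCTDOSE_INTERP_H
#define CBCTDOSE_INTERP_H

#include <cmath>

// Trilinear sampling of a volume at a continuous 0-based voxel index.
// Positions outside [0, n-1] on any axis return `fill` (the source extent
// is taken to end at the outermost voxel centers).
inline double sampleTrilinear(const double* v, int nx, int ny, int nz,
                              double x, double y, double z, double fill) {
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
        return fill;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    int i1 = i0 + 1, j1 = j0 + 1, k1 = k0 + 1;
    if (nx == 1) { i0 = i1 = 0; }
    if (ny == 1) { j0 = j1 = 0; }
    if (nz == 1) { k0 = k1 = 0; }
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (nx == 1) fx = 0.0; if (ny == 1) fy = 0.0; if (nz == 1) fz = 0.0;
    size_t nxy = (size_t)nx * ny;
    #define V(i,j,k) v[(size_t)(i) + (size_t)nx*(j) + nxy*(k)]
    double c00 = V(i0,j0,k0)*(1-fx) + V(i1,j0,k0)*fx;
    double c10 = V(i0,j1,k0)*(1-fx) + V(i1,j1,k0)*fx;
    double c01 = V(i0,j0,k1)*(1-fx) + V(i1,j0,k1)*fx;
    double c11 = V(i0,j1,k1)*(1-fx) + V(i1,j1,k1)*fx;
    #undef V
    double c0 = c00*(1-fy) + c10*fy;
    double c1 = c01*(1-fy) + c11*fy;
    return c0*(1-fz) + c1*fz;
}

inline double sampleNearest(const double* v, int nx, int ny, int nz,
                            double x, double y, double z, double fill) {
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
        return fill;
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0) i = 0; if (i > nx-1) i = nx-1;
    if (j < 0) j = 0; if (j > ny-1) j = ny-1;
    if (k < 0) k = 0; if (k > nz-1) k = nz-1;
    return v[(size_t)i + (size_t)nx*j + (size_t)nx*ny*k];
}

#endif
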