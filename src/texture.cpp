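#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// The 13 unique direction vectors of the 26-neighborhood (one per
// antipodal pair), expressed in voxel steps. Texture matrices that are
// direction-dependent (GLCM, GLRLM) are computed per direction and
// averaged on the R side.
static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
    {1, 0, 0},  {0, 1, 0},  {0, 0, 1},
    {1, 1, 0},  {1, -1, 0}, {1, 0, 1},  {1, 0, -1},
    {0, 1, 1},  {0, 1, -1},
    {1, 1, 1},  {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int vox(int i, int j, int k, int nx, int ny) {
    return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
IntegerMatrix cpp_direction_set() {
    IntegerMatrix D(NDIR, 3);
    for (int d = 0; d < NDIR; ++d)
        for (int a = 0; a < 3; ++a) D(d, a) = DIRS[d][a];
    return D;
}

// Symmetrized gray-level co-occurrence counts at unit offset, one count
// matrix per direction. Levels are 1..ng.
// [[Rcpp::export]]
List cpp_glcm_counts(IntegerVector lv, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    List out(NDIR);
    for (int d = 0; d < NDIR; ++d) {
        NumericMatrix M(ng, ng);
        int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        for (int k = 0; k < nz; ++k)
            for (int j = 0; j < ny; ++j)
                for (int i = 0; i < nx; ++i) {
                    int i2 = i + dx, j2 = j + dy, k2 = k + dz;
                    if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny ||
                        k2 < 0 || k2 >= nz)
                        continue;
                    int a = lv[vox(i, j, k, nx, ny)] - 1;
                    int b = lv[vox(i2, j2, k2, nx, ny)] - 1;
                    M(a, b) += 1.0;
                    M(b, a) += 1.0;
                }
        out[d] = M;
    }
    return out;
}

// Gray-level run-length counts, one (ng x max_run_length) matrix per
// direction. Every voxel belongs to exactly one run per direction.
// [[Rcpp::export]]
List cpp_glrlm_counts(IntegerVector lv, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int maxlen = std::max(nx, std::max(ny, nz));
    List out(NDIR);
    for (int d = 0; d < NDIR; ++d) {
        NumericMatrix M(ng, maxlen);
        int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        for (int k = 0; k < nz; ++k)
            for (int j = 0; j < ny; ++j)
                for (int i = 0; i < nx; ++i) {
                    // start a line only where the previous voxel along
                    // the direction falls outside the grid
                    int ip = i - dx, jp = j - dy, kp = k - dz;
                    if (ip >= 0 && ip < nx && jp >= 0 && jp < ny &&
                        kp >= 0 && kp < nz)
                        continue;
                    int ci = i, cj = j, ck = k;
                    int cur = lv[vox(ci, cj, ck, nx, ny)];
                    int len = 0;
                    while (ci >= 0 && ci < nx && cj >= 0 && cj < ny &&
                           ck >= 0 && ck < nz) {
                        int g = lv[vox(ci, cj, ck, nx, ny)];
                        if (g == cur) {
                            ++len;
                        } else {
                            M(cur - 1, len - 1) += 1.0;
                            cur = g;
                            len = 1;
                        }
                        ci += dx; cj += dy; ck += dz;
                    }
                    M(cur - 1, len - 1) += 1.0;
                }
        out[d] = M;
    }
    return out;
}

// 26-connected zones of constant gray level. Returns one row per zone:
// (level, size). Zone-size counts are tabulated on the R side.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector lv, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int n = nx * ny * nz;
    std::vector<char> visited(n, 0);
    std::vector<int> zlevel, zsize, stack;
    stack.reserve(256);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                int idx0 = vox(i, j, k, nx, ny);
                if (visited[idx0]) continue;
                int g = lv[idx0];
                int size = 0;
                stack.clear();
                stack.push_back(idx0);
                visited[idx0] = 1;
                while (!stack.empty()) {
                    int idx = stack.back();
                    stack.pop_back();
                    ++size;
                    int ci = idx % nx;
                    int cj = (idx / nx) % ny;
                    int ck = idx / (nx * ny);
                    for (int dk = -1; dk <= 1; ++dk)
                        for (int dj = -1; dj <= 1; ++dj)
                            for (int di = -1; di <= 1; ++di) {
                                if (di == 0 && dj == 0 && dk == 0) continue;
                                int ni = ci + di, nj = cj + dj, nk = ck + dk;
                                if (ni < 0 || ni >= nx || nj < 0 ||
                                    nj >= ny || nk < 0 || nk >= nz)
                                    continue;
                                int nidx = vox(ni, nj, nk, nx, ny);
                                if (visited[nidx] || lv[nidx] != g) continue;
                                visited[nidx] = 1;
                                stack.push_back(nidx);
                            }
                }
                zlevel.push_back(g);
                zsize.push_back(size);
            }
    int nz_out = (int)zlevel.size();
    IntegerMatrix Z(nz_out, 2);
    for (int z = 0; z < nz_out; ++z) {
        Z(z, 0) = zlevel[z];
        Z(z, 1) = zsize[z];
    }
    return Z;
}

// Gray-level dependence counts: for each voxel, the number of 26-
// neighbors within the grid whose level differs from the center by at
// most alpha. Column c (1-based) holds dependence size c, i.e. the
// neighbor count plus one for the center voxel itself.
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector lv, IntegerVector dim, int ng,
                              int alpha) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix M(ng, 27);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                int g = lv[vox(i, j, k, nx, ny)];
                int dep = 0;
                for (int dk = -1; dk <= 1; ++dk)
                    for (int dj = -1; dj <= 1; ++dj)
                        for (int di = -1; di <= 1; ++di) {
                            if (di == 0 && dj == 0 && dk == 0) continue;
                            int ni = i + di, nj = j + dj, nk = k + dk;
                            if (ni < 0 || ni >= nx || nj < 0 || nj >= ny ||
                                nk < 0 || nk >= nz)
                                continue;
                            int gn = lv[vox(ni, nj, nk, nx, ny)];
                            if (std::abs(gn - g) <= alpha) ++dep;
                        }
                M(g - 1, dep) += 1.0;  // column dep (0-based) = size dep+1
            }
    return M;
}

// Neighborhood gray-tone difference accumulators: s[g] is the summed
// absolute difference between level g and the mean of the available
// 26-neighbors, n[g] the voxel count at level g. Voxels with no
// neighbor (1x1x1 grid) are skipped.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector lv, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector s(ng), n(ng);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                int g = lv[vox(i, j, k, nx, ny)];
                double sum = 0.0;
                int cnt = 0;
                for (int dk = -1; dk <= 1; ++dk)
                    for (int dj = -1; dj <= 1; ++dj)
                        for (int di = -1; di <= 1; ++di) {
                            if (di == 0 && dj == 0 && dk == 0) continue;
                            int ni = i + di, nj = j + dj, nk = k + dk;
                            if (ni < 0 || ni >= nx || nj < 0 || nj >= ny ||
                                nk < 0 || nk >= nz)
                                continue;
                            sum += lv[vox(ni, nj, nk, nx, ny)];
                            ++cnt;
                        }
                if (cnt == 0) continue;
                s[g - 1] += std::abs((double)g - sum / cnt);
                n[g - 1] += 1.0;
            }
    return List::create(_["s"] = s, _["n"] = n);
}
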