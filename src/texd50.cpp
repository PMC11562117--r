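#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// In-plane pair directions (0, 45, 90, 135 degrees). Each unordered voxel
// pair is accumulated in both orientations, so the GLCM is symmetric by
// construction and the direction set is invariant under axis mirroring.
static const int DIRS[4][2] = {{1, 0}, {0, 1}, {1, 1}, {1, -1}};

// plane -> the two grid axes that span it: axial (x,y), coronal (x,z),
// sagittal (y,z)
static const int PLANE_AXES[3][2] = {{0, 1}, {0, 2}, {1, 2}};

static inline int vidx(int i, int j, int k, int nx, int ny) {
    return i + nx * (j + ny * k);
}

// Voxel-wise GLCM autocorrelation on three orthogonal planes.
// vol:    raw intensities (only used when per_window = true)
// mask:   analysis mask (levels outside are ignored)
// levels: global quantisation, values in 1..ng inside mask, 0 outside
// Returns a map with NA outside the mask and at voxels with no valid pair
// in any plane.
// [[Rcpp::export]]
NumericVector texture_map_cpp(NumericVector vol, LogicalVector mask,
                              IntegerVector levels, IntegerVector dim,
                              int ng, int radius, int distance,
                              bool per_window) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int n = nx * ny * nz;
    NumericVector out(n, NA_REAL);

    const int wside = 2 * radius + 1;
    std::vector<int> wlev(wside * wside, 0); // per-plane window levels

    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const int c = vidx(i, j, k, nx, ny);
                if (!mask[c]) continue;
                const int ctr[3] = {i, j, k};
                double plane_sum = 0.0;
                int n_planes = 0;

                for (int p = 0; p < 3; ++p) {
                    const int au = PLANE_AXES[p][0], av = PLANE_AXES[p][1];
                    const int nu = dim[au], nv = dim[av];

                    // collect the in-plane window's levels (0 = unusable)
                    double vmin = R_PosInf, vmax = R_NegInf;
                    for (int b = -radius; b <= radius; ++b) {
                        for (int a = -radius; a <= radius; ++a) {
                            int q[3] = {ctr[0], ctr[1], ctr[2]};
                            q[au] += a;
                            q[av] += b;
                            int widx = (a + radius) + wside * (b + radius);
                            wlev[widx] = 0;
                            if (q[au] < 0 || q[au] >= nu || q[av] < 0 ||
                                q[av] >= nv)
                                continue;
                            int vi = vidx(q[0], q[1], q[2], nx, ny);
                            if (!mask[vi]) continue;
                            if (per_window) {
                                double v = vol[vi];
                                if (v < vmin) vmin = v;
                                if (v > vmax) vmax = v;
                                wlev[widx] = -vi - 1; // defer; store voxel
                            } else {
                                wlev[widx] = levels[vi];
                            }
                        }
                    }
                    if (per_window) {
                        const double rng = vmax - vmin;
                        for (int w = 0; w < wside * wside; ++w) {
                            if (wlev[w] >= 0) continue;
                            int vi = -wlev[w] - 1;
                            int lev = 1;
                            if (rng > 0) {
                                lev = (int)std::floor((vol[vi] - vmin) / rng *
                                                      ng) + 1;
                                if (lev > ng) lev = ng;
                            }
                            wlev[w] = lev;
                        }
                    }

                    // accumulate symmetric co-occurrences at the set distance
                    long npair = 0;
                    double acc = 0.0;
                    for (int b = -radius; b <= radius; ++b) {
                        for (int a = -radius; a <= radius; ++a) {
                            int l1 = wlev[(a + radius) + wside * (b + radius)];
                            if (l1 == 0) continue;
                            for (int d = 0; d < 4; ++d) {
                                int a2 = a + DIRS[d][0] * distance;
                                int b2 = b + DIRS[d][1] * distance;
                                if (a2 < -radius || a2 > radius ||
                                    b2 < -radius || b2 > radius)
                                    continue;
                                int l2 = wlev[(a2 + radius) +
                                              wside * (b2 + radius)];
                                if (l2 == 0) continue;
                                acc += 2.0 * l1 * l2;
                                npair += 2;
                            }
                        }
                    }
                    if (npair > 0) {
                        plane_sum += acc / (double)npair;
                        ++n_planes;
                    }
                }
                if (n_planes > 0) out[c] = plane_sum / n_planes;
            }
        }
    }
    out.attr("dim") = dim;
    return out;
}

// Connected-component labelling of a 3D boolean grid at 6-, 18- or
// 26-connectivity. Returns integer labels (0 = background), labelled in
// scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector x, IntegerVector dim,
                                   int connectivity) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int n = nx * ny * nz;
    IntegerVector lab(n, 0);

    // neighbour offsets for the requested connectivity
    std::vector<int> di, dj, dk;
    for (int c = -1; c <= 1; ++c)
        for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
                int m = std::abs(a) + std::abs(b) + std::abs(c);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                di.push_back(a);
                dj.push_back(b);
                dk.push_back(c);
            }

    int next = 0;
    std::vector<int> stack;
    for (int idx = 0; idx < n; ++idx) {
        if (!x[idx] || lab[idx] != 0) continue;
        lab[idx] = ++next;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
            int cur = stack.back();
            stack.pop_back();
            int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
            for (size_t d = 0; d < di.size(); ++d) {
                int ii = ci + di[d], jj = cj + dj[d], kk = ck + dk[d];
                if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                    kk >= nz)
                    continue;
                int nb = vidx(ii, jj, kk, nx, ny);
                if (x[nb] && lab[nb] == 0) {
                    lab[nb] = next;
                    stack.push_back(nb);
                }
            }
        }
    }
    lab.attr("dim") = dim;
    return lab;
}

// Separable Gaussian smoothing of a 3D grid with mirror boundary handling.
// sigma is in voxels; sigma <= 0 returns the input unchanged.
// [[Rcpp::export]]
NumericVector smooth3d_cpp(NumericVector x, IntegerVector dim, double sigma) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector out = clone(x);
    if (sigma <= 0) {
        out.attr("dim") = dim;
        return out;
    }
    const int r = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> w(2 * r + 1);
    double wsum = 0.0;
    for (int t = -r; t <= r; ++t) {
        w[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
        wsum += w[t + r];
    }
    for (double &v : w) v /= wsum;

    NumericVector tmp(nx * ny * nz);
    const int ndim[3] = {nx, ny, nz};
    const int stride[3] = {1, nx, nx * ny};

    for (int axis = 0; axis < 3; ++axis) {
        const int na = ndim[axis], sa = stride[axis];
        for (int k = 0; k < nz; ++k)
            for (int j = 0; j < ny; ++j)
                for (int i = 0; i < nx; ++i) {
                    const int pos[3] = {i, j, k};
                    const int base = vidx(i, j, k, nx, ny);
                    double acc = 0.0;
                    for (int t = -r; t <= r; ++t) {
                        int p = pos[axis] + t;
                        while (p < 0 || p >= na) { // mirror
                            if (p < 0) p = -p - 1;
                            if (p >= na) p = 2 * na - 1 - p;
                        }
                        acc += w[t + r] * out[base + (p - pos[axis]) * sa];
                    }
                    tmp[base] = acc;
                }
        std::copy(tmp.begin(), tmp.end(), out.begin());
    }
    out.attr("dim") = dim;
    return out;
}
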