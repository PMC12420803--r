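#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path compression + union by size.
static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

// TFCE for the positive tail of `v` on a 3D grid with 26-connectivity.
// Heights h = dh, 2*dh, ..., K*dh with K = floor(max(v)/dh); at each height
// every suprathreshold voxel accumulates extent^E * h^H * dh, where extent
// is the size of its connected component at that height. Components are
// grown incrementally from the top height down with a union-find.
static void tfce_one_sign(const std::vector<double> &v,
                          int nx, int ny, int nz,
                          double E, double H, double dh,
                          std::vector<double> &out) {
    const int n = nx * ny * nz;
    double vmax = 0.0;
    for (int i = 0; i < n; ++i) if (v[i] > vmax) vmax = v[i];
    if (vmax <= 0.0 || dh <= 0.0) return;
    const int K = (int)std::floor(vmax / dh + 0.5 + 1e-12);
    if (K < 1) return;

    std::vector<int> order;
    order.reserve(n / 4);
    for (int i = 0; i < n; ++i) if (v[i] > 0.0) order.push_back(i);
    std::sort(order.begin(), order.end(),
              [&v](int a, int b) { return v[a] > v[b]; });

    std::vector<int> parent(n), csize(n, 0);
    std::vector<char> active(n, 0);
    std::vector<int> activeList;
    activeList.reserve(order.size());

    size_t next = 0;
    for (int k = K; k >= 1; --k) {
        // midpoint height of the k-th threshold slab
        const double h = (k - 0.5) * dh;
        // activate voxels with v >= h, merging with active neighbours
        while (next < order.size() && v[order[next]] >= h) {
            const int i = order[next++];
            parent[i] = i;
            csize[i] = 1;
            active[i] = 1;
            activeList.push_back(i);
            const int z = i / (nx * ny);
            const int y = (i - z * nx * ny) / nx;
            const int x = i - z * nx * ny - y * nx;
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!dx && !dy && !dz) continue;
                        const int xx = x + dx, yy = y + dy, zz = z + dz;
                        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                            zz < 0 || zz >= nz) continue;
                        const int j = xx + yy * nx + zz * nx * ny;
                        if (!active[j]) continue;
                        int ri = uf_find(parent, i), rj = uf_find(parent, j);
                        if (ri != rj) {
                            if (csize[ri] < csize[rj]) std::swap(ri, rj);
                            parent[rj] = ri;
                            csize[ri] += csize[rj];
                        }
                    }
        }
        const double hterm = std::pow(h, H) * dh;
        for (int i : activeList)
            out[i] += std::pow((double)csize[uf_find(parent, i)], E) * hterm;
    }
}

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims,
                       double E, double H, double dh) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int n = nx * ny * nz;
    if (map.size() != n) stop("map length does not match dims");
    std::vector<double> pos(n), neg(n), opos(n, 0.0), oneg(n, 0.0);
    for (int i = 0; i < n; ++i) {
        const double x = NumericVector::is_na(map[i]) ? 0.0 : map[i];
        pos[i] = x > 0 ? x : 0.0;
        neg[i] = x < 0 ? -x : 0.0;
    }
    tfce_one_sign(pos, nx, ny, nz, E, H, dh, opos);
    tfce_one_sign(neg, nx, ny, nz, E, H, dh, oneg);
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = opos[i] - oneg[i];
    return out;
}
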