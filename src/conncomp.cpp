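#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labelling of a boolean volume (BFS, label >= 1).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t n = (size_t)nx * ny * nz;
    IntegerVector lab(n); // zero-initialised
    std::vector<size_t> queue;
    int next = 0;
    for (size_t s = 0; s < n; s++) {
        if (!mask[s] || lab[s] != 0) continue;
        next++;
        lab[s] = next;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            size_t cur = queue.back();
            queue.pop_back();
            int i = cur % nx;
            int j = (cur / nx) % ny;
            int k = cur / ((size_t)nx * ny);
            const int di[6] = {-1, 1, 0, 0, 0, 0};
            const int dj[6] = {0, 0, -1, 1, 0, 0};
            const int dk[6] = {0, 0, 0, 0, -1, 1};
            for (int t = 0; t < 6; t++) {
                int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                    continue;
                size_t q = (size_t)ii + (size_t)nx * jj + (size_t)nx * ny * kk;
                if (mask[q] && lab[q] == 0) {
                    lab[q] = next;
                    queue.push_back(q);
                }
            }
        }
    }
    return lab;
}
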