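#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact multilevel Otsu by dynamic programming on a histogram: partition the
// bins into K contiguous classes minimising total within-class weighted sum
// of squares (equivalent to maximising between-class variance). Returns the
// 1-based start bin of each class.
// [[Rcpp::export]]
IntegerVector cpp_multiotsu(NumericVector counts, NumericVector centers, int K) {
    int B = counts.size();
    std::vector<double> W(B + 1, 0.0), M(B + 1, 0.0), S(B + 1, 0.0);
    for (int b = 0; b < B; b++) {
        W[b+1] = W[b] + counts[b];
        M[b+1] = M[b] + counts[b] * centers[b];
        S[b+1] = S[b] + counts[b] * centers[b] * centers[b];
    }
    const double INF = std::numeric_limits<double>::infinity();
    // cost of one class spanning bins [i, j] (0-based, inclusive)
    auto cost = [&](int i, int j) -> double {
        double w = W[j+1] - W[i];
        if (w <= 0) return 0.0;
        double m = M[j+1] - M[i];
        double s = S[j+1] - S[i];
        return s - m * m / w;
    };
    std::vector<double> prev(B, INF), cur(B, INF);
    std::vector<std::vector<int>> arg(K, std::vector<int>(B, 0));
    for (int j = 0; j < B; j++) prev[j] = cost(0, j);
    for (int k = 1; k < K; k++) {
        std::fill(cur.begin(), cur.end(), INF);
        for (int j = k; j < B; j++) {
            double best = INF;
            int bi = k;
            for (int i = k; i <= j; i++) {
                if (prev[i-1] == INF) continue;
                double c = prev[i-1] + cost(i, j);
                if (c < best) { best = c; bi = i; }
            }
            cur[j] = best;
            arg[k][j] = bi;
        }
        prev.swap(cur);
    }
    IntegerVector starts(K);
    int j = B - 1;
    for (int k = K - 1; k >= 1; k--) {
        int i = arg[k][j];
        starts[k] = i + 1; // 1-based
        j = i - 1;
    }
    starts[0] = 1;
    return starts;
}
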