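#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gaps, Gotoh three-state
// DP. A gap of length k costs gap_open + k * gap_extend. Traceback ties are
// broken deterministically: diagonal (M) over gap-in-b (Ix) over gap-in-a
// (Iy), so repeated calls give identical alignments.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string a, std::string b,
                      double match = 1.0, double mismatch = -1.0,
                      double gap_open = 4.0, double gap_extend = 1.0) {
    int n = a.size(), m = b.size();
    if (n == 0 || m == 0) stop("sequences must be non-empty");

    std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
    std::vector<std::vector<double>> Ix(n + 1, std::vector<double>(m + 1, NEG_INF));
    std::vector<std::vector<double>> Iy(n + 1, std::vector<double>(m + 1, NEG_INF));

    M[0][0] = 0.0;
    for (int i = 1; i <= n; ++i) Ix[i][0] = -(gap_open + i * gap_extend);
    for (int j = 1; j <= m; ++j) Iy[0][j] = -(gap_open + j * gap_extend);

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double best = std::max(M[i - 1][j - 1],
                                   std::max(Ix[i - 1][j - 1], Iy[i - 1][j - 1]));
            M[i][j] = best + s;
            Ix[i][j] = std::max(M[i - 1][j] - (gap_open + gap_extend),
                                Ix[i - 1][j] - gap_extend);
            Iy[i][j] = std::max(M[i][j - 1] - (gap_open + gap_extend),
                                Iy[i][j - 1] - gap_extend);
        }
    }

    // traceback from the best end state
    int state; // 0 = M, 1 = Ix (gap in b), 2 = Iy (gap in a)
    double score = M[n][m];
    state = 0;
    if (Ix[n][m] > score) { score = Ix[n][m]; state = 1; }
    if (Iy[n][m] > score) { score = Iy[n][m]; state = 2; }

    std::string out_a, out_b;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (state == 0) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double need = M[i][j] - s;
            out_a.push_back(a[i - 1]);
            out_b.push_back(b[j - 1]);
            --i; --j;
            if (i == 0 && j == 0) break;
            if (M[i][j] == need) state = 0;
            else if (Ix[i][j] == need) state = 1;
            else state = 2;
        } else if (state == 1) {
            out_a.push_back(a[i - 1]);
            out_b.push_back('-');
            double cur = Ix[i][j];
            --i;
            if (M[i][j] - (gap_open + gap_extend) == cur) state = 0;
            else state = 1;
        } else {
            out_a.push_back('-');
            out_b.push_back(b[j - 1]);
            double cur = Iy[i][j];
            --j;
            if (M[i][j] - (gap_open + gap_extend) == cur) state = 0;
            else state = 2;
        }
    }
    std::reverse(out_a.begin(), out_a.end());
    std::reverse(out_b.begin(), out_b.end());

    int n_sub = 0, n_gap = 0;
    for (size_t k = 0; k < out_a.size(); ++k) {
        if (out_a[k] == '-' || out_b[k] == '-') ++n_gap;
        else if (out_a[k] != out_b[k]) ++n_sub;
    }
    return List::create(_["score"] = score,
                        _["substitutions"] = n_sub,
                        _["gap_columns"] = n_gap,
                        _["aligned_a"] = out_a,
                        _["aligned_b"] = out_b);
}
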