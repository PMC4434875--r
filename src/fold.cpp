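#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) with a minimum hairpin
// loop constraint. Weights: G:C = 3, A:T(U) = 2, G:T(U) wobble = 1.
// Deterministic traceback: at (i, j) a pair (k, j) with the smallest k
// achieving the optimum is taken before leaving j unpaired is considered,
// giving a single reproducible structure among co-optimal ones.

static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
    return 0;
}

// [[Rcpp::export(name = ".fold_bpmax")]]
List fold_bpmax(std::string seq, int min_loop) {
    int n = seq.size();
    IntegerVector partner(n, 0);
    if (n == 0) {
        return List::create(_["partner"] = partner, _["score"] = 0);
    }
    // M[i][j], 0-based, j >= i; stored as vector of rows
    std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = M[i][j - 1];  // j unpaired
            for (int k = i; k <= j - min_loop - 1; ++k) {
                int w = pair_weight(seq[k], seq[j]);
                if (w == 0) continue;
                int sc = w;
                if (k > i) sc += M[i][k - 1];
                if (k + 1 <= j - 1) sc += M[k + 1][j - 1];
                if (sc > best) best = sc;
            }
            M[i][j] = best;
        }
    }
    // iterative traceback
    std::vector< std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i <= min_loop) continue;
        int target = M[i][j];
        bool paired = false;
        for (int k = i; k <= j - min_loop - 1; ++k) {
            int w = pair_weight(seq[k], seq[j]);
            if (w == 0) continue;
            int sc = w;
            if (k > i) sc += M[i][k - 1];
            if (k + 1 <= j - 1) sc += M[k + 1][j - 1];
            if (sc == target) {
                partner[k] = j + 1;  // 1-based
                partner[j] = k + 1;
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i, j - 1));
    }
    return List::create(_["partner"] = partner, _["score"] = M[0][n - 1]);
}

// Penalty matrix lookup used by the target scanner: codes A=0, C=1, G=2, T=3.
// Returns a 4x4 matrix of penalties, miRNA base in rows, target base in cols.
// [[Rcpp::export(name = ".target_penalty_matrix")]]
NumericMatrix target_penalty_matrix() {
    NumericMatrix p(4, 4);
    std::string b = "ACGT";
    for (int i = 0; i < 4; ++i) for (int j = 0; j < 4; ++j) {
        int w = pair_weight(b[i], b[j]);
        if (w >= 2) p(i, j) = 0.0;        // Watson-Crick
        else if (w == 1) p(i, j) = 0.5;   // G:U wobble
        else p(i, j) = 1.0;               // mismatch
    }
    return p;
}
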