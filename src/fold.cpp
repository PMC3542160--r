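#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Maximum base-pair (Nussinov-style) folding with a minimum hairpin loop of
// 3 nt and A-U / G-C / G-U pairs. Deterministic traceback: at every interval
// the 5'-most pairing partner achieving the optimum is chosen, and pairing
// is preferred over leaving the 3' base unpaired when both tie.

static inline bool can_pair(char a, char b) {
    switch (a) {
    case 'A': return b == 'U';
    case 'U': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'U';
    case 'C': return b == 'G';
    default:  return false;
    }
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop = 3) {
    int n = seq.size();
    for (int i = 0; i < n; ++i) {
        char c = seq[i];
        if (c == 'T') { seq[i] = 'U'; c = 'U'; }
        if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
            stop("invalid base '%s' at position %d (alphabet ACGU/T)",
                 std::string(1, c).c_str(), i + 1);
    }
    std::vector<int> M((size_t)n * n, 0);
    auto at = [n](int i, int j) { return (size_t)i * n + j; };
    // M[i][j]: max pairs on seq[i..j], 0-based
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = M[at(i, j - 1)];               // j unpaired
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (!can_pair(seq[k], seq[j])) continue;
                int s = 1 + (k > i ? M[at(i, k - 1)] : 0)
                          + (k + 1 <= j - 1 ? M[at(k + 1, j - 1)] : 0);
                if (s > best) best = s;
            }
            M[at(i, j)] = best;
        }
    }
    IntegerVector partner(n, 0);   // 1-based partner, 0 = unpaired
    std::string db(n, '.');
    // iterative traceback over a stack of intervals
    std::vector<std::pair<int, int>> stack;
    if (n > 0) stack.push_back({0, n - 1});
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < min_loop + 1) continue;
        int opt = M[at(i, j)];
        int chosen = -1;
        for (int k = i; k <= j - min_loop - 1; ++k) {   // 5'-most first
            if (!can_pair(seq[k], seq[j])) continue;
            int s = 1 + (k > i ? M[at(i, k - 1)] : 0)
                      + (k + 1 <= j - 1 ? M[at(k + 1, j - 1)] : 0);
            if (s == opt) { chosen = k; break; }
        }
        if (chosen >= 0) {
            partner[chosen] = j + 1;
            partner[j] = chosen + 1;
            db[chosen] = '(';
            db[j] = ')';
            if (chosen > i) stack.push_back({i, chosen - 1});
            if (chosen + 1 <= j - 1) stack.push_back({chosen + 1, j - 1});
        } else {
            stack.push_back({i, j - 1});
        }
    }
    int paired = 0;
    for (int i = 0; i < n; ++i) if (partner[i] > 0) ++paired;
    return List::create(_["structure"] = db,
                        _["partner"] = partner,
                        _["n_paired"] = paired);
}
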