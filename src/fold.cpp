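#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// Maximum base-pairing (Nussinov-style) folding of a single sequence into
// a nested, pseudoknot-free structure. Pairs: Watson-Crick plus G.U wobble.
// Minimum hairpin loop of 3 unpaired bases (i,j can pair only if j-i > 3).
// Traceback is deterministic: at equal score, pairing the opening index
// with the smallest admissible partner wins over leaving it unpaired.

static inline int rc(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
}

static inline bool can_pair(int a, int b) {
    if (a < 0 || b < 0) return false;
    if (a > b) std::swap(a, b);
    return (a == 0 && b == 3) ||   // A-U
           (a == 1 && b == 2) ||   // C-G
           (a == 2 && b == 3);     // G-U
}

// [[Rcpp::export(name = ".cpp_fold_maxpair")]]
IntegerVector cpp_fold_maxpair(std::string seq) {
    const int n = (int) seq.size();
    std::vector<int> code(n);
    for (int i = 0; i < n; ++i) code[i] = rc(seq[i]);
    IntegerVector partner(n, -1L);
    if (n < 5) return partner;
    // M[i][j]: max pairs in seq[i..j]
    std::vector<int> M((size_t) n * n, 0);
    auto at = [&](int i, int j) -> int& { return M[(size_t) i * n + j]; };
    for (int len = 5; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = at(i + 1, j); // i unpaired
            for (int k = i + 4; k <= j; ++k) {
                if (!can_pair(code[i], code[k])) continue;
                int inside = (k - i > 4) ? at(i + 1, k - 1) : 0;
                int outside = (k < j) ? at(k + 1, j) : 0;
                int s = inside + outside + 1;
                if (s > best) best = s;
            }
            at(i, j) = best;
        }
    }
    // iterative traceback, pairing preferred at ties, smallest k first
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < 4) continue;
        int target = at(i, j);
        bool paired = false;
        for (int k = i + 4; k <= j; ++k) {
            if (!can_pair(code[i], code[k])) continue;
            int inside = (k - i > 4) ? at(i + 1, k - 1) : 0;
            int outside = (k < j) ? at(k + 1, j) : 0;
            if (inside + outside + 1 == target) {
                partner[i] = k;
                partner[k] = i;
                if (k - i > 4) stack.push_back(std::make_pair(i + 1, k - 1));
                if (k < j) stack.push_back(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }
    return partner; // 0-based partner index, -1 if unpaired
}
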