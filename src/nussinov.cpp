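#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick + wobble pairing on the DNA alphabet (T stands for U).
static inline bool can_pair(char a, char b) {
    switch (a) {
    case 'A': return b == 'T';
    case 'T': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'T';
    case 'C': return b == 'G';
    default:  return false;
    }
}

// Maximum base-pairing (Nussinov) with a minimum hairpin loop.
// A pair (i, j) is allowed only when j - i > min_loop.
// Traceback is deterministic: at (i, j) prefer pairing i with the
// smallest j' attaining the optimum, else leave i unpaired.
// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerMatrix nussinov_pairs(std::string seq, int min_loop = 3) {
    int n = seq.size();
    if (n == 0) return IntegerMatrix(0, 2);
    std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = M[i + 1][j];  // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
                int rest  = (k < j) ? M[k + 1][j] : 0;
                int sc = 1 + inner + rest;
                if (sc > best) best = sc;
            }
            M[i][j] = best;
        }
    }
    std::vector<std::pair<int, int> > pairs;
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i <= min_loop) continue;
        int best = M[i][j];
        if (best == 0) continue;
        bool paired = false;
        for (int k = i + min_loop + 1; k <= j; ++k) {
            if (!can_pair(seq[i], seq[k])) continue;
            int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
            int rest  = (k < j) ? M[k + 1][j] : 0;
            if (1 + inner + rest == best) {
                pairs.push_back(std::make_pair(i + 1, k + 1));
                if (k - i - 1 > min_loop) stack.push_back(std::make_pair(i + 1, k - 1));
                if (k < j) stack.push_back(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }
    IntegerMatrix out(pairs.size(), 2);
    for (size_t r = 0; r < pairs.size(); ++r) {
        out(r, 0) = pairs[r].first;
        out(r, 1) = pairs[r].second;
    }
    return out;
}
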