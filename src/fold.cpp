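#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
#include <cstdint>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T/U=3, other=4 (never pairs).
static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': case 'U': return 3;
    default:  return 4;
    }
}

// Watson-Crick + wobble pairing on coded bases.
static const bool PAIRABLE[5][5] = {
    // A      C      G      T      N
    {false, false, false, true,  false},  // A
    {false, false, true,  false, false},  // C
    {false, true,  false, true,  false},  // G
    {true,  false, true,  false, false},  // T
    {false, false, false, false, false},  // N
};

// Maximum base-pairing fold (Nussinov-style DP) with a minimum hairpin-loop
// size. Ties are resolved deterministically: when position j can be paired
// without reducing the total pair count, it is paired with the 5'-most
// admissible partner.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
std::string nussinov_fold_cpp(std::string seq, int min_loop) {
    int n = (int) seq.size();
    if (n == 0) return std::string();
    std::vector<int> code((size_t) n);
    for (int i = 0; i < n; ++i) code[(size_t) i] = base_code(seq[(size_t) i]);
    // positions pairable with each j, ascending
    std::vector<std::vector<int> > partners((size_t) n);
    for (int j = 0; j < n; ++j)
        for (int k = 0; k < j - min_loop; ++k)
            if (PAIRABLE[code[(size_t) k]][code[(size_t) j]])
                partners[(size_t) j].push_back(k);
    // N[i][j] flattened; int16 suffices (pair counts <= n/2 <= 32767)
    std::vector<int16_t> N((size_t) n * (size_t) n, 0);
#define NIJ(i, j) N[(size_t) (i) * (size_t) n + (size_t) (j)]
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            int best = NIJ(i, j - 1);
            const std::vector<int> &pk = partners[(size_t) j];
            for (size_t t = 0; t < pk.size(); ++t) {
                int k = pk[t];
                if (k < i) continue;
                int sc = 1 + (k > i ? NIJ(i, k - 1) : 0)
                           + (k + 1 <= j - 1 ? NIJ(k + 1, j - 1) : 0);
                if (sc > best) best = sc;
            }
            NIJ(i, j) = (int16_t) best;
        }
    }
    std::string db((size_t) n, '.');
    std::stack<std::pair<int, int> > todo;
    todo.push(std::make_pair(0, n - 1));
    while (!todo.empty()) {
        std::pair<int, int> seg = todo.top();
        todo.pop();
        int i = seg.first, j = seg.second;
        if (i >= j || j - i <= min_loop) continue;
        int target = NIJ(i, j);
        if (target == 0) continue;
        bool paired = false;
        const std::vector<int> &pk = partners[(size_t) j];
        for (size_t t = 0; t < pk.size(); ++t) {
            int k = pk[t];
            if (k < i) continue;
            int sc = 1 + (k > i ? NIJ(i, k - 1) : 0)
                       + (k + 1 <= j - 1 ? NIJ(k + 1, j - 1) : 0);
            if (sc == target) {
                db[(size_t) k] = '(';
                db[(size_t) j] = ')';
                if (k > i) todo.push(std::make_pair(i, k - 1));
                if (k + 1 <= j - 1) todo.push(std::make_pair(k + 1, j - 1));
                paired = true;
                break;
            }
        }
        if (!paired) todo.push(std::make_pair(i, j - 1));
    }
#undef NIJ
    return db;
}

// Ungapped +1/-1 sliding-window score of a query against one subject strand;
// returns the score at every admissible offset (1 value per start position).
// [[Rcpp::export(name = ".ungapped_scan_cpp")]]
IntegerVector ungapped_scan_cpp(std::string subject, std::string query) {
    int L = (int) subject.size(), n = (int) query.size();
    if (n == 0 || n > L) return IntegerVector(0);
    IntegerVector out(L - n + 1);
    for (int s = 0; s + n <= L; ++s) {
        int sc = 0;
        for (int k = 0; k < n; ++k)
            sc += (subject[(size_t) (s + k)] == query[(size_t) k]) ? 1 : -1;
        out[s] = sc;
    }
    return out;
}
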