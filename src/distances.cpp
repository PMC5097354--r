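#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Base identity rule shared by all kernels: two positions agree only when the
// characters are equal and neither is 'N' (an N mismatches everything,
// including another N).
static inline bool base_match(char a, char b) {
    return a == b && a != 'N' && a != 'n';
}

static int hamming_one(const char* a, const char* b, int n) {
    int d = 0;
    for (int i = 0; i < n; ++i)
        if (!base_match(a[i], b[i])) ++d;
    return d;
}

// [[Rcpp::export(name = ".hamming_c")]]
IntegerVector hamming_c(CharacterVector a, CharacterVector b) {
    R_xlen_t n = a.size();
    if (b.size() != n) stop("'a' and 'b' must have the same length");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* sa = CHAR(STRING_ELT(a, i));
        const char* sb = CHAR(STRING_ELT(b, i));
        int la = (int) std::strlen(sa), lb = (int) std::strlen(sb);
        if (la != lb)
            stop("sequences must have equal length (element %d: %d vs %d)",
                 (int) i + 1, la, lb);
        out[i] = hamming_one(sa, sb, la);
    }
    return out;
}

// Banded unit-cost Levenshtein distance. Returns the exact distance when it is
// <= band, otherwise band + 1 (a "greater than band" sentinel). Full-string
// alignment: length differences are charged as indels.
static int lev_banded(const char* s, int n, const char* t, int m, int band) {
    if (n > m) { const char* tmp = s; s = t; t = tmp; int k = n; n = m; m = k; }
    if (m - n > band) return band + 1;
    const int INF = band + 1;
    std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
    int j0 = 0, j1 = std::min(m, band);
    for (int j = j0; j <= j1; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        int lo = std::max(1, i - band), hi = std::min(m, i + band);
        cur[lo - 1] = INF;
        if (lo == 1) cur[0] = (i <= band) ? i : INF;
        int row_min = INF;
        for (int j = lo; j <= hi; ++j) {
            int sub = prev[j - 1] + (base_match(s[i - 1], t[j - 1]) ? 0 : 1);
            int del = (j <= i + band - 1) ? prev[j] + 1 : INF;      // prev row, same col
            int ins = cur[j - 1] + 1;
            int v = sub;
            if (del < v) v = del;
            if (ins < v) v = ins;
            if (v > INF) v = INF;
            cur[j] = v;
            if (v < row_min) row_min = v;
        }
        if (hi < m) cur[hi + 1] = INF;
        if (row_min >= INF) return band + 1;
        std::swap(prev, cur);
    }
    return std::min(prev[m], INF);
}

// [[Rcpp::export(name = ".levenshtein_c")]]
IntegerVector levenshtein_c(CharacterVector a, CharacterVector b, int band) {
    R_xlen_t n = a.size();
    if (b.size() != n) stop("'a' and 'b' must have the same length");
    if (band < 0) stop("'band' must be >= 0");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* sa = CHAR(STRING_ELT(a, i));
        const char* sb = CHAR(STRING_ELT(b, i));
        out[i] = lev_banded(sa, (int) std::strlen(sa),
                            sb, (int) std::strlen(sb), band);
    }
    return out;
}

// Match each observed index read against the expected set within max_mismatch
// hamming distance. Codes: k > 0 -> unique match to expected[k-1];
// 0 -> none within reach; -1 -> ambiguous (two or more within reach).
// [[Rcpp::export(name = ".match_index_c")]]
IntegerVector match_index_c(CharacterVector observed, CharacterVector expected,
                            int max_mismatch) {
    R_xlen_t n = observed.size(), ne = expected.size();
    if (ne == 0) stop("'expected' must be non-empty");
    std::vector<const char*> exp_s(ne);
    int len = -1;
    for (R_xlen_t k = 0; k < ne; ++k) {
        exp_s[k] = CHAR(STRING_ELT(expected, k));
        int l = (int) std::strlen(exp_s[k]);
        if (len < 0) len = l;
        else if (l != len) stop("expected indices differ in length");
    }
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* obs = CHAR(STRING_ELT(observed, i));
        if ((int) std::strlen(obs) != len)
            stop("observed index %d has length %d, expected %d",
                 (int) i + 1, (int) std::strlen(obs), len);
        int hit = 0, nhit = 0;
        for (R_xlen_t k = 0; k < ne; ++k) {
            if (hamming_one(obs, exp_s[k], len) <= max_mismatch) {
                ++nhit;
                hit = (int) k + 1;
                if (nhit > 1) break;
            }
        }
        out[i] = (nhit == 0) ? 0 : (nhit > 1 ? -1 : hit);
    }
    return out;
}

// Assign each read to the unique nearest reference within max_edit banded
// Levenshtein distance. Returns a 2-column matrix: column 1 the code
// (k > 0 unique best, 0 none, -1 tie at minimum), column 2 the best distance
// (max_edit + 1 when none is within reach).
// [[Rcpp::export(name = ".assign_sequence_c")]]
IntegerMatrix assign_sequence_c(CharacterVector reads, CharacterVector refs,
                                int max_edit) {
    R_xlen_t n = reads.size(), nr = refs.size();
    if (nr == 0) stop("'refs' must be non-empty");
    std::vector<const char*> ref_s(nr);
    std::vector<int> ref_l(nr);
    for (R_xlen_t k = 0; k < nr; ++k) {
        ref_s[k] = CHAR(STRING_ELT(refs, k));
        ref_l[k] = (int) std::strlen(ref_s[k]);
    }
    IntegerMatrix out(n, 2);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* rd = CHAR(STRING_ELT(reads, i));
        int rl = (int) std::strlen(rd);
        if (rl == 0) stop("read %d is empty", (int) i + 1);
        int best = max_edit + 1, best_k = 0, nbest = 0;
        for (R_xlen_t k = 0; k < nr; ++k) {
            int d = lev_banded(rd, rl, ref_s[k], ref_l[k], max_edit);
            if (d < best) { best = d; best_k = (int) k + 1; nbest = 1; }
            else if (d == best && d <= max_edit) ++nbest;
        }
        if (best > max_edit)      { out(i, 0) = 0; }
        else if (nbest > 1)       { out(i, 0) = -1; }
        else                      { out(i, 0) = best_k; }
        out(i, 1) = best;
    }
    return out;
}
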