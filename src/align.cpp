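#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Affine-gap pairwise aligner used by the similarity-search engine and the
// long-read clustering/consensus code.
//
// Scoring convention: match/mismatch are scores (mismatch negative); gap
// penalties are positive costs, a gap of length L costs open + L * ext.
// Terminal gaps (runs touching either end of either sequence) are charged at
// term_open/term_ext; free_ends = true makes them free and computes identity
// over the aligned core only (ends-free / "overlap" alignment). 'N' never
// matches anything, including another 'N'.

static const double NEG_INF = -1e18;

static inline double subscore(char a, char b, double match, double mismatch) {
    if (a == 'N' || b == 'N') return mismatch;
    return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string q, std::string s,
                    double match, double mismatch,
                    double gap_open, double gap_ext,
                    double term_open, double term_ext,
                    bool free_ends) {
    const size_t m = q.size(), n = s.size();
    if (m == 0 || n == 0) stop("sequences must be non-empty");

    const size_t W = n + 1;
    std::vector<double> M((m + 1) * W, NEG_INF), Iq((m + 1) * W, NEG_INF),
        Is((m + 1) * W, NEG_INF);
    // traceback: predecessor state (0 = M, 1 = Iq, 2 = Is), 3 = boundary
    std::vector<unsigned char> tM((m + 1) * W, 3), tIq((m + 1) * W, 3),
        tIs((m + 1) * W, 3);

    auto lead = [&](size_t L) -> double {
        if (L == 0) return 0.0;
        return free_ends ? 0.0 : -(term_open + (double)L * term_ext);
    };

    M[0] = 0.0;
    for (size_t i = 1; i <= m; ++i) Iq[i * W] = lead(i);
    for (size_t j = 1; j <= n; ++j) Is[j] = lead(j);

    const double open_cost = gap_open + gap_ext;
    for (size_t i = 1; i <= m; ++i) {
        for (size_t j = 1; j <= n; ++j) {
            const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                         u = (i - 1) * W + j, l = i * W + (j - 1);
            // diagonal
            double best = M[d]; unsigned char bs = 0;
            if (Iq[d] > best) { best = Iq[d]; bs = 1; }
            if (Is[d] > best) { best = Is[d]; bs = 2; }
            M[c] = best + subscore(q[i - 1], s[j - 1], match, mismatch);
            tM[c] = bs;
            // gap in subject (consume query char)
            double a = M[u] - open_cost, b = Iq[u] - gap_ext,
                   e = Is[u] - open_cost;
            if (a >= b && a >= e) { Iq[c] = a; tIq[c] = 0; }
            else if (b >= e)      { Iq[c] = b; tIq[c] = 1; }
            else                  { Iq[c] = e; tIq[c] = 2; }
            // gap in query (consume subject char)
            a = M[l] - open_cost; b = Is[l] - gap_ext; e = Iq[l] - open_cost;
            if (a >= b && a >= e) { Is[c] = a; tIs[c] = 0; }
            else if (b >= e)      { Is[c] = b; tIs[c] = 2; }
            else                  { Is[c] = e; tIs[c] = 1; }
        }
    }

    // choose endpoint: (m, n) directly, or stop early and pay a terminal gap
    double best = NEG_INF;
    size_t bi = m, bj = n, trail_q = 0, trail_s = 0;
    unsigned char bstate = 0;
    auto consider = [&](size_t i, size_t j, unsigned char st, double sc,
                        size_t tq, size_t ts) {
        if (sc > best) { best = sc; bi = i; bj = j; bstate = st;
                         trail_q = tq; trail_s = ts; }
    };
    for (unsigned char st = 0; st < 3; ++st) {
        const std::vector<double>& S = (st == 0) ? M : (st == 1) ? Iq : Is;
        consider(m, n, st, S[m * W + n], 0, 0);
        for (size_t j = 0; j < n; ++j)              // trailing subject gap
            consider(m, j, st, S[m * W + j] + lead(n - j), 0, n - j);
        for (size_t i = 0; i < m; ++i)              // trailing query gap
            consider(i, n, st, S[i * W + n] + lead(m - i), m - i, 0);
    }

    // traceback into aligned strings
    std::string qa, sa;
    qa.reserve(m + n); sa.reserve(m + n);
    for (size_t k = 0; k < trail_s; ++k) { qa += '-'; sa += s[n - 1 - k]; }
    for (size_t k = 0; k < trail_q; ++k) { qa += q[m - 1 - k]; sa += '-'; }
    size_t i = bi, j = bj;
    unsigned char st = bstate;
    while (i > 0 || j > 0) {
        if (i == 0) { qa += '-'; sa += s[--j]; st = 2; continue; }
        if (j == 0) { qa += q[--i]; sa += '-'; st = 1; continue; }
        const size_t c = i * W + j;
        if (st == 0)      { qa += q[i - 1]; sa += s[j - 1]; st = tM[c]; --i; --j; }
        else if (st == 1) { qa += q[i - 1]; sa += '-'; st = tIq[c]; --i; }
        else              { qa += '-'; sa += s[j - 1]; st = tIs[c]; --j; }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());

    const size_t L = qa.size();
    // core = first..last column where both sequences contribute a residue
    size_t core_lo = L, core_hi = 0;
    for (size_t k = 0; k < L; ++k)
        if (qa[k] != '-' && sa[k] != '-') {
            if (core_lo == L) core_lo = k;
            core_hi = k + 1;
        }
    size_t lo = free_ends ? core_lo : 0, hi = free_ends ? core_hi : L;
    if (core_lo == L) { lo = 0; hi = free_ends ? 0 : L; }  // no aligned pair

    long matches = 0, mismatches = 0, gap_opens = 0, columns = 0;
    bool in_gap_q = false, in_gap_s = false;
    size_t q_before = 0, s_before = 0, q_in = 0, s_in = 0;
    for (size_t k = 0; k < L; ++k) {
        const bool qc = qa[k] != '-', sc = sa[k] != '-';
        if (k < lo) { if (qc) ++q_before; if (sc) ++s_before; continue; }
        if (k >= hi) continue;
        ++columns;
        if (qc) ++q_in;
        if (sc) ++s_in;
        if (qc && sc) {
            in_gap_q = in_gap_s = false;
            if (qa[k] == sa[k] && qa[k] != 'N') ++matches; else ++mismatches;
        } else if (!qc) {
            if (!in_gap_q) { ++gap_opens; in_gap_q = true; }
            in_gap_s = false;
        } else {
            if (!in_gap_s) { ++gap_opens; in_gap_s = true; }
            in_gap_q = false;
        }
    }
    const double identity =
        (columns > 0) ? 100.0 * (double)matches / (double)columns : 0.0;

    return List::create(
        _["score"] = best,
        _["identity"] = identity,
        _["matches"] = (double)matches,
        _["mismatches"] = (double)mismatches,
        _["gap_opens"] = (double)gap_opens,
        _["columns"] = (double)columns,
        _["query_start"] = (double)q_before,
        _["query_end"] = (double)(q_before + q_in),
        _["subject_start"] = (double)s_before,
        _["subject_end"] = (double)(s_before + s_in),
        _["aligned_query"] = qa,
        _["aligned_subject"] = sa);
}

// Hamming distance restricted to equal-length sequences; -1 when lengths
// differ (used by the abundance-skew denoiser, which only absorbs
// substitution-type errors).
// [[Rcpp::export(name = ".hamming_cpp")]]
int hamming_cpp(std::string a, std::string b) {
    if (a.size() != b.size()) return -1;
    int d = 0;
    for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++d;
    return d;
}

// Does any k-mer of the query occur in the subject? Seed filter emulating
// word-size-based search sensitivity (word 28 ~ fast mode, 11 ~ sensitive).
// [[Rcpp::export(name = ".shares_kmer_cpp")]]
bool shares_kmer_cpp(std::string q, std::string s, int k) {
    if ((int)q.size() < k || (int)s.size() < k) return false;
    std::vector<std::string> words;
    words.reserve(s.size() - k + 1);
    for (size_t j = 0; j + k <= s.size(); ++j) words.push_back(s.substr(j, k));
    std::sort(words.begin(), words.end());
    for (size_t i = 0; i + k <= q.size(); ++i)
        if (std::binary_search(words.begin(), words.end(), q.substr(i, k)))
            return true;
    return false;
}
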