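#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Greedy left-to-right non-overlapping occurrence starts (0-based) of `kmer`
// in `seq`. This is the "repeat times" counting rule used throughout: an
// occurrence is counted only if it starts at or after the end of the
// previously counted one.
static std::vector<int> greedy_starts(const std::string& seq, const std::string& kmer) {
    std::vector<int> out;
    const size_t k = kmer.size();
    if (k == 0 || seq.size() < k) return out;
    size_t pos = 0;
    while ((pos = seq.find(kmer, pos)) != std::string::npos) {
        out.push_back((int)pos);
        pos += k;
    }
    return out;
}

// Enumerate every distinct N-free k-substring for k in [kmin, kmax] with its
// greedy non-overlapping repeat count. Returns parallel vectors.
// [[Rcpp::export]]
List cpp_enumerate_kmers(std::string seq, int kmin, int kmax, int min_count) {
    const int L = (int)seq.size();
    std::vector<std::string> kmers;
    std::vector<int> ks, counts;

    // distance to next N at or after each position (suffix scan) so a kmer
    // overlapping any N is skipped in O(1)
    std::vector<int> next_n(L + 1, L);
    for (int i = L - 1; i >= 0; --i)
        next_n[i] = (seq[i] == 'N') ? i : next_n[i + 1];

    for (int k = kmin; k <= kmax && k <= L; ++k) {
        std::unordered_map<std::string, std::pair<int,int>> tab; // kmer -> (count, last_end)
        tab.reserve(L);
        for (int i = 0; i + k <= L; ++i) {
            if (next_n[i] < i + k) continue;
            std::string km = seq.substr(i, k);
            auto it = tab.find(km);
            if (it == tab.end()) {
                tab.emplace(std::move(km), std::make_pair(1, i + k));
            } else if (i >= it->second.second) {
                it->second.first += 1;
                it->second.second = i + k;
            }
        }
        for (auto& kv : tab) {
            if (kv.second.first >= min_count) {
                kmers.push_back(kv.first);
                ks.push_back(k);
                counts.push_back(kv.second.first);
            }
        }
    }
    return List::create(_["kmer"] = kmers, _["k"] = ks, _["repeat_times"] = counts);
}

// Greedy non-overlapping occurrence starts (0-based) for each kmer.
// [[Rcpp::export]]
List cpp_occurrences(std::string seq, CharacterVector kmers) {
    List out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i)
        out[i] = wrap(greedy_starts(seq, as<std::string>(kmers[i])));
    return out;
}

// Number of counted occurrences of the shorter kmer lying entirely inside
// counted occurrences of the longer kmer (both greedy non-overlapping sets,
// both sorted ascending). Two-pointer sweep.
static int contained_count(const std::vector<int>& short_starts, int ks,
                           const std::vector<int>& long_starts, int kl) {
    int n = 0;
    size_t j = 0;
    for (int t : short_starts) {
        while (j < long_starts.size() && long_starts[j] + kl < t + ks) ++j;
        if (j == long_starts.size()) break;
        if (long_starts[j] <= t && t + ks <= long_starts[j] + kl) ++n;
    }
    return n;
}

// Exact all-pairs kmer tournament on one window.
//
// For every unordered pair the pairwise Value is S1 - S2; when one kmer is a
// proper substring of the other, the shorter one is additionally penalised by
// (number of its counted occurrences lying inside counted occurrences of the
// longer kmer) x (its length). A kmer wins a pairing iff its Value is > 0
// (Value 0 is a draw). Returns per-kmer win counts and summed pairwise Values.
//
// Implementation: all non-substring pairs are decided purely by S, so base
// win counts come from the S order; only substring-related pairs (found by
// hashing every substring of every kmer) are then corrected. Algebraically
// identical to the literal double loop.
// [[Rcpp::export]]
List cpp_tournament(std::string seq, CharacterVector kmer_in, IntegerVector S_in) {
    const int M = kmer_in.size();
    std::vector<std::string> kmers(M);
    std::vector<int> S(M), len(M);
    for (int i = 0; i < M; ++i) {
        kmers[i] = as<std::string>(kmer_in[i]);
        len[i] = (int)kmers[i].size();
        S[i] = S_in[i];
    }

    // base wins and base value sums from the S ordering
    std::vector<double> value_sum(M);
    std::vector<int> wins(M);
    {
        std::vector<int> ord(M);
        for (int i = 0; i < M; ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(), [&](int a, int b) { return S[a] < S[b]; });
        double totS = 0;
        for (int i = 0; i < M; ++i) totS += S[i];
        int i = 0;
        while (i < M) {
            int j = i;
            while (j < M && S[ord[j]] == S[ord[i]]) ++j;
            for (int t = i; t < j; ++t) wins[ord[t]] = i; // # strictly smaller S
            i = j;
        }
        for (int t = 0; t < M; ++t)
            value_sum[t] = (double)(M - 1) * S[t] - (totS - S[t]);
    }

    // index kmers for substring lookup
    std::unordered_map<std::string, int> idx;
    idx.reserve(M * 2);
    for (int i = 0; i < M; ++i) idx[kmers[i]] = i;
    int kmin = len[0], kmax = len[0];
    for (int i = 1; i < M; ++i) {
        kmin = std::min(kmin, len[i]);
        kmax = std::max(kmax, len[i]);
    }

    // occurrence sets, computed lazily (only kmers touched by a substring pair)
    std::vector<std::vector<int>> occ(M);
    std::vector<char> occ_done(M, 0);
    auto get_occ = [&](int i) -> const std::vector<int>& {
        if (!occ_done[i]) {
            occ[i] = greedy_starts(seq, kmers[i]);
            occ_done[i] = 1;
        }
        return occ[i];
    };

    // correct every substring-related pair once
    for (int b = 0; b < M; ++b) {
        const int kl = len[b];
        if (kl <= kmin) continue;
        std::unordered_map<int, bool> seen; // shorter index -> handled for this b
        for (int ks = kmin; ks < kl; ++ks) {
            for (int off = 0; off + ks <= kl; ++off) {
                auto it = idx.find(kmers[b].substr(off, ks));
                if (it == idx.end()) continue;
                int a = it->second;
                if (seen.count(a)) continue;
                seen[a] = true;
                int pen = contained_count(get_occ(a), ks, get_occ(b), kl) * ks;
                int v0 = S[a] - S[b];           // outcome already tallied
                int v1 = v0 - pen;              // literal penalised Value
                if (v0 != v1) {
                    if (v0 > 0) wins[a] -= 1; else if (v0 < 0) wins[b] -= 1;
                    if (v1 > 0) wins[a] += 1; else if (v1 < 0) wins[b] += 1;
                    value_sum[a] += (v1 - v0);
                    value_sum[b] -= (v1 - v0);
                }
            }
        }
    }

    return List::create(_["win_times"] = wrap(wins), _["value_sum"] = wrap(value_sum));
}
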