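// Exact seed-and-extend block matching between two sequences.
// Seeds are k-mers (2-bit encoded, k <= 32) hashed over the target;
// each query k-mer hit is extended to a maximal exact match, with a
// per-diagonal high-water mark so a block is reported once.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// [[Rcpp::export(name = ".exactMatchBlocks")]]
DataFrame exact_match_blocks(std::string query, std::string target,
                             int k = 32, int min_len = 50,
                             int max_hits = 64) {
    std::vector<int> qs, qe, ts, te;
    long long qn = (long long)query.size(), tn = (long long)target.size();
    if (k < 4 || k > 32) stop("k must be in [4, 32]");
    if (qn >= k && tn >= k) {
        uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        std::unordered_map<uint64_t, std::vector<int> > index;
        index.reserve((size_t)tn);
        uint64_t kmer = 0; int valid = 0;
        for (long long i = 0; i < tn; ++i) {
            int c = code(target[(size_t)i]);
            if (c < 0) { valid = 0; kmer = 0; continue; }
            kmer = ((kmer << 2) | (uint64_t)c) & mask;
            if (++valid >= k) {
                std::vector<int> &v = index[kmer];
                if ((int)v.size() < max_hits)
                    v.push_back((int)(i - k + 1));
            }
        }
        std::unordered_map<long long, long long> diagEnd;
        kmer = 0; valid = 0;
        for (long long i = 0; i < qn; ++i) {
            int c = code(query[(size_t)i]);
            if (c < 0) { valid = 0; kmer = 0; continue; }
            kmer = ((kmer << 2) | (uint64_t)c) & mask;
            if (++valid < k) continue;
            long long qpos = i - k + 1;
            std::unordered_map<uint64_t, std::vector<int> >::iterator it =
                index.find(kmer);
            if (it == index.end()) continue;
            for (size_t h = 0; h < it->second.size(); ++h) {
                long long tpos = it->second[h];
                long long d = qpos - tpos;
                std::unordered_map<long long, long long>::iterator de =
                    diagEnd.find(d);
                if (de != diagEnd.end() && qpos <= de->second) continue;
                long long ql = qpos, tl = tpos;
                while (ql > 0 && tl > 0 &&
                       query[(size_t)(ql - 1)] == target[(size_t)(tl - 1)] &&
                       code(query[(size_t)(ql - 1)]) >= 0) { --ql; --tl; }
                long long qr = qpos + k - 1, tr = tpos + k - 1;
                while (qr + 1 < qn && tr + 1 < tn &&
                       query[(size_t)(qr + 1)] == target[(size_t)(tr + 1)] &&
                       code(query[(size_t)(qr + 1)]) >= 0) { ++qr; ++tr; }
                diagEnd[d] = qr;
                if (qr - ql + 1 >= min_len) {
                    qs.push_back((int)ql + 1);
                    qe.push_back((int)qr + 1);
                    ts.push_back((int)tl + 1);
                    te.push_back((int)tr + 1);
                }
            }
        }
    }
    int n = (int)qs.size();
    IntegerVector len(n);
    NumericVector ident(n, 1.0);
    for (int i = 0; i < n; ++i) len[i] = qe[i] - qs[i] + 1;
    return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                             _["tstart"] = ts, _["tend"] = te,
                             _["length"] = len, _["identity"] = ident,
                             _["stringsAsFactors"] = false);
}
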