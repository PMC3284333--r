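#include <Rcpp.h>
#include <algorithm>
#include "bases.h"

using namespace Rcpp;

// Seed-and-extend, ungapped, unique-best read placement against a small
// reference. Seeds are exact k-mers at non-overlapping offsets plus the
// final L-k window (pigeonhole: a placement with <= 3 mismatches over a
// 76-b read always leaves at least one of the four 20-b windows clean).
// A read is reported mapped iff exactly one placement attains the minimal
// mismatch count among placements with <= max_mm mismatches.
//
// Mismatch counting uses the 2-bit packed reference: XOR + popcount over
// 64-bit words, with N bases (reference or read) always counting as
// mismatches via a parallel N-mask.

static const uint64_t LOWBITS = 0x5555555555555555ULL;

struct RefIndex {
    std::vector<uint8_t> code;           // concatenated contig codes
    std::vector<uint64_t> pack;          // 2-bit packed bases, LSB-first
    std::vector<uint64_t> npack;         // N positions (low bit of each slot)
    std::vector<long> offset;            // start of each contig in `code`
    std::vector<long> clen;              // contig lengths
    std::vector<std::pair<uint64_t, uint32_t>> kmers; // (key, global pos)
    std::vector<uint32_t> bucket;        // prefix table into `kmers`
    long total;
    int k, pbits;
};

static inline uint64_t fetch_bits(const std::vector<uint64_t> &v, long bitpos) {
    size_t i = bitpos >> 6;
    int s = bitpos & 63;
    uint64_t w = v[i] >> s;
    if (s) w |= v[i + 1] << (64 - s);
    return w;
}

static void build_index(const CharacterVector &ref_seqs, int k, RefIndex &ix) {
    ix.k = k;
    long total = 0;
    for (int i = 0; i < ref_seqs.size(); ++i) {
        ix.offset.push_back(total);
        long n = LENGTH(STRING_ELT(ref_seqs, i));
        ix.clen.push_back(n);
        total += n;
    }
    ix.total = total;
    ix.code.resize(total);
    ix.pack.assign((size_t)(total / 32 + 3), 0);
    ix.npack.assign((size_t)(total / 32 + 3), 0);
    for (int i = 0; i < ref_seqs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(ref_seqs, i));
        for (long j = 0; j < ix.clen[i]; ++j) {
            long g = ix.offset[i] + j;
            uint8_t b = base_code(s[j]);
            ix.code[g] = b;
            uint64_t slot = (uint64_t)(b > 3 ? 0 : b);
            ix.pack[g >> 5] |= slot << (2 * (g & 31));
            if (b > 3) ix.npack[g >> 5] |= 1ULL << (2 * (g & 31));
        }
    }
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    for (int c = 0; c < (int)ix.offset.size(); ++c) {
        long beg = ix.offset[c], n = ix.clen[c];
        int run = 0;
        key = 0;
        for (long j = 0; j < n; ++j) {
            uint8_t b = ix.code[beg + j];
            if (b > 3) { run = 0; key = 0; continue; }
            key = ((key << 2) | b) & mask;
            if (++run >= k)
                ix.kmers.push_back({key, (uint32_t)(beg + j - k + 1)});
        }
    }
    std::sort(ix.kmers.begin(), ix.kmers.end());
    ix.pbits = std::min(2 * k, 20);
    size_t nb = ((size_t)1 << ix.pbits) + 1;
    ix.bucket.assign(nb, 0);
    int shift = 2 * k - ix.pbits;
    for (auto &kv : ix.kmers) ++ix.bucket[(kv.first >> shift) + 1];
    for (size_t i = 1; i < nb; ++i) ix.bucket[i] += ix.bucket[i - 1];
}

static int contig_of(const RefIndex &ix, long gpos) {
    int lo = 0, hi = (int)ix.offset.size() - 1;
    while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (ix.offset[mid] <= gpos) lo = mid; else hi = mid - 1;
    }
    return lo;
}

// mismatches of a packed read placed at global position `cand`; early exit
// above `cap`
static int count_mm(const RefIndex &ix, const std::vector<uint64_t> &rw,
                    const std::vector<uint64_t> &rn, int L, long cand, int cap) {
    int mm = 0;
    int nw = (L + 31) / 32;
    long bit = 2 * cand;
    for (int w = 0; w < nw; ++w) {
        uint64_t a = fetch_bits(ix.pack, bit + 64L * w);
        uint64_t an = fetch_bits(ix.npack, bit + 64L * w);
        uint64_t x = a ^ rw[w];
        uint64_t y = ((x >> 1) | x | an | rn[w]) & LOWBITS;
        int rem = L - 32 * w;
        if (rem < 32) y &= (1ULL << (2 * rem)) - 1;
        mm += __builtin_popcountll(y);
        if (mm > cap) return mm;
    }
    return mm;
}

// [[Rcpp::export(name = ".ps_map_reads")]]
List ps_map_reads(CharacterVector ref_seqs, CharacterVector reads,
                  int k, int max_mm, int max_hits) {
    RefIndex ix;
    build_index(ref_seqs, k, ix);
    int n = reads.size();
    IntegerVector status(n);   // 0 unmapped, 1 mapped, 2 ambiguous
    IntegerVector contig(n, NA_INTEGER), pos(n, NA_INTEGER), nm(n, NA_INTEGER);
    LogicalVector minus(n, NA_LOGICAL);
    CharacterVector oriented(n);

    std::vector<uint8_t> rc[2];
    std::vector<uint64_t> rw[2], rn[2];
    std::vector<long> seen;
    std::vector<int> offs;
    std::string obuf;
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int shift_pb = 2 * k - std::min(2 * k, 20);

    for (int i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(reads, i));
        int L = LENGTH(STRING_ELT(reads, i));
        if (L < k) { status[i] = 0; oriented[i] = NA_STRING; continue; }
        int nw = (L + 31) / 32;
        for (int st = 0; st < 2; ++st) {
            rc[st].resize(L);
            rw[st].assign(nw, 0);
            rn[st].assign(nw, 0);
        }
        for (int j = 0; j < L; ++j) rc[0][j] = base_code(s[j]);
        for (int j = 0; j < L; ++j) {
            uint8_t b = rc[0][L - 1 - j];
            rc[1][j] = (b > 3) ? 4 : (uint8_t)(3 - b);
        }
        for (int st = 0; st < 2; ++st) {
            for (int j = 0; j < L; ++j) {
                uint8_t b = rc[st][j];
                rw[st][j >> 5] |= (uint64_t)(b > 3 ? 0 : b) << (2 * (j & 31));
                if (b > 3) rn[st][j >> 5] |= 1ULL << (2 * (j & 31));
            }
        }

        offs.clear();
        for (int o = 0; o + k <= L; o += k) offs.push_back(o);
        if (offs.back() != L - k) offs.push_back(L - k);

        int best_nm = max_mm + 1, best_count = 0, best_strand = 0;
        long best_pos = -1;
        seen.clear();

        for (int strand = 0; strand < 2; ++strand) {
            const std::vector<uint8_t> &rd = rc[strand];
            for (int use_off : offs) {
                uint64_t key = 0;
                bool ok = true;
                for (int j = 0; j < k; ++j) {
                    uint8_t b = rd[use_off + j];
                    if (b > 3) { ok = false; break; }
                    key = ((key << 2) | b) & mask;
                }
                if (!ok) continue;
                uint64_t pb = key >> shift_pb;
                auto beg = ix.kmers.begin() + ix.bucket[pb];
                auto end = ix.kmers.begin() + ix.bucket[pb + 1];
                auto lo = std::lower_bound(beg, end,
                                           std::make_pair(key, (uint32_t)0));
                auto hi = std::upper_bound(lo, end,
                                           std::make_pair(key, UINT32_MAX));
                if (hi - lo > max_hits) continue;
                for (auto it = lo; it != hi; ++it) {
                    long cand = (long)it->second - use_off;
                    if (cand < 0) continue;
                    int c = contig_of(ix, cand);
                    if (cand + L > ix.offset[c] + ix.clen[c]) continue;
                    long tag = (cand << 1) | strand;
                    if (std::find(seen.begin(), seen.end(), tag) != seen.end())
                        continue;
                    seen.push_back(tag);
                    int mm = count_mm(ix, rw[strand], rn[strand], L, cand, max_mm);
                    if (mm > max_mm) continue;
                    if (mm < best_nm) {
                        best_nm = mm; best_count = 1;
                        best_pos = cand; best_strand = strand;
                    } else if (mm == best_nm) {
                        ++best_count;
                    }
                }
            }
        }

        if (best_count == 0) {
            status[i] = 0; oriented[i] = NA_STRING;
        } else if (best_count > 1) {
            status[i] = 2; oriented[i] = NA_STRING;
        } else {
            status[i] = 1;
            int c = contig_of(ix, best_pos);
            contig[i] = c + 1;
            pos[i] = (int)(best_pos - ix.offset[c]);
            nm[i] = best_nm;
            minus[i] = (best_strand == 1);
            obuf.resize(L);
            const std::vector<uint8_t> &rd = rc[best_strand];
            for (int j = 0; j < L; ++j) obuf[j] = code_base(rd[j]);
            oriented[i] = Rf_mkCharLen(obuf.data(), L);
        }
    }
    return List::create(_["status"] = status, _["contig"] = contig,
                        _["pos"] = pos, _["minus"] = minus, _["nm"] = nm,
                        _["seq"] = oriented);
}
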