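#include <Rcpp.h>
#include <map>
#include <tuple>
#include "bases.h"

using namespace Rcpp;

// Per-position allele counting from reference-oriented aligned reads.
// CIGARs: NA/empty means fully-matched (ungapped internal mapper); otherwise
// M/=/X consume both, I consumes read (recorded anchored after the previous
// reference base), D consumes reference (recorded at its first deleted base),
// S consumes read, N consumes reference.
// [[Rcpp::export(name = ".ps_pileup")]]
List ps_pileup(CharacterVector ref_seqs, IntegerVector contig,
               IntegerVector pos, CharacterVector seq, CharacterVector cigar) {
    int nc = ref_seqs.size();
    std::vector<long> clen(nc);
    List counts(nc);
    std::vector<int *> cptr(nc);
    for (int c = 0; c < nc; ++c) {
        clen[c] = LENGTH(STRING_ELT(ref_seqs, c));
        IntegerMatrix m(5, (int)clen[c]);
        counts[c] = m;
        cptr[c] = INTEGER(m);
    }

    std::map<std::tuple<int, long, std::string>, int> ins;
    std::map<std::tuple<int, long, int>, int> del;

    int n = contig.size();
    for (int i = 0; i < n; ++i) {
        int c = contig[i] - 1;
        if (c < 0 || c >= nc) stop("alignment %d: contig index out of range", i + 1);
        const char *s = CHAR(STRING_ELT(seq, i));
        int L = LENGTH(STRING_ELT(seq, i));
        long rp = pos[i];
        int *cnt = cptr[c];
        bool plain = (cigar.size() == 0) || (STRING_ELT(cigar, i) == NA_STRING);
        std::string cg = plain ? "" : std::string(CHAR(STRING_ELT(cigar, i)));
        if (!plain && (cg.empty() || cg == "*")) plain = true;

        if (plain) {
            if (rp < 0 || rp + L > clen[c])
                stop("alignment %d extends beyond contig end", i + 1);
            for (int j = 0; j < L; ++j)
                ++cnt[5 * (rp + j) + base_code(s[j])];
            continue;
        }

        int qp = 0;
        size_t ci = 0;
        while (ci < cg.size()) {
            long len = 0;
            while (ci < cg.size() && isdigit(cg[ci]))
                len = len * 10 + (cg[ci++] - '0');
            if (ci >= cg.size()) stop("alignment %d: malformed CIGAR '%s'", i + 1, cg.c_str());
            char op = cg[ci++];
            switch (op) {
            case 'M': case '=': case 'X':
                if (rp < 0 || rp + len > clen[c] || qp + len > L)
                    stop("alignment %d extends beyond contig end", i + 1);
                for (long j = 0; j < len; ++j)
                    ++cnt[5 * (rp + j) + base_code(s[qp + j])];
                rp += len; qp += len;
                break;
            case 'I': {
                if (qp + len > L) stop("alignment %d: CIGAR overruns read", i + 1);
                std::string inserted(s + qp, s + qp + len);
                ++ins[{c, rp - 1, inserted}];
                qp += len;
                break;
            }
            case 'D':
                if (rp + len > clen[c])
                    stop("alignment %d extends beyond contig end", i + 1);
                ++del[{c, rp, (int)len}];
                rp += len;
                break;
            case 'S': qp += len; break;
            case 'N': rp += len; break;
            case 'H': case 'P': break;
            default:
                stop("alignment %d: unsupported CIGAR op '%c'", i + 1, op);
            }
        }
    }

    int ni = (int)ins.size(), nd = (int)del.size();
    IntegerVector ic(ni), icount(ni);
    NumericVector ipos(ni);
    CharacterVector iseq(ni);
    int j = 0;
    for (auto &kv : ins) {
        ic[j] = std::get<0>(kv.first) + 1;
        ipos[j] = (double)std::get<1>(kv.first);
        iseq[j] = std::get<2>(kv.first);
        icount[j] = kv.second;
        ++j;
    }
    IntegerVector dc(nd), dlen(nd), dcount(nd);
    NumericVector dpos(nd);
    j = 0;
    for (auto &kv : del) {
        dc[j] = std::get<0>(kv.first) + 1;
        dpos[j] = (double)std::get<1>(kv.first);
        dlen[j] = std::get<2>(kv.first);
        dcount[j] = kv.second;
        ++j;
    }

    return List::create(
        _["counts"] = counts,
        _["ins"] = DataFrame::create(_["contig"] = ic, _["pos"] = ipos,
                                     _["seq"] = iseq, _["count"] = icount,
                                     _["stringsAsFactors"] = false),
        _["del"] = DataFrame::create(_["contig"] = dc, _["pos"] = dpos,
                                     _["len"] = dlen, _["count"] = dcount));
}
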