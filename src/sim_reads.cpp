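#include <Rcpp.h>
#include "bases.h"

using namespace Rcpp;

// Draw `k` distinct positions in [0, len) using R's RNG.
// Binomial count + uniform distinct positions == i.i.d. Bernoulli per base.
static void draw_positions(int k, int len, std::vector<int> &out) {
    out.clear();
    while ((int)out.size() < k) {
        int p = (int)(unif_rand() * len);
        if (p >= len) p = len - 1;
        bool dup = false;
        for (int q : out) if (q == p) { dup = true; break; }
        if (!dup) out.push_back(p);
    }
}

static void inject_errors(std::string &read, double error_rate, double n_rate,
                          std::vector<int> &scratch) {
    int L = (int)read.size();
    if (error_rate > 0) {
        int k = (int)R::rbinom((double)L, error_rate);
        draw_positions(k, L, scratch);
        for (int p : scratch) {
            uint8_t b = base_code(read[p]);
            if (b < 4) {
                uint8_t nb = (uint8_t)((b + 1 + (int)(unif_rand() * 3)) % 4);
                read[p] = code_base(nb);
            }
        }
    }
    if (n_rate > 0) {
        int k = (int)R::rbinom((double)L, n_rate);
        draw_positions(k, L, scratch);
        for (int p : scratch) read[p] = 'N';
    }
}

// Simulate paired (or single) reads from a pool of haplotype genomes.
// haplotypes: list of character vectors (named contig sequences), one per isolate.
// Fragments are drawn uniformly across isolates, contigs chosen proportional to
// length, start uniform. Read names record the truth for oracle checks:
//   f<i>|h<hap>|<contig>|<start0>|<fraglen>
// [[Rcpp::export(name = ".ps_sim_reads")]]
List ps_sim_reads(List haplotypes, int n_frags, int read_len,
                  double insert_mean, double insert_sd,
                  double error_rate, double n_rate, bool paired) {
    int n_hap = haplotypes.size();
    if (n_hap < 1) stop("no haplotypes");

    // cache contig sequences and cumulative lengths per haplotype
    std::vector<std::vector<std::string>> seqs(n_hap);
    std::vector<std::vector<std::string>> cnames(n_hap);
    std::vector<std::vector<double>> cumlen(n_hap);
    for (int h = 0; h < n_hap; ++h) {
        CharacterVector g = haplotypes[h];
        CharacterVector nm = g.attr("names");
        double acc = 0;
        for (int j = 0; j < g.size(); ++j) {
            std::string s = as<std::string>(g[j]);
            acc += (double)s.size();
            seqs[h].push_back(std::move(s));
            cnames[h].push_back(as<std::string>(nm[j]));
            cumlen[h].push_back(acc);
        }
    }

    CharacterVector id(n_frags), seq1(n_frags);
    CharacterVector seq2(paired ? n_frags : 0);
    IntegerVector hap_out(n_frags), start_out(n_frags), frag_out(n_frags);
    IntegerVector contig_out(n_frags);
    std::vector<int> scratch;
    std::string r1, r2;
    char buf[256];

    for (int i = 0; i < n_frags; ++i) {
        int h = (int)(unif_rand() * n_hap);
        if (h >= n_hap) h = n_hap - 1;
        const std::vector<double> &cl = cumlen[h];
        double total = cl.back();

        int frag = read_len, cj = 0;
        long start = 0;
        for (int attempt = 0; ; ++attempt) {
            if (attempt > 1000) stop("cannot place fragment: contigs shorter than insert");
            double u = unif_rand() * total;
            cj = (int)(std::lower_bound(cl.begin(), cl.end(), u) - cl.begin());
            if (cj >= (int)cl.size()) cj = (int)cl.size() - 1;
            long clen = (long)seqs[h][cj].size();
            if (paired) {
                double f = R::rnorm(insert_mean, insert_sd);
                frag = (int)(f + 0.5);
                if (frag < read_len) frag = read_len;
            } else {
                frag = read_len;
            }
            if (clen >= frag) {
                long span = clen - frag;
                start = (long)(unif_rand() * (span + 1));
                if (start > span) start = span;
                break;
            }
        }

        const std::string &src = seqs[h][cj];
        r1.assign(src, start, read_len);
        inject_errors(r1, error_rate, n_rate, scratch);
        seq1[i] = Rf_mkCharLen(r1.data(), read_len);
        if (paired) {
            r2.resize(read_len);
            long m2 = start + frag - read_len;
            for (int j = 0; j < read_len; ++j)
                r2[j] = comp_base(src[m2 + read_len - 1 - j]);
            inject_errors(r2, error_rate, n_rate, scratch);
            seq2[i] = Rf_mkCharLen(r2.data(), read_len);
        }
        snprintf(buf, sizeof(buf), "f%d|h%d|%s|%ld|%d", i + 1, h + 1,
                 cnames[h][cj].c_str(), start, frag);
        id[i] = buf;
        hap_out[i] = h + 1;
        contig_out[i] = cj + 1;
        start_out[i] = (int)start;
        frag_out[i] = frag;
    }

    return List::create(_["id"] = id, _["seq1"] = seq1,
                        _["seq2"] = paired ? (SEXP)seq2 : R_NilValue,
                        _["hap"] = hap_out, _["contig"] = contig_out,
                        _["start"] = start_out, _["frag"] = frag_out);
}
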