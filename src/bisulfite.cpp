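#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Three-letter bisulfite alignment. Two converted search spaces share one
// coordinate frame (forward-strand 0-based starts):
//   space 1 (origin "+"): reference C->T vs read C->T
//   space 2 (origin "-"): reference G->A vs revcomp(read) with G->A, which
//                         equals revcomp(C->T read)
// Reads are single-end, ungapped; mismatches counted in converted space.

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
    }
}

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
        switch (r[i]) {
        case 'A': r[i] = 'T'; break; case 'T': r[i] = 'A'; break;
        case 'C': r[i] = 'G'; break; case 'G': r[i] = 'C'; break;
        default: break;
        }
    }
    return r;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = revcomp_str(std::string(seqs[i]));
    return out;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > KmerMap;

// k-mer hash over one converted reference copy; k <= 31 (2 bits/base)
static void index_space(const std::vector<std::string> &ref, int k, KmerMap &map) {
    for (size_t ci = 0; ci < ref.size(); ++ci) {
        const std::string &s = ref[ci];
        if ((int)s.size() < k) continue;
        uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        int valid = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int c = base_code(s[i]);
            if (c < 0) { valid = 0; key = 0; continue; }
            key = ((key << 2) | (uint64_t)c) & mask;
            if (++valid >= k)
                map[key].push_back(std::make_pair((int)ci, (int)(i - k + 1)));
        }
    }
}

static inline int count_mismatches(const std::string &ref, int start,
                                   const std::string &q, int cap) {
    int mm = 0;
    for (size_t i = 0; i < q.size(); ++i) {
        if (ref[start + i] != q[i] && ++mm > cap) return mm;
    }
    return mm;
}

struct Best {
    int mm, chrom, pos, space, n_best;
    Best() : mm(INT_MAX), chrom(-1), pos(-1), space(0), n_best(0) {}
    void offer(int m, int c, int p, int sp) {
        if (m < mm) { mm = m; chrom = c; pos = p; space = sp; n_best = 1; }
        else if (m == mm) {
            if (c != chrom || p != pos || sp != space) ++n_best;
        }
    }
};

static DataFrame best_to_frame(const std::vector<Best> &best,
                               const CharacterVector &chrom_names,
                               int max_mismatches) {
    int n = best.size();
    IntegerVector chrom_idx(n), start(n), mism(n);
    CharacterVector strand(n), status(n);
    for (int i = 0; i < n; ++i) {
        const Best &b = best[i];
        if (b.n_best == 0 || b.mm > max_mismatches) {
            chrom_idx[i] = NA_INTEGER; start[i] = NA_INTEGER; mism[i] = NA_INTEGER;
            strand[i] = NA_STRING; status[i] = "unaligned";
        } else if (b.n_best > 1) {
            chrom_idx[i] = NA_INTEGER; start[i] = NA_INTEGER; mism[i] = b.mm;
            strand[i] = NA_STRING; status[i] = "multi";
        } else {
            chrom_idx[i] = b.chrom + 1; start[i] = b.pos; mism[i] = b.mm;
            strand[i] = (b.space == 1) ? "+" : "-"; status[i] = "unique";
        }
    }
    return DataFrame::create(_["chrom_idx"] = chrom_idx, _["start"] = start,
                             _["strand"] = strand, _["mismatches"] = mism,
                             _["status"] = status,
                             _["stringsAsFactors"] = false);
}

// Seed-and-extend: exact first-k-mer seed per space, ungapped extension.
// [[Rcpp::export(name = ".cpp_align_seeded")]]
DataFrame cpp_align_seeded(CharacterVector ref_ct, CharacterVector ref_ga,
                           CharacterVector chrom_names, CharacterVector reads_ct,
                           int k, int max_mismatches) {
    std::vector<std::string> r1(ref_ct.size()), r2(ref_ga.size());
    for (int i = 0; i < ref_ct.size(); ++i) r1[i] = std::string(ref_ct[i]);
    for (int i = 0; i < ref_ga.size(); ++i) r2[i] = std::string(ref_ga[i]);
    KmerMap idx1, idx2;
    index_space(r1, k, idx1);
    index_space(r2, k, idx2);

    int n = reads_ct.size();
    std::vector<Best> best(n);
    for (int i = 0; i < n; ++i) {
        std::string q1 = std::string(reads_ct[i]);
        if ((int)q1.size() < k) continue; // too short to seed -> unaligned
        std::string q2 = revcomp_str(q1); // GA-converted reverse complement
        for (int sp = 1; sp <= 2; ++sp) {
            const std::string &q = (sp == 1) ? q1 : q2;
            const std::vector<std::string> &ref = (sp == 1) ? r1 : r2;
            KmerMap &idx = (sp == 1) ? idx1 : idx2;
            uint64_t key = 0;
            bool ok = true;
            for (int j = 0; j < k; ++j) {
                int c = base_code(q[j]);
                if (c < 0) { ok = false; break; }
                key = (key << 2) | (uint64_t)c;
            }
            if (!ok) continue;
            KmerMap::const_iterator hit = idx.find(key);
            if (hit == idx.end()) continue;
            for (size_t h = 0; h < hit->second.size(); ++h) {
                int ci = hit->second[h].first, pos = hit->second[h].second;
                if (pos + (int)q.size() > (int)ref[ci].size()) continue;
                int mm = count_mismatches(ref[ci], pos, q, max_mismatches);
                if (mm <= max_mismatches) best[i].offer(mm, ci, pos, sp);
            }
        }
    }
    return best_to_frame(best, chrom_names, max_mismatches);
}

// Exhaustive reference aligner: scores every start position of every
// chromosome in both converted spaces. Independent of the seeded path.
// [[Rcpp::export(name = ".cpp_align_scan")]]
DataFrame cpp_align_scan(CharacterVector ref_ct, CharacterVector ref_ga,
                         CharacterVector chrom_names, CharacterVector reads_ct,
                         int max_mismatches) {
    std::vector<std::string> r1(ref_ct.size()), r2(ref_ga.size());
    for (int i = 0; i < ref_ct.size(); ++i) r1[i] = std::string(ref_ct[i]);
    for (int i = 0; i < ref_ga.size(); ++i) r2[i] = std::string(ref_ga[i]);

    int n = reads_ct.size();
    std::vector<Best> best(n);
    for (int i = 0; i < n; ++i) {
        std::string q1 = std::string(reads_ct[i]);
        if (q1.empty()) continue;
        std::string q2 = revcomp_str(q1);
        int L = q1.size();
        for (int sp = 1; sp <= 2; ++sp) {
            const std::string &q = (sp == 1) ? q1 : q2;
            const std::vector<std::string> &ref = (sp == 1) ? r1 : r2;
            for (size_t ci = 0; ci < ref.size(); ++ci) {
                int last = (int)ref[ci].size() - L;
                for (int pos = 0; pos <= last; ++pos) {
                    int mm = 0;
                    const char *rp = ref[ci].c_str() + pos;
                    for (int j = 0; j < L; ++j) {
                        if (rp[j] != q[j] && ++mm > max_mismatches) break;
                    }
                    if (mm <= max_mismatches) best[i].offer(mm, (int)ci, pos, sp);
                }
            }
        }
        if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return best_to_frame(best, chrom_names, max_mismatches);
}

// Strand-aware pileup at cytosine positions. `oriented` holds each usable
// read in forward-genome orientation (minus-origin reads already
// reverse-complemented by the caller). For "+"-origin reads only genomic C
// positions are informative (C retained / T converted); for "-"-origin reads
// only genomic G positions (G retained / A converted).
// [[Rcpp::export(name = ".cpp_pileup")]]
List cpp_pileup(CharacterVector genome, IntegerVector chrom_idx,
                IntegerVector start, CharacterVector strand,
                CharacterVector oriented) {
    int nchr = genome.size();
    std::vector<std::string> chrs(nchr);
    for (int i = 0; i < nchr; ++i) chrs[i] = std::string(genome[i]);
    std::vector<IntegerVector> retp(nchr), convp(nchr), retm(nchr), convm(nchr);
    for (int i = 0; i < nchr; ++i) {
        int len = chrs[i].size();
        retp[i] = IntegerVector(len); convp[i] = IntegerVector(len);
        retm[i] = IntegerVector(len); convm[i] = IntegerVector(len);
    }
    int n = chrom_idx.size();
    for (int i = 0; i < n; ++i) {
        int ci = chrom_idx[i] - 1, s = start[i];
        std::string seq = std::string(oriented[i]);
        int L = seq.size();
        if (ci < 0 || ci >= nchr || s < 0 || s + L > (int)chrs[ci].size())
            stop("alignment overhangs chromosome end (read %d)", i + 1);
        bool plus = (strand[i] == "+");
        const std::string &g = chrs[ci];
        for (int j = 0; j < L; ++j) {
            char gb = g[s + j], rb = seq[j];
            if (plus) {
                if (gb == 'C') {
                    if (rb == 'C') ++retp[ci][s + j];
                    else if (rb == 'T') ++convp[ci][s + j];
                }
            } else {
                if (gb == 'G') {
                    if (rb == 'G') ++retm[ci][s + j];
                    else if (rb == 'A') ++convm[ci][s + j];
                }
            }
        }
    }
    List out(nchr);
    for (int i = 0; i < nchr; ++i)
        out[i] = List::create(_["ret_plus"] = retp[i], _["conv_plus"] = convp[i],
                              _["ret_minus"] = retm[i], _["conv_minus"] = convm[i]);
    return out;
}
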