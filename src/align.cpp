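#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Seed-indexed search for all placements of short reads on a set of
// reference sequences allowing at most one substitution (no indels).
// Pigeonhole: with <=1 mismatch and read length >= 14, either the first
// or the last 7-mer of the read is an exact match, so candidate positions
// are drawn from a 7-mer positional index of the reference.

static const int SEED = 7;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': case 'U': case 'u': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
    return r;
}

// positional 7-mer index of one reference sequence (plus strand)
struct SeqIndex {
    std::vector<int> head;      // 4^7 buckets, -1 = empty
    std::vector<int> nxt;       // linked list over start positions
    explicit SeqIndex(const std::string& s) {
        head.assign(1 << (2 * SEED), -1);
        int n = (int) s.size();
        nxt.assign(std::max(n, 1), -1);
        if (n < SEED) return;
        // rolling 2-bit code; restart after ambiguous bases
        int code = 0, run = 0;
        const int mask = (1 << (2 * SEED)) - 1;
        for (int i = 0; i < n; ++i) {
            int b = base_code(s[i]);
            if (b < 0) { run = 0; code = 0; continue; }
            code = ((code << 2) | b) & mask;
            if (++run >= SEED) {
                int p = i - SEED + 1;
                nxt[p] = head[code];
                head[code] = p;
            }
        }
    }
};

static inline int seed_code(const std::string& s, int from) {
    int code = 0;
    for (int i = 0; i < SEED; ++i) {
        int b = base_code(s[from + i]);
        if (b < 0) return -1;
        code = (code << 2) | b;
    }
    return code;
}

// count substitutions between pat and subject at position p, early exit > 1
static inline int count_mm(const std::string& pat, const std::string& subj,
                           int p) {
    int mm = 0;
    const int L = (int) pat.size();
    for (int i = 0; i < L; ++i) {
        char a = pat[i], b = subj[p + i];
        int ca = base_code(a), cb = base_code(b);
        if (ca != cb || ca < 0) { if (++mm > 1) return 2; }
    }
    return mm;
}

static void match_one(const std::string& pat, const std::string& subj,
                      const SeqIndex& idx, std::vector<int>& starts,
                      std::vector<int>& mms) {
    const int L = (int) pat.size();
    const int n = (int) subj.size();
    if (L < 2 * SEED || L > n) return;
    std::vector<int> cand;
    int c1 = seed_code(pat, 0);
    if (c1 >= 0)
        for (int p = idx.head[c1]; p >= 0; p = idx.nxt[p])
            if (p + L <= n) cand.push_back(p);
    int c2 = seed_code(pat, L - SEED);
    if (c2 >= 0)
        for (int p = idx.head[c2]; p >= 0; p = idx.nxt[p]) {
            int q = p - (L - SEED);
            if (q >= 0 && q + L <= n) cand.push_back(q);
        }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int p : cand) {
        int mm = count_mm(pat, subj, p);
        if (mm <= 1) { starts.push_back(p); mms.push_back(mm); }
    }
}

// [[Rcpp::export(name = ".cpp_align_mm1")]]
DataFrame cpp_align_mm1(CharacterVector reads, CharacterVector ref_names,
                        CharacterVector ref_seqs) {
    const int nref = ref_seqs.size();
    std::vector<std::string> refs(nref);
    std::vector<SeqIndex*> idx(nref);
    for (int r = 0; r < nref; ++r) {
        refs[r] = as<std::string>(ref_seqs[r]);
        idx[r] = new SeqIndex(refs[r]);
    }
    std::vector<int> out_read, out_ref, out_start, out_mm;
    std::vector<int> out_strand; // 1 = plus, 0 = minus
    for (int i = 0; i < reads.size(); ++i) {
        std::string fwd = as<std::string>(reads[i]);
        std::string rev = revcomp(fwd);
        for (int r = 0; r < nref; ++r) {
            std::vector<int> st, mm;
            match_one(fwd, refs[r], *idx[r], st, mm);
            for (size_t k = 0; k < st.size(); ++k) {
                out_read.push_back(i + 1);
                out_ref.push_back(r + 1);
                out_start.push_back(st[k] + 1); // 1-based
                out_strand.push_back(1);
                out_mm.push_back(mm[k]);
            }
            st.clear(); mm.clear();
            match_one(rev, refs[r], *idx[r], st, mm);
            for (size_t k = 0; k < st.size(); ++k) {
                out_read.push_back(i + 1);
                out_ref.push_back(r + 1);
                out_start.push_back(st[k] + 1);
                out_strand.push_back(0);
                out_mm.push_back(mm[k]);
            }
        }
    }
    for (int r = 0; r < nref; ++r) delete idx[r];
    CharacterVector chrom(out_read.size());
    CharacterVector strand(out_read.size());
    for (size_t k = 0; k < out_read.size(); ++k) {
        chrom[k] = ref_names[out_ref[k] - 1];
        strand[k] = out_strand[k] ? "+" : "-";
    }
    return DataFrame::create(
        _["read"] = wrap(out_read), _["chrom"] = chrom,
        _["start"] = wrap(out_start), _["strand"] = strand,
        _["mismatches"] = wrap(out_mm),
        _["stringsAsFactors"] = false);
}
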