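#include <Rcpp.h>
using namespace Rcpp;

// An 'N' (or any non-ACGT character normalised to N upstream) never matches
// anything, including another N.
static inline bool base_match(char a, char b) {
    return a == b && a != 'N';
}

static int hamming_raw(const char *a, const char *b, int n) {
    int d = 0;
    for (int i = 0; i < n; ++i)
        if (!base_match(a[i], b[i])) ++d;
    return d;
}

// Unit-cost Levenshtein distance (substitution/insertion/deletion all 1),
// two-row dynamic programme. Substitution cost 0 only when bases match
// under the N rule above.
static int levenshtein_raw(const char *a, int na, const char *b, int nb) {
    if (na == 0) return nb;
    if (nb == 0) return na;
    std::vector<int> prev(nb + 1), cur(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = j;
    for (int i = 1; i <= na; ++i) {
        cur[0] = i;
        for (int j = 1; j <= nb; ++j) {
            int sub = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
        }
        std::swap(prev, cur);
    }
    return prev[nb];
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
    R_xlen_t n = a.size();
    if (b.size() != n)
        stop("'a' and 'b' must have the same number of sequences");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *sa = CHAR(STRING_ELT(a, i));
        const char *sb = CHAR(STRING_ELT(b, i));
        int la = LENGTH(STRING_ELT(a, i));
        int lb = LENGTH(STRING_ELT(b, i));
        if (la != lb)
            stop("Hamming distance undefined for unequal lengths (%d vs %d at element %d)",
                 la, lb, (int)(i + 1));
        out[i] = hamming_raw(sa, sb, la);
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
    R_xlen_t n = a.size();
    if (b.size() != n)
        stop("'a' and 'b' must have the same number of sequences");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        out[i] = levenshtein_raw(CHAR(STRING_ELT(a, i)), LENGTH(STRING_ELT(a, i)),
                                 CHAR(STRING_ELT(b, i)), LENGTH(STRING_ELT(b, i)));
    }
    return out;
}

// Batch matcher for one chunk of queries against the full reference.
// metric: 0 = Hamming (pass when distance <= cutoff; length mismatch never
// passes), 1 = normalized edit ratio (pass when 1 - L/max(|a|,|b|) >= cutoff).
// Returns n_passing per query and the 1-based reference index when exactly
// one reference passes (NA otherwise).
// [[Rcpp::export]]
List cpp_match_chunk(CharacterVector queries, CharacterVector refs,
                     int metric, double cutoff) {
    R_xlen_t nq = queries.size(), nr = refs.size();
    if (nr == 0) stop("reference must be nonempty");
    IntegerVector n_passing(nq), ref_index(nq);
    for (R_xlen_t i = 0; i < nq; ++i) {
        const char *q = CHAR(STRING_ELT(queries, i));
        int lq = LENGTH(STRING_ELT(queries, i));
        int npass = 0, hit = NA_INTEGER;
        for (R_xlen_t j = 0; j < nr; ++j) {
            const char *r = CHAR(STRING_ELT(refs, j));
            int lr = LENGTH(STRING_ELT(refs, j));
            bool pass;
            if (metric == 0) {
                pass = (lq == lr) && hamming_raw(q, r, lq) <= (int)cutoff;
            } else {
                int m = std::max(lq, lr);
                double sim;
                if (m == 0) sim = 1.0;          // both empty: identical
                else sim = 1.0 - (double)levenshtein_raw(q, lq, r, lr) / m;
                pass = sim >= cutoff;
            }
            if (pass) {
                if (++npass == 1) hit = (int)(j + 1);
                else hit = NA_INTEGER;
            }
        }
        n_passing[i] = npass;
        ref_index[i] = hit;
    }
    return List::create(_["n_passing"] = n_passing, _["ref_index"] = ref_index);
}

// Greedy keep-first near-match deduplication within one key group. Molecules
// are scanned in input order; a UMI within Hamming distance <= max_mismatch
// of any already-kept UMI is attached to the first such kept molecule.
// Returns the 1-based index (within the group) of each molecule's kept
// representative; rep[i] == i+1 means molecule i is itself kept.
// [[Rcpp::export]]
IntegerVector cpp_dedup_close_group(CharacterVector umis, int max_mismatch) {
    R_xlen_t n = umis.size();
    IntegerVector rep(n);
    std::vector<int> kept;
    int len0 = n > 0 ? LENGTH(STRING_ELT(umis, 0)) : 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *u = CHAR(STRING_ELT(umis, i));
        int lu = LENGTH(STRING_ELT(umis, i));
        if (lu != len0)
            stop("ragged UMI lengths within a dedup group (%d vs %d)", lu, len0);
        int r = 0;
        for (size_t k = 0; k < kept.size(); ++k) {
            const char *v = CHAR(STRING_ELT(umis, kept[k]));
            if (hamming_raw(u, v, lu) <= max_mismatch) { r = kept[k] + 1; break; }
        }
        if (r == 0) { kept.push_back((int)i); r = (int)(i + 1); }
        rep[i] = r;
    }
    return rep;
}
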