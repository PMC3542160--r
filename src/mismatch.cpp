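#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Minimum mismatch count of each tag against a reference under ungapped
// sliding alignment. Offsets are all placements whose tag overhang past
// either reference end is at most max_overhang (overhanging bases are
// tolerated, not counted). If max_shift >= 0, the tag 5' end may only sit
// within [-max_shift, +max_shift] of the reference 5' end (the known-miRNA
// rule); max_shift < 0 allows any offset (the ncRNA screening rule).

// [[Rcpp::export(name = ".mismatch_scan_cpp")]]
IntegerVector mismatch_scan_cpp(CharacterVector tags, std::string ref,
                                int max_overhang = 2, int max_shift = -1) {
    int R = ref.size();
    int n = tags.size();
    IntegerVector out(n);
    for (int t = 0; t < n; ++t) {
        std::string tag = as<std::string>(tags[t]);
        int L = tag.size();
        int best = NA_INTEGER;
        int lo = -max_overhang, hi = R - L + max_overhang;
        if (max_shift >= 0) {
            lo = std::max(lo, -max_shift);
            hi = std::min(hi, max_shift);
        }
        for (int off = lo; off <= hi; ++off) {
            // tag position i (0-based) faces ref position off + i
            int over = std::max(0, -off) + std::max(0, off + L - R);
            if (over > max_overhang) continue;
            int mm = 0;
            for (int i = 0; i < L; ++i) {
                int r = off + i;
                if (r < 0 || r >= R) continue;
                if (tag[i] != ref[r]) ++mm;
            }
            if (best == NA_INTEGER || mm < best) best = mm;
        }
        out[t] = best;
    }
    return out;
}
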