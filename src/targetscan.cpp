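#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Plant miRNA target complementarity scoring in the Targetfinder lineage:
// mismatch 1.0, G:U wobble 0.5, gap (bulged nucleotide on either strand)
// 2.0, every penalty doubled when it falls at miRNA positions 2-13
// (5' end = position 1); at most one single-nucleotide gap per site, and
// only at interior positions (an edge bulge is not a bulge).
//
// The site is given 5'->3' on the transcript; the miRNA pairs antiparallel,
// so miRNA position i faces the (width + 1 - i)-th site base.

static inline char to_rna(char c) { return c == 'T' ? 'U' : c; }

// 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
static inline int pair_class(char m, char t) {
    m = to_rna(m); t = to_rna(t);
    if ((m == 'A' && t == 'U') || (m == 'U' && t == 'A') ||
        (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 0;
    if ((m == 'G' && t == 'U') || (m == 'U' && t == 'G')) return 1;
    return 2;
}

static inline double pos_weight(int i) { return (i >= 2 && i <= 13) ? 2.0 : 1.0; }

// score miRNA against the reversed site 'tr' (tr[0] faces miRNA position 1)
// with a bulged base removed; bulge_m: 1-based bulged miRNA position (0 =
// none), bulge_t: 1-based bulged index in tr (0 = none).
static double score_config(const std::string &mir, const std::string &tr,
                           int bulge_m, int bulge_t,
                           int *mm = NULL, int *wob = NULL) {
    double score = 0.0;
    int L = mir.size(), nmm = 0, nwob = 0;
    int ti = 0;
    for (int i = 1; i <= L; ++i) {
        if (i == bulge_m) { score += 2.0 * pos_weight(i); continue; }
        if (ti + 1 == bulge_t) { score += 2.0 * pos_weight(i); ++ti; }
        int cls = pair_class(mir[i - 1], tr[ti]);
        ++ti;
        if (cls == 1) { score += 0.5 * pos_weight(i); ++nwob; }
        else if (cls == 2) { score += 1.0 * pos_weight(i); ++nmm; }
    }
    if (mm) *mm = nmm;
    if (wob) *wob = nwob;
    return score;
}

// [[Rcpp::export(name = ".score_site_cpp")]]
List score_site_cpp(std::string mirna, std::string site) {
    int L = mirna.size(), W = site.size();
    if (W < L - 1) stop("site window shorter than miRNA length - 1");
    if (W > L + 1) stop("site window longer than miRNA length + 1");
    std::string tr(site.rbegin(), site.rend());
    double best = R_PosInf;
    int best_mm = 0, best_wob = 0, best_gap = 0;
    std::string best_side = "none";
    int mm, wob;
    if (W == L) {
        best = score_config(mirna, tr, 0, 0, &best_mm, &best_wob);
    } else if (W == L + 1) {
        for (int b = 2; b <= W - 1; ++b) {
            double s = score_config(mirna, tr, 0, b, &mm, &wob);
            if (s < best) { best = s; best_mm = mm; best_wob = wob;
                            best_gap = 1; best_side = "target"; }
        }
    } else {                                   // W == L - 1, bulged miRNA nt
        for (int b = 2; b <= L - 1; ++b) {
            double s = score_config(mirna, tr, b, 0, &mm, &wob);
            if (s < best) { best = s; best_mm = mm; best_wob = wob;
                            best_gap = 1; best_side = "mirna"; }
        }
    }
    return List::create(_["score"] = best, _["mismatches"] = best_mm,
                        _["wobbles"] = best_wob, _["gaps"] = best_gap,
                        _["gap_side"] = best_side);
}

// [[Rcpp::export(name = ".scan_transcript_cpp")]]
DataFrame scan_transcript_cpp(std::string mirna, std::string transcript,
                              double threshold) {
    int L = mirna.size(), n = transcript.size();
    std::vector<int> starts, widths;
    std::vector<double> scores;
    for (int s = 0; s + L - 1 <= n; ++s) {     // 0-based start, allow W=L-1 at end
        double best = R_PosInf;
        int best_w = 0;
        for (int W = L - 1; W <= L + 1; ++W) {
            if (W < 1 || s + W > n) continue;
            std::string site = transcript.substr(s, W);
            std::string tr(site.rbegin(), site.rend());
            double sc;
            if (W == L) {
                sc = score_config(mirna, tr, 0, 0);
            } else if (W == L + 1) {
                sc = R_PosInf;
                for (int b = 2; b <= W - 1; ++b)
                    sc = std::min(sc, score_config(mirna, tr, 0, b));
            } else {
                sc = R_PosInf;
                for (int b = 2; b <= L - 1; ++b)
                    sc = std::min(sc, score_config(mirna, tr, b, 0));
            }
            // prefer the ungapped width on ties
            if (sc < best || (sc == best && W == L)) { best = sc; best_w = W; }
        }
        if (best <= threshold) {
            starts.push_back(s + 1);           // report 1-based
            widths.push_back(best_w);
            scores.push_back(best);
        }
    }
    return DataFrame::create(_["start"] = starts, _["width"] = widths,
                             _["score"] = scores);
}
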