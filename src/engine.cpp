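// Built-in seed-and-extend local alignment engine.
//
// Exact k-mer seeding against an indexed subject set, greedy clustering of
// seeds in (diagonal, position) space, then an exact banded Smith-Waterman
// over the seeded window with affine gaps (a gap of length L costs
// gap_open + L * gap_ext, the same convention as Biostrings'
// pairwiseAlignment). One candidate alignment is produced per seed cluster;
// selection of the best hit per query/subject pair happens on the R side.
//
// N (and any non-ACGT nucleotide) never seeds and never counts as a match.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

namespace {

const double NEG_INF = -1e30;

inline int nt_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
    }
}

struct RawHit {
    int qi, si;
    double score;
    int qstart, qend, sstart, send; // 1-based inclusive
    int matches, length;
};

typedef std::vector<std::vector<uint8_t> > SeqList;

void encode_all(const CharacterVector& x, bool protein, SeqList& out) {
    out.resize(x.size());
    for (int i = 0; i < x.size(); ++i) {
        const char* s = CHAR(STRING_ELT(x, i));
        size_t n = std::strlen(s);
        std::vector<uint8_t>& v = out[i];
        v.resize(n);
        if (protein) {
            for (size_t j = 0; j < n; ++j) {
                char c = s[j];
                if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
                v[j] = (uint8_t)c;
            }
        } else {
            for (size_t j = 0; j < n; ++j) v[j] = (uint8_t)nt_code(s[j]);
        }
    }
}

inline bool kmer_at(const std::vector<uint8_t>& s, size_t pos, int k,
                    bool protein, uint64_t& key) {
    key = 0;
    for (int j = 0; j < k; ++j) {
        uint8_t c = s[pos + j];
        if (protein) {
            if (c < 'A' || c > 'Z') return false;
            key = key * 27ULL + (uint64_t)(c - 'A');
        } else {
            if (c > 3) return false;
            key = (key << 2) | (uint64_t)c;
        }
    }
    return true;
}

// Exact banded affine local alignment of q vs s[ws..we] (0-based bounds),
// restricted to window diagonals [dlo, dhi] (diag = j - i, window coords,
// both 1-based during DP). Out-of-band cells are -inf so the alignment
// cannot leave the band. Returns false when no positive-scoring cell exists.
bool banded_sw(const std::vector<uint8_t>& q,
               const std::vector<uint8_t>& s, int ws, int we,
               int dlo, int dhi,
               double match, double mismatch,
               double gap_open, double gap_ext,
               const double* submat, bool protein,
               RawHit& hit) {
    const int m = (int)q.size();
    const int n = we - ws + 1;
    if (m <= 0 || n <= 0) return false;
    if (dlo < 1 - m) dlo = 1 - m;
    if (dhi > n - 1) dhi = n - 1;
    if (dlo > dhi) return false;
    int W = dhi - dlo + 1;

    // clamp band area; centre on the middle diagonal if oversized
    const double max_cells = 3.2e7;
    if ((double)(m + 1) * (W + 2) > max_cells) {
        int mid = (dlo + dhi) / 2;
        int half = (int)(max_cells / (double)(m + 1) / 2.0) - 2;
        if (half < 16) half = 16;
        dlo = mid - half;
        dhi = mid + half;
        if (dlo < 1 - m) dlo = 1 - m;
        if (dhi > n - 1) dhi = n - 1;
        W = dhi - dlo + 1;
        if (W <= 0) return false;
    }

    // rolling rows over band columns b = (j - i) - dlo in [0, W-1]
    std::vector<double> Hprev(W, NEG_INF), Hcur(W, NEG_INF);
    std::vector<double> Fprev(W, NEG_INF), Fcur(W, NEG_INF);
    std::vector<double> Ecur(W, NEG_INF);
    // traceback byte per cell: bits 0-1 H move (0 stop, 1 diag, 2 E, 3 F);
    // bit 4: E extends; bit 5: F extends
    std::vector<uint8_t> tb((size_t)(m + 1) * (size_t)W, 0);

    // row 0: H = 0 on in-band cells (alignment may start before any query char)
    for (int b = 0; b < W; ++b) {
        int j = 0 + dlo + b;
        Hprev[b] = (j >= 0 && j <= n) ? 0.0 : NEG_INF;
    }

    double best = 0.0;
    int bi = -1, bb = -1;

    for (int i = 1; i <= m; ++i) {
        std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
        std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
        std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
        int blo = std::max(0, 1 - i - dlo);
        int bhi = std::min(W - 1, n - i - dlo);
        uint8_t qc = q[i - 1];
        size_t rowoff = (size_t)i * (size_t)W;
        for (int b = blo; b <= bhi; ++b) {
            int j = i + dlo + b;
            uint8_t sc = s[ws + j - 1];
            uint8_t code = 0;

            // E(i,j): gap in query, predecessor at (i, j-1) = band b-1, same row
            double e = NEG_INF;
            if (b >= 1) {
                double eo = (Hcur[b - 1] > NEG_INF / 2) ? Hcur[b - 1] - gap_open - gap_ext : NEG_INF;
                double ee = (Ecur[b - 1] > NEG_INF / 2) ? Ecur[b - 1] - gap_ext : NEG_INF;
                if (ee > eo) { e = ee; code |= 0x10; } else e = eo;
            }
            Ecur[b] = e;

            // F(i,j): gap in subject, predecessor at (i-1, j) = band b+1, prev row
            double f = NEG_INF;
            if (b + 1 < W) {
                double fo = (Hprev[b + 1] > NEG_INF / 2) ? Hprev[b + 1] - gap_open - gap_ext : NEG_INF;
                double fe = (Fprev[b + 1] > NEG_INF / 2) ? Fprev[b + 1] - gap_ext : NEG_INF;
                if (fe > fo) { f = fe; code |= 0x20; } else f = fo;
            }
            Fcur[b] = f;

            // diagonal predecessor (i-1, j-1) = band b, prev row
            double sub;
            if (protein) sub = submat[(size_t)qc * 128 + sc];
            else sub = (qc < 4 && sc < 4 && qc == sc) ? match : mismatch;
            double d = (Hprev[b] > NEG_INF / 2) ? Hprev[b] + sub : NEG_INF;

            double h = 0.0; uint8_t mv = 0;
            if (d > h) { h = d; mv = 1; }
            if (e > h) { h = e; mv = 2; }
            if (f > h) { h = f; mv = 3; }
            Hcur[b] = h;
            tb[rowoff + b] = code | mv;
            if (h > best) { best = h; bi = i; bb = b; }
        }
        Hprev.swap(Hcur);
        Fprev.swap(Fcur);
    }

    if (best <= 0.0 || bi < 0) return false;

    // traceback
    int i = bi, b = bb;
    int j = i + dlo + b;
    int qend = i, send = j;
    int qstart = i + 1, sstart = j + 1;
    int matches = 0, length = 0;
    int state = 0; // 0 = H, 1 = E, 2 = F
    while (true) {
        uint8_t t = tb[(size_t)i * (size_t)W + (size_t)b];
        if (state == 0) {
            uint8_t mv = t & 0x03;
            if (mv == 0) break;
            if (mv == 1) {
                uint8_t qc = q[i - 1], sc = s[ws + j - 1];
                bool eq = protein ? (qc == sc) : (qc < 4 && sc < 4 && qc == sc);
                if (eq) ++matches;
                ++length;
                qstart = i; sstart = j;
                --i; --j;           // band index unchanged on diagonal move
            } else if (mv == 2) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {    // E: consumes subject char j
            ++length;
            sstart = j;
            bool ext = (t & 0x10) != 0;
            --j; --b;
            state = ext ? 1 : 0;
        } else {                    // F: consumes query char i
            ++length;
            qstart = i;
            bool ext = (t & 0x20) != 0;
            --i; ++b;
            state = ext ? 2 : 0;
        }
        if (i <= 0 || j <= 0) {
            if (state == 0) break;
            // gap chains cannot start at the matrix edge in a local alignment
            break;
        }
    }

    hit.score = best;
    hit.qstart = qstart;
    hit.qend = qend;
    hit.sstart = ws + sstart;   // back to full-subject 1-based coordinates
    hit.send = ws + send;
    hit.matches = matches;
    hit.length = length;
    return true;
}

struct Seed { int qpos, spos; };

bool seed_less(const Seed& a, const Seed& b) {
    int da = a.spos - a.qpos, db = b.spos - b.qpos;
    if (da != db) return da < db;
    return a.spos < b.spos;
}

} // namespace

// [[Rcpp::export(name = ".seed_extend_search")]]
DataFrame seed_extend_search(CharacterVector queries, CharacterVector subjects,
                             int word_size, int min_seeds,
                             double match, double mismatch,
                             double gap_open, double gap_ext,
                             bool protein,
                             Rcpp::Nullable<NumericMatrix> submat_,
                             int diag_gap, int band_pad) {
    SeqList qs, ss;
    encode_all(queries, protein, qs);
    encode_all(subjects, protein, ss);

    // 128x128 substitution lookup for protein tasks
    std::vector<double> submat((size_t)128 * 128, 0.0);
    if (protein) {
        if (submat_.isNull())
            stop("protein task requires a substitution matrix");
        NumericMatrix sm(submat_);
        CharacterVector rn = rownames(sm), cn = colnames(sm);
        for (size_t a = 0; a < submat.size(); ++a) submat[a] = -4.0;
        for (int a = 0; a < sm.nrow(); ++a) {
            char ca = CHAR(STRING_ELT(rn, a))[0];
            for (int b = 0; b < sm.ncol(); ++b) {
                char cb = CHAR(STRING_ELT(cn, b))[0];
                submat[(size_t)(uint8_t)ca * 128 + (uint8_t)cb] = sm(a, b);
            }
        }
    }

    // subject k-mer index
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > index;
    {
        size_t total = 0;
        for (size_t i = 0; i < ss.size(); ++i)
            if (ss[i].size() >= (size_t)word_size)
                total += ss[i].size() - word_size + 1;
        index.reserve(total + 16);
        for (size_t i = 0; i < ss.size(); ++i) {
            if (ss[i].size() < (size_t)word_size) continue;
            for (size_t p = 0; p + word_size <= ss[i].size(); ++p) {
                uint64_t key;
                if (kmer_at(ss[i], p, word_size, protein, key))
                    index[key].push_back(std::make_pair((int32_t)i, (int32_t)p));
            }
        }
    }

    std::vector<RawHit> hits;

    for (size_t qi = 0; qi < qs.size(); ++qi) {
        const std::vector<uint8_t>& q = qs[qi];
        const int qlen = (int)q.size();
        if (qlen < word_size) continue;

        // collect seeds per subject
        std::unordered_map<int, std::vector<Seed> > per_subject;
        for (int p = 0; p + word_size <= qlen; ++p) {
            uint64_t key;
            if (!kmer_at(q, (size_t)p, word_size, protein, key)) continue;
            std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > >::const_iterator it = index.find(key);
            if (it == index.end()) continue;
            const std::vector<std::pair<int32_t, int32_t> >& v = it->second;
            for (size_t a = 0; a < v.size(); ++a) {
                Seed sd; sd.qpos = p; sd.spos = v[a].second;
                per_subject[v[a].first].push_back(sd);
            }
        }

        std::vector<int> sids;
        sids.reserve(per_subject.size());
        for (std::unordered_map<int, std::vector<Seed> >::iterator it = per_subject.begin();
             it != per_subject.end(); ++it)
            sids.push_back(it->first);
        std::sort(sids.begin(), sids.end());

        for (size_t a = 0; a < sids.size(); ++a) {
            int si = sids[a];
            std::vector<Seed>& seeds = per_subject[si];
            std::sort(seeds.begin(), seeds.end(), seed_less);
            const std::vector<uint8_t>& s = ss[si];
            const int slen = (int)s.size();
            const int pos_gap = qlen + 100;

            size_t c0 = 0;
            while (c0 < seeds.size()) {
                size_t c1 = c0 + 1;
                int last_diag = seeds[c0].spos - seeds[c0].qpos;
                int last_spos = seeds[c0].spos;
                while (c1 < seeds.size()) {
                    int d = seeds[c1].spos - seeds[c1].qpos;
                    if (d - last_diag > diag_gap) break;
                    if (seeds[c1].spos - last_spos > pos_gap) break;
                    last_diag = d;
                    last_spos = seeds[c1].spos;
                    ++c1;
                }
                int nseeds = (int)(c1 - c0);
                if (nseeds >= min_seeds) {
                    int dmin = seeds[c0].spos - seeds[c0].qpos;
                    int dmax = dmin, ws = INT32_MAX, we = 0;
                    for (size_t c = c0; c < c1; ++c) {
                        int d = seeds[c].spos - seeds[c].qpos;
                        if (d < dmin) dmin = d;
                        if (d > dmax) dmax = d;
                        int lo = seeds[c].spos - seeds[c].qpos;           // alignment could reach subject pos of q[0]
                        int hi = seeds[c].spos + (qlen - seeds[c].qpos) + word_size;
                        if (lo < ws) ws = lo;
                        if (hi > we) we = hi;
                    }
                    ws -= band_pad; we += band_pad;
                    if (ws < 0) ws = 0;
                    if (we > slen - 1) we = slen - 1;
                    // window-relative diagonal band
                    int wdlo = (dmin - ws) - band_pad;
                    int wdhi = (dmax - ws) + band_pad;
                    RawHit h;
                    if (banded_sw(q, s, ws, we, wdlo, wdhi,
                                  match, mismatch, gap_open, gap_ext,
                                  submat.data(), protein, h)) {
                        h.qi = (int)qi + 1;
                        h.si = si + 1;
                        hits.push_back(h);
                    }
                }
                c0 = c1;
            }
        }
    }

    const int nh = (int)hits.size();
    IntegerVector qi(nh), si(nh), qstart(nh), qend(nh), sstart(nh), send(nh),
        matches(nh), length(nh);
    NumericVector score(nh);
    for (int i = 0; i < nh; ++i) {
        qi[i] = hits[i].qi; si[i] = hits[i].si;
        qstart[i] = hits[i].qstart; qend[i] = hits[i].qend;
        sstart[i] = hits[i].sstart; send[i] = hits[i].send;
        matches[i] = hits[i].matches; length[i] = hits[i].length;
        score[i] = hits[i].score;
    }
    return DataFrame::create(
        Named("qi") = qi, Named("si") = si, Named("score") = score,
        Named("q_start") = qstart, Named("q_end") = qend,
        Named("s_start") = sstart, Named("s_end") = send,
        Named("matches") = matches, Named("align_length") = length);
}
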