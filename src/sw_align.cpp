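#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length L costs
// gap_open + L * gap_extend, the BLAST protein convention.
// Scores come in as a 26x26 integer lookup indexed by (letter - 'A');
// the R layer maps non-canonical letters onto X before building it.

static const int NEG = -1000000000;

struct AlnResult {
    int score;
    int aln_len;
    int n_ident;
    int q_start, q_end, s_start, s_end; // 1-based inclusive, 0 if no alignment
};

// Score-only DP with rolling rows: one previous H row, one F row and a
// scalar E carry, so the working set stays in L1 cache. Used for the
// all-vs-all pre-pass; full matrices are only built for pairs that
// clear the reporting threshold.
static int sw_score_only(const char *a, int n, const char *b, int m,
                         const int *S, int gap_open, int gap_extend,
                         std::vector<int> &Hprev, std::vector<int> &Fprev) {
    const int open_cost = gap_open + gap_extend;
    Hprev.assign(m + 1, 0);
    Fprev.assign(m + 1, NEG);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
        const int *Srow = S + 26 * (a[i - 1] - 'A');
        int Hdiag = 0;  // H[i-1][j-1]
        int Hleft = 0;  // H[i][j-1]
        int E = NEG;
        for (int j = 1; j <= m; ++j) {
            int e_open = Hleft - open_cost;
            int e_ext = E - gap_extend;
            E = e_open >= e_ext ? e_open : e_ext;
            int f_open = Hprev[j] - open_cost;
            int f_ext = Fprev[j] - gap_extend;
            int F = f_open >= f_ext ? f_open : f_ext;
            int h = Hdiag + Srow[b[j - 1] - 'A'];
            if (h < 0) h = 0;
            if (E > h) h = E;
            if (F > h) h = F;
            if (h > best) best = h;
            Hdiag = Hprev[j];
            Hprev[j] = h;
            Hleft = h;
            Fprev[j] = F;
        }
    }
    return best;
}

// Traceback codes per DP cell, one matrix per Gotoh state.
// H: 0 = stop (cell is 0), 1 = diagonal, 2 = came from E, 3 = came from F
// E (gap in query / consumes subject): 0 = opened from H, 1 = extended
// F (gap in subject / consumes query): 0 = opened from H, 1 = extended
static AlnResult sw_one(const char *a, int n, const char *b, int m,
                        const int *S, int gap_open, int gap_extend,
                        bool traceback,
                        std::vector<int> &H, std::vector<int> &E,
                        std::vector<int> &F, std::vector<unsigned char> &TH,
                        std::vector<unsigned char> &TE,
                        std::vector<unsigned char> &TF) {
    const int W = m + 1;
    H.assign((size_t)(n + 1) * W, 0);
    E.assign((size_t)(n + 1) * W, NEG);
    F.assign((size_t)(n + 1) * W, NEG);
    if (traceback) {
        TH.assign((size_t)(n + 1) * W, 0);
        TE.assign((size_t)(n + 1) * W, 0);
        TF.assign((size_t)(n + 1) * W, 0);
    }
    int best = 0, bi = 0, bj = 0;
    const int open_cost = gap_open + gap_extend;
    for (int i = 1; i <= n; ++i) {
        const int ai = a[i - 1] - 'A';
        const int *Srow = S + 26 * ai;
        for (int j = 1; j <= m; ++j) {
            const size_t c = (size_t)i * W + j;
            // E: gap in the query, moving along b
            int e_open = H[c - 1] - open_cost;
            int e_ext = E[c - 1] - gap_extend;
            if (e_open >= e_ext) {
                E[c] = e_open;
                if (traceback) TE[c] = 0;
            } else {
                E[c] = e_ext;
                if (traceback) TE[c] = 1;
            }
            // F: gap in the subject, moving along a
            int f_open = H[c - W] - open_cost;
            int f_ext = F[c - W] - gap_extend;
            if (f_open >= f_ext) {
                F[c] = f_open;
                if (traceback) TF[c] = 0;
            } else {
                F[c] = f_ext;
                if (traceback) TF[c] = 1;
            }
            int diag = H[c - W - 1] + Srow[b[j - 1] - 'A'];
            int h = 0;
            unsigned char th = 0;
            if (diag > h) { h = diag; th = 1; }
            if (E[c] > h) { h = E[c]; th = 2; }
            if (F[c] > h) { h = F[c]; th = 3; }
            H[c] = h;
            if (traceback) TH[c] = th;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    AlnResult r;
    r.score = best;
    r.aln_len = 0; r.n_ident = 0;
    r.q_start = r.q_end = r.s_start = r.s_end = 0;
    if (best <= 0 || !traceback) return r;
    // Walk back from the best cell through the three-state machine.
    int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
    r.q_end = bi; r.s_end = bj;
    while (true) {
        const size_t c = (size_t)i * W + j;
        if (state == 0) {
            unsigned char th = TH[c];
            if (th == 0) break;          // reached a zero cell
            if (th == 1) {
                ++r.aln_len;
                if (a[i - 1] == b[j - 1]) ++r.n_ident;
                r.q_start = i; r.s_start = j;
                --i; --j;
            } else if (th == 2) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            ++r.aln_len;                 // gap column in the query
            if (TE[c] == 0) state = 0;
            --j;
        } else {
            ++r.aln_len;                 // gap column in the subject
            if (TF[c] == 0) state = 0;
            --i;
        }
        if (i == 0 || j == 0) {
            if (i > 0) r.q_start = i + 1;
            if (j > 0) r.s_start = j + 1;
            break;
        }
    }
    return r;
}

// [[Rcpp::export(name = ".sw_align_pairs")]]
DataFrame sw_align_pairs(CharacterVector seqs_a, CharacterVector seqs_b,
                         IntegerMatrix score_lookup, int gap_open,
                         int gap_extend, bool traceback = true) {
    if (score_lookup.nrow() != 26 || score_lookup.ncol() != 26)
        stop("score lookup must be 26x26");
    const int np = seqs_a.size();
    if (seqs_b.size() != np) stop("sequence vectors differ in length");
    std::vector<int> S(26 * 26);
    for (int i = 0; i < 26; ++i)
        for (int j = 0; j < 26; ++j) S[26 * i + j] = score_lookup(i, j);
    IntegerVector score(np), aln_len(np), n_ident(np);
    IntegerVector q_start(np), q_end(np), s_start(np), s_end(np);
    std::vector<int> H, E, F;
    std::vector<unsigned char> TH, TE, TF;
    for (int k = 0; k < np; ++k) {
        std::string sa = as<std::string>(seqs_a[k]);
        std::string sb = as<std::string>(seqs_b[k]);
        if (sa.empty() || sb.empty()) stop("empty sequence in alignment input");
        AlnResult r = sw_one(sa.c_str(), (int)sa.size(), sb.c_str(),
                             (int)sb.size(), S.data(), gap_open, gap_extend,
                             traceback, H, E, F, TH, TE, TF);
        score[k] = r.score; aln_len[k] = r.aln_len; n_ident[k] = r.n_ident;
        q_start[k] = r.q_start; q_end[k] = r.q_end;
        s_start[k] = r.s_start; s_end[k] = r.s_end;
    }
    return DataFrame::create(
        _["raw_score"] = score, _["n_ident"] = n_ident,
        _["aln_len"] = aln_len, _["q_start"] = q_start, _["q_end"] = q_end,
        _["s_start"] = s_start, _["s_end"] = s_end);
}

// All-vs-all over one sequence set: aligns every unordered pair i<j and
// returns one row per pair. The R layer mirrors rows into directed hits
// (local alignment under a symmetric matrix is symmetric in score,
// identity and length; coordinates swap).
// [[Rcpp::export(name = ".sw_align_all")]]
DataFrame sw_align_all(CharacterVector seqs, IntegerMatrix score_lookup,
                       int gap_open, int gap_extend, int min_score = 1) {
    const int n = seqs.size();
    std::vector<int> S(26 * 26);
    for (int i = 0; i < 26; ++i)
        for (int j = 0; j < 26; ++j) S[26 * i + j] = score_lookup(i, j);
    std::vector<std::string> sq(n);
    for (int i = 0; i < n; ++i) {
        sq[i] = as<std::string>(seqs[i]);
        if (sq[i].empty()) stop("empty sequence in alignment input");
    }
    std::vector<int> ia, ja, sc, al, id, qs, qe, ss, se;
    std::vector<int> H, E, F, Hprev, Fprev;
    std::vector<unsigned char> TH, TE, TF;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            // score-only pass first: traceback bookkeeping is only
            // needed for the minority of pairs that clear min_score
            int s0 = sw_score_only(sq[i].c_str(), (int)sq[i].size(),
                                   sq[j].c_str(), (int)sq[j].size(), S.data(),
                                   gap_open, gap_extend, Hprev, Fprev);
            if (s0 <= 0 || s0 < min_score) continue;
            AlnResult r = sw_one(sq[i].c_str(), (int)sq[i].size(),
                                 sq[j].c_str(), (int)sq[j].size(), S.data(),
                                 gap_open, gap_extend, true, H, E, F, TH, TE,
                                 TF);
            ia.push_back(i + 1); ja.push_back(j + 1);
            sc.push_back(r.score); al.push_back(r.aln_len);
            id.push_back(r.n_ident);
            qs.push_back(r.q_start); qe.push_back(r.q_end);
            ss.push_back(r.s_start); se.push_back(r.s_end);
        }
        Rcpp::checkUserInterrupt();
    }
    return DataFrame::create(
        _["i"] = ia, _["j"] = ja, _["raw_score"] = sc, _["n_ident"] = id,
        _["aln_len"] = al, _["q_start"] = qs, _["q_end"] = qe,
        _["s_start"] = ss, _["s_end"] = se);
}
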