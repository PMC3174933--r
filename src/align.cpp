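// Dynamic-programming kernels for frameshift-aware codon alignment.
//
// All kernels maximise an amino-acid-level score with affine gap costs in
// codon-site units, free terminal gaps (semi-global), free trailing partial
// codons and free terminal stop codons. Only the origin cell is explicitly
// initialised; every other boundary access goes through a -inf sentinel
// that can never win a maximisation.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e18;

// amino-acid index of the codon starting at 0-based position start0:
// 0..19 residue, 20 = X (any N), 21 = stop
static inline int aaAt(const IntegerVector& s, int start0,
                       const IntegerVector& aaMap) {
    int x = s[start0], y = s[start0 + 1], z = s[start0 + 2];
    if (x == 4 || y == 4 || z == 4) return 20;
    return aaMap[16 * x + 4 * y + z] - 1;
}

// ---------------------------------------------------------------------------
// Pairwise 15-move DP (three Gotoh states M/D/I over nucleotide prefixes)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_align_pair(IntegerVector a, IntegerVector b,
                    IntegerVector aaMapA, IntegerVector aaMapB,
                    NumericMatrix sub, double gapOpen, double gapExt,
                    double fsA, double fsB, double stopA, double stopB) {
    const int n = a.size(), m = b.size();
    const int W = m + 1;
    const size_t NC = (size_t)(n + 1) * W;
    std::vector<double> S[3];
    std::vector<signed char> bpA[3], bpB[3], bpP[3];
    for (int st = 0; st < 3; st++) {
        S[st].assign(NC, NEG);
        bpA[st].assign(NC, -1); bpB[st].assign(NC, -1); bpP[st].assign(NC, -1);
    }
    S[0][0] = 0.0;

    // moves per state in deterministic tie-break priority order
    const int Mda[9] = {3, 3, 3, 2, 1, 2, 2, 1, 1};
    const int Mdb[9] = {3, 2, 1, 3, 3, 2, 1, 2, 1};
    const int Dda[3] = {3, 2, 1};
    const int Idb[3] = {3, 2, 1};

    for (int i = 0; i <= n; i++) {
        for (int j = 0; j <= m; j++) {
            if (i == 0 && j == 0) continue;
            const size_t at = (size_t)i * W + j;

            // M: substitution-class moves (da>=1, db>=1)
            {
                double best = NEG; int bda = -1, bdb = -1, bp = -1;
                for (int k = 0; k < 9; k++) {
                    const int da = Mda[k], db = Mdb[k];
                    if (i < da || j < db) continue;
                    double c = 0.0; int aA = -1, aB = -1;
                    if (da == 3) {
                        aA = aaAt(a, i - 3, aaMapA);
                        if (aA == 21 && i < n) c += stopA;
                    } else if (i < n) c += fsA;
                    if (db == 3) {
                        aB = aaAt(b, j - 3, aaMapB);
                        if (aB == 21 && j < m) c += stopB;
                    } else if (j < m) c += fsB;
                    if (da == 3 && db == 3 && aA != 21 && aB != 21)
                        c += sub(aA, aB);
                    const size_t from = (size_t)(i - da) * W + (j - db);
                    for (int p = 0; p < 3; p++) {
                        const double v = S[p][from];
                        if (v <= NEG / 2) continue;
                        if (v + c > best) { best = v + c; bda = da; bdb = db; bp = p; }
                    }
                }
                if (bda >= 0) {
                    S[0][at] = best;
                    bpA[0][at] = (signed char)bda; bpB[0][at] = (signed char)bdb;
                    bpP[0][at] = (signed char)bp;
                }
            }
            // D: consume A only (gap sites in B); gap run has fixed j
            {
                double best = NEG; int bda = -1, bp = -1;
                const bool term = (j == 0 || j == m);
                for (int k = 0; k < 3; k++) {
                    const int da = Dda[k];
                    if (i < da) continue;
                    double c = 0.0;
                    if (da == 3) {
                        const int aA = aaAt(a, i - 3, aaMapA);
                        if (aA == 21 && i < n) c += stopA;
                    } else if (i < n) c += fsA;
                    const size_t from = (size_t)(i - da) * W + j;
                    for (int p = 0; p < 3; p++) {
                        const double v = S[p][from];
                        if (v <= NEG / 2) continue;
                        const double g = term ? 0.0
                            : gapExt + (p == 1 ? 0.0 : gapOpen);
                        if (v + c + g > best) { best = v + c + g; bda = da; bp = p; }
                    }
                }
                if (bda >= 0) {
                    S[1][at] = best;
                    bpA[1][at] = (signed char)bda; bpB[1][at] = 0;
                    bpP[1][at] = (signed char)bp;
                }
            }
            // I: consume B only (gap sites in A)
            {
                double best = NEG; int bdb = -1, bp = -1;
                const bool term = (i == 0 || i == n);
                for (int k = 0; k < 3; k++) {
                    const int db = Idb[k];
                    if (j < db) continue;
                    double c = 0.0;
                    if (db == 3) {
                        const int aB = aaAt(b, j - 3, aaMapB);
                        if (aB == 21 && j < m) c += stopB;
                    } else if (j < m) c += fsB;
                    const size_t from = (size_t)i * W + (j - db);
                    for (int p = 0; p < 3; p++) {
                        const double v = S[p][from];
                        if (v <= NEG / 2) continue;
                        const double g = term ? 0.0
                            : gapExt + (p == 2 ? 0.0 : gapOpen);
                        if (v + c + g > best) { best = v + c + g; bdb = db; bp = p; }
                    }
                }
                if (bdb >= 0) {
                    S[2][at] = best;
                    bpA[2][at] = 0; bpB[2][at] = (signed char)bdb;
                    bpP[2][at] = (signed char)bp;
                }
            }
        }
    }

    // final state: strict improvement, preference M > D > I
    const size_t end = (size_t)n * W + m;
    int bestState = 0; double best = S[0][end];
    for (int st = 1; st < 3; st++)
        if (S[st][end] > best) { best = S[st][end]; bestState = st; }

    std::vector<int> pa, pb;
    if (n + m > 0) {
        int i = n, j = m, st = bestState;
        while (!(i == 0 && j == 0)) {
            const size_t at = (size_t)i * W + j;
            const int da = bpA[st][at], db = bpB[st][at], p = bpP[st][at];
            pa.push_back(da); pb.push_back(db);
            i -= da; j -= db; st = p;
        }
        std::reverse(pa.begin(), pa.end());
        std::reverse(pb.begin(), pb.end());
    } else {
        best = 0.0;
    }
    IntegerMatrix path(pa.size(), 2);
    for (size_t k = 0; k < pa.size(); k++) { path(k, 0) = pa[k]; path(k, 1) = pb[k]; }
    return List::create(_["score"] = best, _["path"] = path);
}

// ---------------------------------------------------------------------------
// Block vs block: columns are atomic, 3 moves, SP substitution costs with
// quasi-natural (pessimistic) gap-opening counts across blocks.
// ---------------------------------------------------------------------------

// is the gap cell at 1-based column `col` row-terminal for row r?
static inline bool cellTerm(const IntegerVector& firstNG,
                            const IntegerVector& lastNG, int r, int col) {
    return col < firstNG[r] || col > lastNG[r];
}
// is an all-gap column inserted after column `after` (0..c) free for row r?
static inline bool insTerm(const IntegerVector& firstNG,
                           const IntegerVector& lastNG, int r, int after) {
    return after < firstNG[r] || after >= lastNG[r];
}

// [[Rcpp::export]]
List cpp_align_blocks(IntegerMatrix isGap1, IntegerMatrix subAa1,
                      NumericMatrix event1,
                      IntegerVector firstNG1, IntegerVector lastNG1,
                      IntegerMatrix isGap2, IntegerMatrix subAa2,
                      NumericMatrix event2,
                      IntegerVector firstNG2, IntegerVector lastNG2,
                      NumericMatrix sub, double gapOpen, double gapExt) {
    const int r1 = isGap1.nrow(), c1 = isGap1.ncol();
    const int r2 = isGap2.nrow(), c2 = isGap2.ncol();
    const int W = c2 + 1;
    const size_t NC = (size_t)(c1 + 1) * W;
    std::vector<double> S[3];
    std::vector<signed char> bpP[3];
    for (int st = 0; st < 3; st++) { S[st].assign(NC, NEG); bpP[st].assign(NC, -1); }
    S[0][0] = 0.0;

    for (int i = 0; i <= c1; i++) {
        for (int j = 0; j <= c2; j++) {
            if (i == 0 && j == 0) continue;
            const size_t at = (size_t)i * W + j;

            // M: pair column i of block 1 with column j of block 2
            if (i >= 1 && j >= 1) {
                const size_t from = (size_t)(i - 1) * W + (j - 1);
                double best = NEG; int bp = -1;
                for (int p = 0; p < 3; p++) {
                    const double v = S[p][from];
                    if (v <= NEG / 2) continue;
                    double c = 0.0;
                    for (int x = 0; x < r1; x++) {
                        const bool g1 = isGap1(x, i - 1) != 0;
                        for (int y = 0; y < r2; y++) {
                            const bool g2 = isGap2(y, j - 1) != 0;
                            if (g1 && g2) continue;
                            if (!g1) c += event1(x, i - 1);
                            if (!g2) c += event2(y, j - 1);
                            if (!g1 && !g2) {
                                const int sa = subAa1(x, i - 1), sb = subAa2(y, j - 1);
                                if (sa >= 0 && sb >= 0) c += sub(sa, sb);
                            } else if (g1) {
                                if (cellTerm(firstNG1, lastNG1, x, i)) continue;
                                c += gapExt;
                                // open unless the previous pair column was
                                // already (gap in x, residue in y)
                                bool open = true;
                                if (p == 0 && !(i - 1 == 0 && j - 1 == 0)) {
                                    const bool pg1 = (i >= 2) ? isGap1(x, i - 2) != 0 : true;
                                    const bool pg2 = (j >= 2) ? isGap2(y, j - 2) != 0 : true;
                                    open = !(pg1 && !pg2);
                                } else if (p == 2) {
                                    // prev pair (gap, col j-1 of block 2)
                                    const bool pg2 = (j >= 2) ? isGap2(y, j - 2) != 0 : true;
                                    open = pg2;
                                }  // p == 1: prev pair (x, gap) -> always open
                                if (open) c += gapOpen;
                            } else { // g2: gap in block 2 row y
                                if (cellTerm(firstNG2, lastNG2, y, j)) continue;
                                c += gapExt;
                                // open unless the previous pair column was
                                // already (residue in x missing?, gap in y):
                                // i.e. prev pair (gap in y, residue in x)
                                bool open = true;
                                if (p == 0 && !(i - 1 == 0 && j - 1 == 0)) {
                                    const bool pg1 = (i >= 2) ? isGap1(x, i - 2) != 0 : true;
                                    const bool pg2 = (j >= 2) ? isGap2(y, j - 2) != 0 : true;
                                    open = !(pg2 && !pg1);
                                } else if (p == 1) {
                                    // prev pair (col i-1 of block 1, gap)
                                    const bool pg1 = (i >= 2) ? isGap1(x, i - 2) != 0 : true;
                                    open = pg1;
                                }  // p == 2: prev pair (gap, y) -> always open
                                if (open) c += gapOpen;
                            }
                        }
                    }
                    if (v + c > best) { best = v + c; bp = p; }
                }
                if (bp >= 0) { S[0][at] = best; bpP[0][at] = (signed char)bp; }
            }
            // D: consume column i of block 1, all-gap column for block 2
            if (i >= 1) {
                const size_t from = (size_t)(i - 1) * W + j;
                double best = NEG; int bp = -1;
                for (int p = 0; p < 3; p++) {
                    const double v = S[p][from];
                    if (v <= NEG / 2) continue;
                    double c = 0.0;
                    for (int x = 0; x < r1; x++) {
                        if (isGap1(x, i - 1)) continue;  // pair columns all both-gap
                        const double ev = event1(x, i - 1);
                        for (int y = 0; y < r2; y++) {
                            c += ev;
                            if (insTerm(firstNG2, lastNG2, y, j)) continue;
                            c += gapExt;
                            // current pair (residue, gap); open unless prev
                            // pair was (residue, gap) too
                            bool open = true;
                            if (p == 1) {
                                const bool pg1 = (i >= 2) ? isGap1(x, i - 2) != 0 : true;
                                open = pg1;  // residue->residue continues the run
                            }
                            if (open) c += gapOpen;
                        }
                    }
                    if (v + c > best) { best = v + c; bp = p; }
                }
                if (bp >= 0) { S[1][at] = best; bpP[1][at] = (signed char)bp; }
            }
            // I: all-gap column for block 1, consume column j of block 2
            if (j >= 1) {
                const size_t from = (size_t)i * W + (j - 1);
                double best = NEG; int bp = -1;
                for (int p = 0; p < 3; p++) {
                    const double v = S[p][from];
                    if (v <= NEG / 2) continue;
                    double c = 0.0;
                    for (int y = 0; y < r2; y++) {
                        if (isGap2(y, j - 1)) continue;
                        const double ev = event2(y, j - 1);
                        for (int x = 0; x < r1; x++) {
                            c += ev;
                            if (insTerm(firstNG1, lastNG1, x, i)) continue;
                            c += gapExt;
                            bool open = true;
                            if (p == 2) {
                                const bool pg2 = (j >= 2) ? isGap2(y, j - 2) != 0 : true;
                                open = pg2;
                            }
                            if (open) c += gapOpen;
                        }
                    }
                    if (v + c > best) { best = v + c; bp = p; }
                }
                if (bp >= 0) { S[2][at] = best; bpP[2][at] = (signed char)bp; }
            }
        }
    }

    const size_t end = (size_t)c1 * W + c2;
    int bestState = 0; double best = S[0][end];
    for (int st = 1; st < 3; st++)
        if (S[st][end] > best) { best = S[st][end]; bestState = st; }

    std::vector<int> mvs;
    int i = c1, j = c2, st = bestState;
    while (!(i == 0 && j == 0)) {
        const size_t at = (size_t)i * W + j;
        const int p = bpP[st][at];
        mvs.push_back(st + 1);  // 1=M, 2=D, 3=I
        if (st == 0) { i--; j--; }
        else if (st == 1) i--;
        else j--;
        st = p;
    }
    std::reverse(mvs.begin(), mvs.end());
    return List::create(_["score"] = best, _["moves"] = IntegerVector(mvs.begin(), mvs.end()));
}

// ---------------------------------------------------------------------------
// Sequence vs block: 7 moves (0 or 1 column of the block, 0-3 nucleotides
// of the sequence), so new frameshifts can be introduced in the sequence.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_align_seq_block(IntegerMatrix isGap1, IntegerMatrix subAa1,
                         NumericMatrix event1,
                         IntegerVector firstNG1, IntegerVector lastNG1,
                         IntegerVector s, IntegerVector aaMapS,
                         NumericMatrix sub, double gapOpen, double gapExt,
                         double fsS, double stopS) {
    const int r = isGap1.nrow(), c = isGap1.ncol();
    const int n = s.size();
    const int W = n + 1;
    const size_t NC = (size_t)(c + 1) * W;
    std::vector<double> S[3];
    std::vector<signed char> bpK[3], bpP[3];
    for (int st = 0; st < 3; st++) {
        S[st].assign(NC, NEG); bpK[st].assign(NC, -1); bpP[st].assign(NC, -1);
    }
    S[0][0] = 0.0;
    const int Ks[3] = {3, 2, 1};   // codon move first, then frameshift moves

    for (int i = 0; i <= c; i++) {
        for (int j = 0; j <= n; j++) {
            if (i == 0 && j == 0) continue;
            const size_t at = (size_t)i * W + j;

            // M: column i of the block vs a site of s built from k nts
            if (i >= 1) {
                double best = NEG; int bk = -1, bp = -1;
                for (int kk = 0; kk < 3; kk++) {
                    const int k = Ks[kk];
                    if (j < k) continue;
                    double evS = 0.0; int subS = -1;
                    if (k == 3) {
                        const int aa = aaAt(s, j - 3, aaMapS);
                        if (aa == 21) { if (j < n) evS = stopS; }
                        else subS = aa;
                    } else if (j < n) evS = fsS;
                    const size_t from = (size_t)(i - 1) * W + (j - k);
                    for (int p = 0; p < 3; p++) {
                        const double v = S[p][from];
                        if (v <= NEG / 2) continue;
                        double cst = 0.0;
                        for (int x = 0; x < r; x++) {
                            cst += evS;   // s is a residue in every pair
                            if (isGap1(x, i - 1)) {
                                if (cellTerm(firstNG1, lastNG1, x, i)) continue;
                                cst += gapExt;
                                bool open = true;
                                if (p == 0 && !(i - 1 == 0 && j - k == 0)) {
                                    const bool pg1 = (i >= 2) ? isGap1(x, i - 2) != 0 : true;
                                    open = !pg1;       // prev pair (pg1, residue)
                                } else if (p == 2) {
                                    open = false;      // prev pair (gap, residue)
                                }
                                if (open) cst += gapOpen;
                            } else {
                                cst += event1(x, i - 1);
                                const int sa = subAa1(x, i - 1);
                                if (sa >= 0 && subS >= 0) cst += sub(sa, subS);
                            }
                        }
                        if (v + cst > best) { best = v + cst; bk = k; bp = p; }
                    }
                }
                if (bk >= 0) { S[0][at] = best; bpK[0][at] = (signed char)bk; bpP[0][at] = (signed char)bp; }
            }
            // D: column i of the block vs a gap site in s (gap run has fixed j)
            if (i >= 1) {
                const size_t from = (size_t)(i - 1) * W + j;
                const bool term = (j == 0 || j == n);
                double best = NEG; int bp = -1;
                for (int p = 0; p < 3; p++) {
                    const double v = S[p][from];
                    if (v <= NEG / 2) continue;
                    double cst = 0.0;
                    for (int x = 0; x < r; x++) {
                        if (isGap1(x, i - 1)) continue;  // both-gap pair column
                        cst += event1(x, i - 1);
                        if (term) continue;
                        cst += gapExt;
                        bool open = true;
                        if (p == 1) {
                            const bool pg1 = (i >= 2) ? isGap1(x, i - 2) != 0 : true;
                            open = pg1;   // residue -> residue continues the run
                        }
                        if (open) cst += gapOpen;
                    }
                    if (v + cst > best) { best = v + cst; bp = p; }
                }
                if (bp >= 0) { S[1][at] = best; bpK[1][at] = 0; bpP[1][at] = (signed char)bp; }
            }
            // I: all-gap column inserted into the block vs a site of s
            {
                double best = NEG; int bk = -1, bp = -1;
                for (int kk = 0; kk < 3; kk++) {
                    const int k = Ks[kk];
                    if (j < k) continue;
                    double evS = 0.0;
                    if (k == 3) {
                        const int aa = aaAt(s, j - 3, aaMapS);
                        if (aa == 21) { if (j < n) evS = stopS; }
                    } else if (j < n) evS = fsS;
                    const size_t from = (size_t)i * W + (j - k);
                    for (int p = 0; p < 3; p++) {
                        const double v = S[p][from];
                        if (v <= NEG / 2) continue;
                        double cst = 0.0;
                        for (int x = 0; x < r; x++) {
                            cst += evS;
                            if (insTerm(firstNG1, lastNG1, x, i)) continue;
                            cst += gapExt;
                            bool open = true;
                            if (p == 2) open = false;       // (gap, residue) continues
                            else if (p == 0) {
                                const bool pg1 = (i >= 1) ? isGap1(x, i - 1) != 0 : true;
                                open = !pg1;
                            }
                            if (open) cst += gapOpen;
                        }
                        if (v + cst > best) { best = v + cst; bk = k; bp = p; }
                    }
                }
                if (bk >= 0) { S[2][at] = best; bpK[2][at] = (signed char)bk; bpP[2][at] = (signed char)bp; }
            }
        }
    }

    const size_t end = (size_t)c * W + n;
    int bestState = 0; double best = S[0][end];
    for (int st = 1; st < 3; st++)
        if (S[st][end] > best) { best = S[st][end]; bestState = st; }

    std::vector<int> takeCol, kNts;
    int i = c, j = n, st = bestState;
    while (!(i == 0 && j == 0)) {
        const size_t at = (size_t)i * W + j;
        const int p = bpP[st][at];
        if (st == 0) { const int k = bpK[0][at]; takeCol.push_back(1); kNts.push_back(k); i--; j -= k; }
        else if (st == 1) { takeCol.push_back(1); kNts.push_back(0); i--; }
        else { const int k = bpK[2][at]; takeCol.push_back(0); kNts.push_back(k); j -= k; }
        st = p;
    }
    std::reverse(takeCol.begin(), takeCol.end());
    std::reverse(kNts.begin(), kNts.end());
    IntegerMatrix path(takeCol.size(), 2);
    for (size_t q = 0; q < takeCol.size(); q++) { path(q, 0) = takeCol[q]; path(q, 1) = kNts[q]; }
    return List::create(_["score"] = best, _["path"] = path);
}
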