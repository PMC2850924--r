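// Glocal profile-HMM dynamic programming.
//
// Architecture: match states M_1..M_M, insert states I_0..I_M, delete
// states D_1..D_M; entry B -> {M_1, I_0, D_1}, exit from M_M, I_M or D_M.
// Glocal mode: every profile column is visited (match or delete) while the
// alignment is local in the target -- flanking target residues are
// unaligned and contribute nothing because emissions are log-odds against
// the background.
//
// Transition vectors are passed in log2 with length M+1; index p holds the
// transitions *from position p* (p = 0 is entry, p = M leads to exit).
// Pure-delete entry (B->D1->...->Mj) and exit (Mj->D->...->E) chains are
// folded into begin/end cost vectors so the inner recurrence only tracks
// internal states.  Paths that emit nothing are excluded.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e300;

static inline double emit(const NumericMatrix& m, int row, int s) {
    // s == -1 encodes X: scores as background (log-odds 0)
    return s < 0 ? 0.0 : m(row, s);
}

static inline double lse2(double a, double b) {
    if (a <= NEG / 2) return b;
    if (b <= NEG / 2) return a;
    double m = a > b ? a : b;
    return m + std::log2(1.0 + std::exp2((a > b ? b : a) - m));
}

static void beginEndCosts(const NumericVector& ltMM,
                          const NumericVector& ltMD,
                          const NumericVector& ltDM,
                          const NumericVector& ltDD,
                          int M,
                          std::vector<double>& beginCost,
                          std::vector<double>& endCost) {
    beginCost.assign(M + 1, NEG);
    endCost.assign(M + 1, NEG);
    beginCost[1] = ltMM[0];                    // B -> M1
    double acc = ltMD[0];                      // B -> D1
    for (int j = 2; j <= M; ++j) {
        if (acc <= NEG / 2) break;
        beginCost[j] = acc + ltDM[j - 1];      // ... D_{j-1} -> M_j
        acc += ltDD[j - 1];                    // D_{j-1} -> D_j
    }
    endCost[M] = ltMM[M];                      // M_M -> E
    // delChain = cost from D_{j+1} down to E
    double delChain = ltDM[M];                 // D_M -> E
    for (int j = M - 1; j >= 1; --j) {
        if (delChain <= NEG / 2) break;
        endCost[j] = ltMD[j] + delChain;       // M_j -> D_{j+1} ... -> E
        delChain = ltDD[j] + delChain;         // prepend D_j -> D_{j+1}
    }
}

// [[Rcpp::export]]
List viterbi_glocal(NumericMatrix lmOdds, NumericMatrix liOdds,
                    NumericVector ltMM, NumericVector ltMI,
                    NumericVector ltMD, NumericVector ltIM,
                    NumericVector ltII, NumericVector ltDM,
                    NumericVector ltDD, IntegerVector seq) {
    const int M = lmOdds.nrow();
    const int L = seq.size();
    std::vector<double> beginCost, endCost;
    beginEndCosts(ltMM, ltMD, ltDM, ltDD, M, beginCost, endCost);

    const int W = M + 1;
    std::vector<double> dpM((L + 1) * W, NEG), dpI((L + 1) * W, NEG),
        dpD((L + 1) * W, NEG);
    std::vector<signed char> pM((L + 1) * W, -1), pI((L + 1) * W, -1),
        pD((L + 1) * W, -1);
#define AT(a, i, j) a[(i) * W + (j)]

    for (int i = 1; i <= L; ++i) {
        int s = seq[i - 1];
        for (int j = 1; j <= M; ++j) {
            // match: candidates in tie-break order M > D > I > begin
            double best = NEG; signed char ptr = -1;
            if (j >= 2 && i >= 2) {
                double c = AT(dpM, i - 1, j - 1) + ltMM[j - 1];
                if (c > best) { best = c; ptr = 0; }
            }
            if (j >= 2 && i >= 2) {
                double c = AT(dpD, i - 1, j - 1) + ltDM[j - 1];
                if (c > best) { best = c; ptr = 1; }
            }
            if (i >= 2) {
                double c = AT(dpI, i - 1, j - 1) + ltIM[j - 1];
                if (c > best) { best = c; ptr = 2; }
            }
            if (beginCost[j] > best) { best = beginCost[j]; ptr = 3; }
            AT(dpM, i, j) = best <= NEG / 2 ? NEG
                                            : best + emit(lmOdds, j - 1, s);
            AT(pM, i, j) = ptr;
        }
        for (int j = 0; j <= M; ++j) {
            double best = NEG; signed char ptr = -1;
            if (j >= 1 && i >= 2) {
                double c = AT(dpM, i - 1, j) + ltMI[j];
                if (c > best) { best = c; ptr = 0; }
            }
            if (i >= 2) {
                double c = AT(dpI, i - 1, j) + ltII[j];
                if (c > best) { best = c; ptr = 1; }
            }
            if (j == 0 && ltMI[0] > best) { best = ltMI[0]; ptr = 2; }
            AT(dpI, i, j) = best <= NEG / 2 ? NEG
                                            : best + emit(liOdds, j, s);
            AT(pI, i, j) = ptr;
        }
        for (int j = 2; j <= M; ++j) {
            double best = NEG; signed char ptr = -1;
            double c = AT(dpM, i, j - 1) + ltMD[j - 1];
            if (c > best) { best = c; ptr = 0; }
            c = AT(dpD, i, j - 1) + ltDD[j - 1];
            if (c > best) { best = c; ptr = 1; }
            AT(dpD, i, j) = best;
            AT(pD, i, j) = ptr;
        }
    }

    double best = NEG; int bi = -1, bj = -1; bool endInsert = false;
    for (int i = 1; i <= L; ++i) {
        for (int j = 1; j <= M; ++j) {
            double c = AT(dpM, i, j) + endCost[j];
            if (c > best) { best = c; bi = i; bj = j; endInsert = false; }
        }
        double c = AT(dpI, i, M) + ltIM[M];
        if (c > best) { best = c; bi = i; bj = M; endInsert = true; }
    }

    IntegerVector map(M, 0L), ins(M + 1, 0L);
    int envStart = 0, envEnd = 0;
    if (best > NEG / 2) {
        envEnd = bi;
        int i = bi, j = bj;
        int type = endInsert ? 2 : 0; // 0 = M, 1 = D, 2 = I
        bool done = false;
        while (!done) {
            if (type == 0) {
                map[j - 1] = i;
                signed char p = AT(pM, i, j);
                if (p == 3) { envStart = i; done = true; }
                else if (p == 0) { --i; --j; }
                else if (p == 1) { type = 1; --i; --j; }
                else { type = 2; --i; --j; }
            } else if (type == 1) {
                signed char p = AT(pD, i, j);
                if (p == 0) { type = 0; --j; }
                else { --j; }
            } else {
                ins[j] += 1;
                signed char p = AT(pI, i, j);
                if (p == 2) { envStart = i; done = true; }
                else if (p == 0) { type = 0; --i; }
                else { --i; }
            }
        }
    } else {
        best = R_NegInf;
    }
    return List::create(_["score"] = best, _["map"] = map,
                        _["inserts"] = ins, _["envStart"] = envStart,
                        _["envEnd"] = envEnd);
#undef AT
}

// [[Rcpp::export]]
double forward_glocal(NumericMatrix lmOdds, NumericMatrix liOdds,
                      NumericVector ltMM, NumericVector ltMI,
                      NumericVector ltMD, NumericVector ltIM,
                      NumericVector ltII, NumericVector ltDM,
                      NumericVector ltDD, IntegerVector seq) {
    const int M = lmOdds.nrow();
    const int L = seq.size();
    std::vector<double> beginCost, endCost;
    beginEndCosts(ltMM, ltMD, ltDM, ltDD, M, beginCost, endCost);
    const int W = M + 1;
    std::vector<double> dpM((L + 1) * W, NEG), dpI((L + 1) * W, NEG),
        dpD((L + 1) * W, NEG);
#define AT(a, i, j) a[(i) * W + (j)]
    for (int i = 1; i <= L; ++i) {
        int s = seq[i - 1];
        for (int j = 1; j <= M; ++j) {
            double acc = beginCost[j];
            if (i >= 2) {
                if (j >= 2) {
                    acc = lse2(acc, AT(dpM, i - 1, j - 1) + ltMM[j - 1]);
                    acc = lse2(acc, AT(dpD, i - 1, j - 1) + ltDM[j - 1]);
                }
                acc = lse2(acc, AT(dpI, i - 1, j - 1) + ltIM[j - 1]);
            }
            AT(dpM, i, j) = acc <= NEG / 2 ? NEG
                                           : acc + emit(lmOdds, j - 1, s);
        }
        for (int j = 0; j <= M; ++j) {
            double acc = j == 0 ? ltMI[0] : NEG;
            if (i >= 2) {
                if (j >= 1) acc = lse2(acc, AT(dpM, i - 1, j) + ltMI[j]);
                acc = lse2(acc, AT(dpI, i - 1, j) + ltII[j]);
            }
            AT(dpI, i, j) = acc <= NEG / 2 ? NEG : acc + emit(liOdds, j, s);
        }
        for (int j = 2; j <= M; ++j) {
            double acc = lse2(AT(dpM, i, j - 1) + ltMD[j - 1],
                              AT(dpD, i, j - 1) + ltDD[j - 1]);
            AT(dpD, i, j) = acc;
        }
    }
    double total = NEG;
    for (int i = 1; i <= L; ++i) {
        for (int j = 1; j <= M; ++j)
            total = lse2(total, AT(dpM, i, j) + endCost[j]);
        total = lse2(total, AT(dpI, i, M) + ltIM[M]);
    }
    return total <= NEG / 2 ? R_NegInf : total;
#undef AT
}
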