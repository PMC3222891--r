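#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Linear SVM via dual coordinate descent on the L1-loss (hinge) dual,
// the solver used by LIBLINEAR for small dense problems.  The
// intercept is an augmented constant feature, so it is (weakly)
// regularised; kernel entries therefore carry a "+ 1".
//
// Two code paths exist for the leave-one-trial-out engine:
//   * raw features: kernelised dual with the participant's Gram matrix
//     computed once and per-coordinate gradients maintained, so a
//     warm-started leave-one-out refit costs O(epochs * m^2) with
//     m ~ 2 * trials-per-condition;
//   * per-pair z-scoring: primal-style solve on explicitly rescaled
//     training subsets, since fold-dependent scaling invalidates a
//     precomputed Gram matrix.

// ---- primal-representation solver (used for standalone fits and the
// ---- z-scoring path) -------------------------------------------------------

static int dcd_solve_primal(int d, int m, const double* X, const double* y,
                            double C, double tol, int max_epochs,
                            const double* Q, double* alpha, double* w,
                            double* beta, int skip) {
    for (int ep = 0; ep < max_epochs; ++ep) {
        double maxpg = 0.0;
        for (int j = 0; j < m; ++j) {
            if (j == skip) continue;
            const double* xj = X + (size_t)j * d;
            double dec = *beta;
            for (int k = 0; k < d; ++k) dec += w[k] * xj[k];
            const double G = y[j] * dec - 1.0;
            const double a = alpha[j];
            double pg = G;
            if (a <= 0.0 && G > 0.0) pg = 0.0;
            else if (a >= C && G < 0.0) pg = 0.0;
            const double apg = std::fabs(pg);
            if (apg > maxpg) maxpg = apg;
            if (apg > 1e-12) {
                double anew = a - G / Q[j];
                if (anew < 0.0) anew = 0.0;
                else if (anew > C) anew = C;
                const double delta = (anew - a) * y[j];
                if (delta != 0.0) {
                    for (int k = 0; k < d; ++k) w[k] += delta * xj[k];
                    *beta += delta;
                    alpha[j] = anew;
                }
            }
        }
        if (maxpg < tol) return ep + 1;
    }
    return -max_epochs;
}

// [[Rcpp::export]]
List cpp_dcd_fit(NumericMatrix X, NumericVector y, double cost,
                 double tol, int max_epochs, NumericVector alpha0) {
    const int d = X.nrow(), m = X.ncol();
    if ((int)y.size() != m) stop("label length does not match sample count");
    std::vector<double> Q(m), alpha(m, 0.0), w(d, 0.0);
    double beta = 0.0;
    const double* xp = REAL(X);
    for (int j = 0; j < m; ++j) {
        const double* xj = xp + (size_t)j * d;
        double q = 1.0;
        for (int k = 0; k < d; ++k) q += xj[k] * xj[k];
        Q[j] = q;
    }
    if (alpha0.size() == m) {
        for (int j = 0; j < m; ++j) {
            alpha[j] = alpha0[j];
            const double ay = alpha0[j] * y[j];
            if (ay != 0.0) {
                const double* xj = xp + (size_t)j * d;
                for (int k = 0; k < d; ++k) w[k] += ay * xj[k];
                beta += ay;
            }
        }
    }
    int ep = dcd_solve_primal(d, m, xp, REAL(y), cost, tol, max_epochs,
                              Q.data(), alpha.data(), w.data(), &beta, -1);
    return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                        _["b"] = beta,
                        _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                        _["epochs"] = std::abs(ep),
                        _["converged"] = (ep > 0));
}

// ---- kernel-representation solver ------------------------------------------

// K: m x m pair kernel (x_i.x_j + 1), g: maintained gradient
// y_j * dec_j - 1.  alpha/g must be consistent on entry.
static int dcd_solve_kernel(int m, const double* K, const double* y,
                            double C, double tol, int max_epochs,
                            double* alpha, double* g, int skip) {
    for (int ep = 0; ep < max_epochs; ++ep) {
        double maxpg = 0.0;
        for (int j = 0; j < m; ++j) {
            if (j == skip) continue;
            const double G = g[j];
            const double a = alpha[j];
            double pg = G;
            if (a <= 0.0 && G > 0.0) pg = 0.0;
            else if (a >= C && G < 0.0) pg = 0.0;
            const double apg = std::fabs(pg);
            if (apg > maxpg) maxpg = apg;
            if (apg > 1e-12) {
                const double* Kj = K + (size_t)j * m;
                double anew = a - G / Kj[j];
                if (anew < 0.0) anew = 0.0;
                else if (anew > C) anew = C;
                const double dya = (anew - a) * y[j];
                if (dya != 0.0) {
                    for (int i = 0; i < m; ++i) g[i] += dya * y[i] * Kj[i];
                    alpha[j] = anew;
                }
            }
        }
        if (maxpg < tol) return ep + 1;
    }
    return -max_epochs;
}

struct PairModel {
    int a, b;                    // 0-based class indices, a < b
    std::vector<int> idx;        // trial indices in this pair
    std::vector<double> y;       // +1 for class a, -1 for class b
    // raw/kernel path
    std::vector<double> K;       // m x m pair kernel
    std::vector<double> alpha, g;
    // zscore path
    std::vector<double> Z;       // d x m raw sample columns
    std::vector<double> fsum, fss, mu, sd;
    std::vector<double> Zs, Qs, alpha_z, w_z;
    double beta_z;
};

static void zstats(int d, int m, const double* fsum, const double* fss,
                   const double* xdrop, double* mu, double* sd) {
    const double n = xdrop ? (double)(m - 1) : (double)m;
    for (int k = 0; k < d; ++k) {
        double s = fsum[k], ss = fss[k];
        if (xdrop) { s -= xdrop[k]; ss -= xdrop[k] * xdrop[k]; }
        const double mk = s / n;
        double v = (ss - n * mk * mk) / (n - 1.0);
        if (v < 1e-24) v = 1.0;  // constant voxel: centre only
        mu[k] = mk;
        sd[k] = std::sqrt(v);
    }
}

// Engine state reused across permutations for one participant.
struct LotoEngine {
    int d, n, K_classes;
    const double* X;             // d x n
    std::vector<double> G;       // n x n Gram (x_i.x_j + 1), raw path
    bool zscore;
    double C, tol;
    int max_epochs;

    LotoEngine(int d_, int n_, const double* X_, int K_, double C_,
               bool zscore_, double tol_, int maxep)
        : d(d_), n(n_), K_classes(K_), X(X_), zscore(zscore_), C(C_),
          tol(tol_), max_epochs(maxep) {
        if (!zscore) {
            G.resize((size_t)n * n);
            for (int i = 0; i < n; ++i) {
                const double* xi = X + (size_t)i * d;
                for (int j = 0; j <= i; ++j) {
                    const double* xj = X + (size_t)j * d;
                    double s = 1.0;
                    for (int k = 0; k < d; ++k) s += xi[k] * xj[k];
                    G[(size_t)i * n + j] = s;
                    G[(size_t)j * n + i] = s;
                }
            }
        }
    }

    void run(const int* lab, int* pred);
};

void LotoEngine::run(const int* lab, int* pred) {
    std::vector<PairModel> pairs;
    for (int a = 0; a < K_classes; ++a)
        for (int b = a + 1; b < K_classes; ++b) {
            PairModel pm;
            pm.a = a; pm.b = b;
            for (int i = 0; i < n; ++i)
                if (lab[i] == a || lab[i] == b) pm.idx.push_back(i);
            const int m = (int)pm.idx.size();
            if (m < 2) stop("a class pair has fewer than two trials");
            pm.y.resize(m);
            for (int j = 0; j < m; ++j)
                pm.y[j] = (lab[pm.idx[j]] == a) ? 1.0 : -1.0;
            if (!zscore) {
                pm.K.resize((size_t)m * m);
                for (int j = 0; j < m; ++j) {
                    const double* Grow = G.data() + (size_t)pm.idx[j] * n;
                    double* Kj = pm.K.data() + (size_t)j * m;
                    for (int i = 0; i < m; ++i) Kj[i] = Grow[pm.idx[i]];
                }
                pm.alpha.assign(m, 0.0);
                pm.g.assign(m, -1.0);
                dcd_solve_kernel(m, pm.K.data(), pm.y.data(), C, tol,
                                 max_epochs, pm.alpha.data(), pm.g.data(), -1);
            } else {
                pm.Z.resize((size_t)d * m);
                pm.fsum.assign(d, 0.0);
                pm.fss.assign(d, 0.0);
                for (int j = 0; j < m; ++j) {
                    const double* src = X + (size_t)pm.idx[j] * d;
                    double* dst = pm.Z.data() + (size_t)j * d;
                    for (int k = 0; k < d; ++k) {
                        dst[k] = src[k];
                        pm.fsum[k] += src[k];
                        pm.fss[k] += src[k] * src[k];
                    }
                }
                pm.mu.resize(d); pm.sd.resize(d);
                zstats(d, m, pm.fsum.data(), pm.fss.data(), nullptr,
                       pm.mu.data(), pm.sd.data());
                pm.Zs.resize((size_t)d * m);
                pm.Qs.resize(m);
                for (int j = 0; j < m; ++j) {
                    const double* xj = pm.Z.data() + (size_t)j * d;
                    double* zj = pm.Zs.data() + (size_t)j * d;
                    double q = 1.0;
                    for (int k = 0; k < d; ++k) {
                        zj[k] = (xj[k] - pm.mu[k]) / pm.sd[k];
                        q += zj[k] * zj[k];
                    }
                    pm.Qs[j] = q;
                }
                pm.alpha_z.assign(m, 0.0);
                pm.w_z.assign(d, 0.0);
                pm.beta_z = 0.0;
                dcd_solve_primal(d, m, pm.Zs.data(), pm.y.data(), C, tol,
                                 max_epochs, pm.Qs.data(), pm.alpha_z.data(),
                                 pm.w_z.data(), &pm.beta_z, -1);
            }
            pairs.push_back(std::move(pm));
        }

    std::vector<double> walpha, wg, wmu, wsd, wZs, wQs, ww;
    std::vector<int> votes(K_classes);
    std::vector<double> score(K_classes);

    for (int f = 0; f < n; ++f) {
        std::fill(votes.begin(), votes.end(), 0);
        std::fill(score.begin(), score.end(), 0.0);
        for (auto& pm : pairs) {
            const int m = (int)pm.idx.size();
            double dec = 0.0;
            const bool in_pair = (lab[f] == pm.a || lab[f] == pm.b);
            if (!zscore) {
                const double* Grow = G.data() + (size_t)f * n;
                if (!in_pair) {
                    for (int j = 0; j < m; ++j)
                        dec += pm.alpha[j] * pm.y[j] * Grow[pm.idx[j]];
                } else {
                    int pos = -1;
                    for (int j = 0; j < m; ++j)
                        if (pm.idx[j] == f) { pos = j; break; }
                    if (pm.alpha[pos] == 0.0) {
                        // dropped trial is not a support vector: the
                        // remaining dual variables stay optimal, so the
                        // full-pair solution is the exact refit
                        for (int j = 0; j < m; ++j)
                            dec += pm.alpha[j] * pm.y[j] * Grow[pm.idx[j]];
                    } else {
                        walpha = pm.alpha;
                        wg = pm.g;
                        const double dya = -walpha[pos] * pm.y[pos];
                        const double* Kp = pm.K.data() + (size_t)pos * m;
                        for (int i = 0; i < m; ++i) wg[i] += dya * pm.y[i] * Kp[i];
                        walpha[pos] = 0.0;
                        dcd_solve_kernel(m, pm.K.data(), pm.y.data(), C, tol,
                                         max_epochs, walpha.data(), wg.data(),
                                         pos);
                        for (int j = 0; j < m; ++j)
                            dec += walpha[j] * pm.y[j] * Grow[pm.idx[j]];
                    }
                }
            } else {
                if (!in_pair) {
                    dec = pm.beta_z;
                    const double* xf = X + (size_t)f * d;
                    for (int k = 0; k < d; ++k)
                        dec += pm.w_z[k] * (xf[k] - pm.mu[k]) / pm.sd[k];
                } else {
                    int pos = -1;
                    for (int j = 0; j < m; ++j)
                        if (pm.idx[j] == f) { pos = j; break; }
                    // leave-one-out scaling stats, rescale, warm start
                    wmu.resize(d); wsd.resize(d);
                    zstats(d, m, pm.fsum.data(), pm.fss.data(),
                           pm.Z.data() + (size_t)pos * d,
                           wmu.data(), wsd.data());
                    wZs.assign((size_t)d * m, 0.0);
                    wQs.assign(m, 0.0);
                    for (int j = 0; j < m; ++j) {
                        if (j == pos) continue;
                        const double* xj = pm.Z.data() + (size_t)j * d;
                        double* zj = wZs.data() + (size_t)j * d;
                        double q = 1.0;
                        for (int k = 0; k < d; ++k) {
                            zj[k] = (xj[k] - wmu[k]) / wsd[k];
                            q += zj[k] * zj[k];
                        }
                        wQs[j] = q;
                    }
                    walpha = pm.alpha_z;
                    walpha[pos] = 0.0;
                    ww.assign(d, 0.0);
                    double wbeta = 0.0;
                    for (int j = 0; j < m; ++j) {
                        const double ay = walpha[j] * pm.y[j];
                        if (ay != 0.0) {
                            const double* zj = wZs.data() + (size_t)j * d;
                            for (int k = 0; k < d; ++k) ww[k] += ay * zj[k];
                            wbeta += ay;
                        }
                    }
                    dcd_solve_primal(d, m, wZs.data(), pm.y.data(), C, tol,
                                     max_epochs, wQs.data(), walpha.data(),
                                     ww.data(), &wbeta, pos);
                    dec = wbeta;
                    const double* xf = X + (size_t)f * d;
                    for (int k = 0; k < d; ++k)
                        dec += ww[k] * (xf[k] - wmu[k]) / wsd[k];
                }
            }
            const int winner = (dec >= 0.0) ? pm.a : pm.b;
            votes[winner] += 1;
            score[pm.a] += dec;
            score[pm.b] -= dec;
        }
        int best = 0;
        for (int c = 1; c < K_classes; ++c) {
            if (votes[c] > votes[best] ||
                (votes[c] == votes[best] && score[c] > score[best]))
                best = c;
        }
        pred[f] = best;
    }
}

// [[Rcpp::export]]
IntegerVector cpp_loto(NumericMatrix Xt, IntegerVector lab, int K,
                       double cost, bool zscore, double tol, int max_epochs) {
    const int d = Xt.nrow(), n = Xt.ncol();
    if ((int)lab.size() != n) stop("label length does not match trial count");
    std::vector<int> l0(n), p(n);
    for (int i = 0; i < n; ++i) l0[i] = lab[i] - 1;
    LotoEngine eng(d, n, REAL(Xt), K, cost, zscore, tol, max_epochs);
    eng.run(l0.data(), p.data());
    IntegerVector pred(n);
    for (int i = 0; i < n; ++i) pred[i] = p[i] + 1;
    return pred;
}

// Accuracy of the full LOTO analysis for many label vectors (columns
// of `labmat`) against one pattern matrix — the permutation-test inner
// loop.  The Gram matrix is computed once and shared.
// [[Rcpp::export]]
NumericVector cpp_loto_many(NumericMatrix Xt, IntegerMatrix labmat, int K,
                            double cost, bool zscore, double tol,
                            int max_epochs) {
    const int d = Xt.nrow(), n = Xt.ncol();
    if (labmat.nrow() != n) stop("label matrix rows must equal trial count");
    const int P = labmat.ncol();
    NumericVector acc(P);
    LotoEngine eng(d, n, REAL(Xt), K, cost, zscore, tol, max_epochs);
    std::vector<int> l0(n), p(n);
    for (int q = 0; q < P; ++q) {
        for (int i = 0; i < n; ++i) l0[i] = labmat(i, q) - 1;
        eng.run(l0.data(), p.data());
        int hits = 0;
        for (int i = 0; i < n; ++i) hits += (p[i] == l0[i]);
        acc[q] = (double)hits / n;
        if (q % 16 == 15) Rcpp::checkUserInterrupt();
    }
    return acc;
}
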