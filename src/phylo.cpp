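#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning over 4-state nucleotide columns.
//
// The substitution model arrives pre-diagonalized: for a reversible Q with
// stationary distribution pi, Q = A diag(lambda) B where
//   A = diag(1/sqrt(pi)) V,  B = t(V) diag(sqrt(pi)),
// V the orthonormal eigenvectors of the symmetrized matrix. Then
//   P(t) = A diag(exp(lambda t)) B
// with a real spectrum, which is numerically stable for any t >= 0.
//
// Trees come in as ape postorder edge matrices (1-based node ids, root =
// nTip + 1), so every child row is finished before its parent is read.

static void pmat(const double* lambda, const double* A, const double* B,
                 double t, double* P) {
    double e[4];
    for (int k = 0; k < 4; ++k) e[k] = std::exp(lambda[k] * t);
    for (int j = 0; j < 4; ++j) {
        for (int i = 0; i < 4; ++i) {
            double s = 0.0;
            for (int k = 0; k < 4; ++k) s += A[i + 4 * k] * e[k] * B[k + 4 * j];
            // eigen round-off can leave tiny negatives; clamp for probabilities
            P[i + 4 * j] = s < 0.0 ? 0.0 : s;
        }
    }
}

// One column, transition matrices already built (one 4x4 per edge).
static double colLogLik(const int* parent, const int* child, int nEdge,
                        int nTip, int nNodeTotal, const double* Pall,
                        const int* states, const double* pi,
                        std::vector<double>& L) {
    for (int n = nTip; n < nNodeTotal; ++n)
        for (int i = 0; i < 4; ++i) L[4 * n + i] = 1.0;
    double logScale = 0.0;
    for (int e = 0; e < nEdge; ++e) {
        const double* P = Pall + 16 * e;
        int pa = parent[e] - 1, ch = child[e] - 1;
        double vec[4];
        if (ch < nTip) {
            int s = states[ch];
            if (s == 0) {
                // missing tip: partial vector of ones, P rows sum to ~1
                vec[0] = vec[1] = vec[2] = vec[3] = 1.0;
            } else {
                for (int i = 0; i < 4; ++i) vec[i] = P[i + 4 * (s - 1)];
            }
        } else {
            for (int i = 0; i < 4; ++i) {
                double s = 0.0;
                for (int j = 0; j < 4; ++j) s += P[i + 4 * j] * L[4 * ch + j];
                vec[i] = s;
            }
        }
        double mx = 0.0;
        for (int i = 0; i < 4; ++i) {
            L[4 * pa + i] *= vec[i];
            if (L[4 * pa + i] > mx) mx = L[4 * pa + i];
        }
        if (mx > 0.0 && mx < 1e-200) {
            for (int i = 0; i < 4; ++i) L[4 * pa + i] /= mx;
            logScale += std::log(mx);
        }
    }
    int root = nTip; // 0-based id of node nTip+1
    double lik = 0.0;
    for (int i = 0; i < 4; ++i) lik += pi[i] * L[4 * root + i];
    if (lik <= 0.0) return R_NegInf;
    return std::log(lik) + logScale;
}

static void buildP(const NumericVector& elen, double scale, int nEdge,
                   const double* lambda, const double* A, const double* B,
                   std::vector<double>& Pall) {
    for (int e = 0; e < nEdge; ++e) {
        double* P = &Pall[16 * e];
        if (scale == 0.0) {
            for (int i = 0; i < 16; ++i) P[i] = 0.0;
            for (int i = 0; i < 4; ++i) P[i + 4 * i] = 1.0;
        } else {
            pmat(lambda, A, B, elen[e] * scale, P);
        }
    }
}

// [[Rcpp::export(name = ".pruneLogLikCpp")]]
NumericVector pruneLogLikCpp(IntegerMatrix edge, int nTip, int nNodeTotal,
                             NumericVector elen, IntegerMatrix tips,
                             NumericVector pi, NumericVector lambda,
                             NumericMatrix A, NumericMatrix B, double scale) {
    int nEdge = edge.nrow(), nCol = tips.ncol();
    std::vector<int> parent(nEdge), child(nEdge);
    for (int e = 0; e < nEdge; ++e) {
        parent[e] = edge(e, 0);
        child[e] = edge(e, 1);
    }
    std::vector<double> Pall(16 * nEdge);
    buildP(elen, scale, nEdge, lambda.begin(), A.begin(), B.begin(), Pall);
    std::vector<double> L(4 * nNodeTotal);
    std::vector<int> st(nTip);
    NumericVector out(nCol);
    for (int c = 0; c < nCol; ++c) {
        for (int t = 0; t < nTip; ++t) st[t] = tips(t, c);
        out[c] = colLogLik(parent.data(), child.data(), nEdge, nTip,
                           nNodeTotal, Pall.data(), st.data(), pi.begin(), L);
    }
    return out;
}

// Column log-likelihood as a function of the rate scale rho, for the
// all-branches LRT. Golden-section maximization on [0, rhoMax] plus explicit
// checks of both endpoints and the null rho = 1.
// [[Rcpp::export(name = ".rhoLrtCpp")]]
NumericMatrix rhoLrtCpp(IntegerMatrix edge, int nTip, int nNodeTotal,
                        NumericVector elen, IntegerMatrix tips,
                        NumericVector pi, NumericVector lambda,
                        NumericMatrix A, NumericMatrix B, double rhoMax,
                        double tol) {
    int nEdge = edge.nrow(), nCol = tips.ncol();
    std::vector<int> parent(nEdge), child(nEdge);
    for (int e = 0; e < nEdge; ++e) {
        parent[e] = edge(e, 0);
        child[e] = edge(e, 1);
    }
    std::vector<double> L(4 * nNodeTotal), Pall(16 * nEdge);
    std::vector<int> st(nTip);
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    NumericMatrix out(nCol, 3); // rho_hat, logL(rho_hat), logL(1)

    // null P matrices are shared by all columns
    std::vector<double> Pnull(16 * nEdge);
    buildP(elen, 1.0, nEdge, lambda.begin(), A.begin(), B.begin(), Pnull);

    for (int c = 0; c < nCol; ++c) {
        for (int t = 0; t < nTip; ++t) st[t] = tips(t, c);
        double ll1 = colLogLik(parent.data(), child.data(), nEdge, nTip,
                               nNodeTotal, Pnull.data(), st.data(), pi.begin(),
                               L);
        // f(rho)
        auto f = [&](double rho) {
            buildP(elen, rho, nEdge, lambda.begin(), A.begin(), B.begin(),
                   Pall);
            return colLogLik(parent.data(), child.data(), nEdge, nTip,
                             nNodeTotal, Pall.data(), st.data(), pi.begin(),
                             L);
        };
        double a = 0.0, b = rhoMax;
        double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
        double f1 = f(x1), f2 = f(x2);
        while (b - a > tol) {
            if (f1 < f2) {
                a = x1; x1 = x2; f1 = f2;
                x2 = a + gr * (b - a); f2 = f(x2);
            } else {
                b = x2; x2 = x1; f2 = f1;
                x1 = b - gr * (b - a); f1 = f(x1);
            }
        }
        double rho = (a + b) / 2.0;
        double fr = f(rho);
        double f0 = f(0.0);
        double fmaxend = f(rhoMax);
        if (f0 >= fr) { rho = 0.0; fr = f0; }
        if (fmaxend > fr) { rho = rhoMax; fr = fmaxend; }
        if (fr < ll1) { rho = 1.0; fr = ll1; } // optimizer never beats the null
        out(c, 0) = rho;
        out(c, 1) = fr;
        out(c, 2) = ll1;
    }
    return out;
}
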