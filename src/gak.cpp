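#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Log-space dynamic program for the unnormalized Global Alignment Kernel.
//
// Local kernel between scalar observations a and b:
//   d     = -(a - b)^2 / (2 sigma^2)          (<= 0)
//   kappa = e^d / (2 - e^d)                   (in [0, 1], = 1 iff a == b)
// Path sum over all monotone alignments (steps right, down, diagonal):
//   M[i,j] = kappa(x_i, y_j) * (M[i-1,j] + M[i,j-1] + M[i-1,j-1])
// with M[0,0] = 1 and zero borders.  Everything is carried in logs because
// products of hundreds of sub-unity kernels underflow double precision.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log_kappa(double a, double b, double inv2sig2) {
    double diff = a - b;
    double d = -diff * diff * inv2sig2;         // d <= 0
    // log kappa = d - log(2 - e^d) = d - log1p(-expm1(d))
    return d - std::log1p(-std::expm1(d));
}

static inline double lse3(double a, double b, double c) {
    double m = a;
    if (b > m) m = b;
    if (c > m) m = c;
    if (m == NEG_INF) return NEG_INF;
    return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

static double gak_log_core(const double* x, int n, const double* y, int m,
                           double inv2sig2) {
    // two-row DP over log M; row index j runs over y
    std::vector<double> prev(m + 1, NEG_INF), cur(m + 1, NEG_INF);
    prev[0] = 0.0;                               // log M[0,0] = 0
    for (int i = 1; i <= n; ++i) {
        cur[0] = NEG_INF;
        for (int j = 1; j <= m; ++j) {
            double lk = log_kappa(x[i - 1], y[j - 1], inv2sig2);
            cur[j] = lk + lse3(prev[j], cur[j - 1], prev[j - 1]);
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

//' @noRd
// [[Rcpp::export(name = ".gak_log_cpp")]]
double gak_log_cpp(NumericVector x, NumericVector y, double sigma) {
    if (sigma <= 0 || !std::isfinite(sigma))
        stop("sigma must be positive and finite");
    if (x.size() < 1 || y.size() < 1)
        stop("sequences must be non-empty");
    double inv2sig2 = 1.0 / (2.0 * sigma * sigma);
    return gak_log_core(x.begin(), x.size(), y.begin(), y.size(), inv2sig2);
}

// Cross log-kernel matrix between columns of A and columns of B.
// A: n x p (p sequences of length n), B: m x q.  Returns p x q.
// [[Rcpp::export(name = ".gak_cross_log_cpp")]]
NumericMatrix gak_cross_log_cpp(NumericMatrix A, NumericMatrix B, double sigma) {
    if (sigma <= 0 || !std::isfinite(sigma))
        stop("sigma must be positive and finite");
    int n = A.nrow(), p = A.ncol(), m = B.nrow(), q = B.ncol();
    double inv2sig2 = 1.0 / (2.0 * sigma * sigma);
    NumericMatrix out(p, q);
    for (int a = 0; a < p; ++a) {
        const double* xa = &A(0, a);
        for (int b = 0; b < q; ++b) {
            out(a, b) = gak_log_core(xa, n, &B(0, b), m, inv2sig2);
        }
    }
    return out;
}

// Self log-kernels log k(x, x) for every column of A.
// [[Rcpp::export(name = ".gak_self_log_cpp")]]
NumericVector gak_self_log_cpp(NumericMatrix A, double sigma) {
    if (sigma <= 0 || !std::isfinite(sigma))
        stop("sigma must be positive and finite");
    int n = A.nrow(), p = A.ncol();
    double inv2sig2 = 1.0 / (2.0 * sigma * sigma);
    NumericVector out(p);
    for (int a = 0; a < p; ++a)
        out[a] = gak_log_core(&A(0, a), n, &A(0, a), n, inv2sig2);
    return out;
}
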