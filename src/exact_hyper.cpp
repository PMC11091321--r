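#include <Rcpp.h>
#include <vector>
#include <stdexcept>

// Exact-rational enumeration of the hypergeometric upper tail for small N.
//
// Binomial coefficients come from an exact __int128 Pascal triangle; the
// tail numerator sum_{i=k}^{min(K,n)} C(K,i) * C(N-K,n-i) and denominator
// C(N,n) are exact integers (each term is bounded by C(N,n) via the
// Vandermonde identity, so nothing overflows for N <= 120), and the single
// final division is done in long double. This is the small-table reference
// against which the log-space implementation is validated.

static const int MAXN = 120;

static const std::vector<std::vector<__int128>>& pascal() {
  static std::vector<std::vector<__int128>> C;
  if (C.empty()) {
    C.resize(MAXN + 1);
    for (int i = 0; i <= MAXN; ++i) {
      C[i].resize(i + 1);
      C[i][0] = C[i][i] = 1;
      for (int j = 1; j < i; ++j) C[i][j] = C[i - 1][j - 1] + C[i - 1][j];
    }
  }
  return C;
}

static inline __int128 choose(int nn, int kk) {
  if (kk < 0 || kk > nn) return 0;
  return pascal()[nn][kk];
}

// [[Rcpp::export(rng = false)]]
Rcpp::NumericVector hyper_tail_exact_cpp(Rcpp::IntegerVector k,
                                         Rcpp::IntegerVector K,
                                         Rcpp::IntegerVector n,
                                         Rcpp::IntegerVector N) {
  R_xlen_t m = k.size();
  Rcpp::NumericVector out(m);
  for (R_xlen_t t = 0; t < m; ++t) {
    int kk = k[t], KK = K[t], nn = n[t], NN = N[t];
    if (NN < 0 || NN > MAXN || KK < 0 || KK > NN || nn < 0 || nn > NN)
      Rcpp::stop("exact enumeration requires 0 <= K, n <= N <= %d", MAXN);
    int lo = std::max(0, KK + nn - NN);
    int hi = std::min(KK, nn);
    if (kk < lo) kk = lo;               // whole support: p = 1
    if (kk > hi) Rcpp::stop("k exceeds the hypergeometric support");
    __int128 num = 0;
    for (int i = kk; i <= hi; ++i) num += choose(KK, i) * choose(NN - KK, nn - i);
    __int128 den = choose(NN, nn);
    out[t] = (double)((long double)num / (long double)den);
  }
  return out;
}
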