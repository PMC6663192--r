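#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// Exact tail probability of the two-sample Kolmogorov-Smirnov statistic on
// Betti step functions:  P(D_q >= d) = 1 - A_{q,q} / C(2q, q),
// where A_{u,v} counts monotone lattice paths from (0,0) to (u,v) staying
// strictly inside the band |u - v| < d, with A_{u,0} = A_{0,v} = 1 on the
// in-band axes and A_{0,0} = 0.
//
// Both A_{q,q} and C(2q,q) are computed exactly in arbitrary-precision
// integer arithmetic (vectors of base-2^32 limbs): C(2q,q) overflows double
// already at q ~ 514, and the probability must not inherit that overflow.

typedef std::vector<uint64_t> Big;  // little-endian limbs, each < 2^32

static const uint64_t LIMB_MASK = 0xFFFFFFFFULL;

static void big_add_into(Big &a, const Big &b) {  // a += b
  size_t n = std::max(a.size(), b.size());
  a.resize(n, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = a[i] + (i < b.size() ? b[i] : 0) + carry;
    a[i] = s & LIMB_MASK;
    carry = s >> 32;
  }
  if (carry) a.push_back(carry);
}

static void big_mul_small(Big &a, uint64_t m) {  // a *= m, m < 2^32
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t s = a[i] * m + carry;
    a[i] = s & LIMB_MASK;
    carry = s >> 32;
  }
  while (carry) {
    a.push_back(carry & LIMB_MASK);
    carry >>= 32;
  }
}

static bool big_is_zero(const Big &a) {
  for (size_t i = a.size(); i-- > 0;)
    if (a[i]) return false;
  return true;
}

// value ~ mantissa * 2^exp2 with mantissa from the top three limbs
static void big_frexp(const Big &a, long double &mant, long &exp2) {
  size_t n = a.size();
  while (n > 0 && a[n - 1] == 0) --n;
  if (n == 0) {
    mant = 0.0L;
    exp2 = 0;
    return;
  }
  mant = 0.0L;
  int take = (int)std::min<size_t>(3, n);
  for (int i = 0; i < take; ++i)
    mant = mant * 4294967296.0L + (long double)a[n - 1 - i];
  exp2 = (long)(n - take) * 32;
}

// Exact C(2q, q) by Legendre prime factorization.
static Big binom_central(long q) {
  long N = 2 * q;
  std::vector<char> sieve(N + 1, 1);
  Big result(1, 1);
  for (long p = 2; p <= N; ++p) {
    if (!sieve[p]) continue;
    for (long j = 2 * p; j <= N; j += p) sieve[j] = 0;
    long e = 0;
    for (long pk = p; pk <= N; pk *= p) {
      e += N / pk - 2 * (q / pk);
      if (pk > N / p) break;  // avoid overflow of pk * p
    }
    while (e > 0) {
      // multiply by p^chunk keeping the factor below 2^32
      uint64_t f = 1;
      while (e > 0 && f * (uint64_t)p < (1ULL << 32)) {
        f *= (uint64_t)p;
        --e;
      }
      big_mul_small(result, f);
    }
  }
  return result;
}

// [[Rcpp::export(name = ".exact_tail_cpp")]]
double exact_tail_cpp(int q, int d) {
  if (q < 1) Rcpp::stop("q must be >= 1");
  if (d <= 0) return 1.0;
  if (d > q) return 0.0;

  // Row-by-row recursion, keeping only the previous row. Cells outside the
  // band stay empty (zero).
  std::vector<Big> prev(q + 1), cur(q + 1);
  // row u = 0: A_{0,0} = 0; A_{0,v} = 1 while v < d, 0 beyond.
  for (int v = 1; v <= q && v < d; ++v) prev[v] = Big(1, 1);

  for (int u = 1; u <= q; ++u) {
    int lo = std::max(0, u - d + 1), hi = std::min(q, u + d - 1);
    for (int v = 0; v <= q; ++v) cur[v].clear();
    for (int v = lo; v <= hi; ++v) {
      if (v == 0) {
        if (u < d) cur[0] = Big(1, 1);  // in-band axis boundary
        continue;
      }
      // interior: A_{u-1,v} + A_{u,v-1}; out-of-band neighbours are empty
      Big s = prev[v];
      big_add_into(s, cur[v - 1]);
      cur[v] = std::move(s);
    }
    std::swap(prev, cur);
    if ((u & 255) == 0) Rcpp::checkUserInterrupt();
  }

  const Big &A = prev[q];
  if (big_is_zero(A)) return 1.0;
  Big C = binom_central(q);

  long double mA, mC;
  long eA, eC;
  big_frexp(A, mA, eA);
  big_frexp(C, mC, eC);
  long double ratio = (mA / mC) * std::pow(2.0L, (long double)(eA - eC));
  double p = (double)(1.0L - ratio);
  if (p < 0) p = 0;
  if (p > 1) p = 1;
  return p;
}
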