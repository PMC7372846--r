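// RNS-CKKS core: negacyclic NTT arithmetic over machine-prime chains,
// canonical-embedding encoder, and the scheme operations (key generation,
// encryption, add/mult/rotate, rescaling, decomposition + special-modulus
// key switching).  Polynomials are stored coefficient-wise per RNS prime;
// switching keys are kept in NTT form since they are only used pointwise.
//
// Basis convention: ctx.primes[0] is the special prime p0; ctx.primes[1..L]
// are the level primes q_0..q_{L-1}.  A ciphertext at level l lives over
// rows q_0..q_{l-1}; valid levels are 1..L.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <complex>
#include <cmath>

using namespace Rcpp;

typedef uint64_t u64;
typedef int64_t i64;
typedef unsigned __int128 u128;
typedef __int128 i128;

// ---------------------------------------------------------------- mod arith

static inline u64 addmod(u64 a, u64 b, u64 q) { u64 s = a + b; return s >= q ? s - q : s; }
static inline u64 submod(u64 a, u64 b, u64 q) { return a >= b ? a - b : a + q - b; }
static inline u64 mulmod(u64 a, u64 b, u64 q) { return (u64)(((u128)a * b) % q); }

static u64 powmod(u64 a, u64 e, u64 q) {
  u64 r = 1; a %= q;
  while (e) { if (e & 1) r = mulmod(r, a, q); a = mulmod(a, a, q); e >>= 1; }
  return r;
}
static inline u64 invmod(u64 a, u64 q) { return powmod(a, q - 2, q); } // q prime

// deterministic Miller-Rabin for 64-bit integers
static bool is_prime_u64(u64 n) {
  if (n < 2) return false;
  for (u64 p : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    if (n % p == 0) return n == p;
  }
  u64 d = n - 1; int r = 0;
  while ((d & 1) == 0) { d >>= 1; ++r; }
  for (u64 a : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    u64 x = powmod(a % n, d, n);
    if (x == 1 || x == n - 1) continue;
    bool comp = true;
    for (int i = 1; i < r; ++i) {
      x = mulmod(x, x, n);
      if (x == n - 1) { comp = false; break; }
    }
    if (comp) return false;
  }
  return true;
}

// ---------------------------------------------------------------- RNG
// Self-contained seedable generator (splitmix-initialised xoshiro-style via
// std::mt19937_64 would be fine too, but we avoid distribution objects whose
// streams are implementation-defined).

struct Rng {
  u64 s[4];
  explicit Rng(u64 seed) {
    // splitmix64 expansion
    u64 z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      u64 t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline u64 rotl(u64 x, int k) { return (x << k) | (x >> (64 - k)); }
  u64 next() { // xoshiro256**
    u64 r = rotl(s[1] * 5, 7) * 9;
    u64 t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  u64 uniform_mod(u64 q) { // rejection sampling, unbiased
    u64 lim = UINT64_MAX - (UINT64_MAX % q);
    u64 x;
    do { x = next(); } while (x >= lim);
    return x % q;
  }
  int ternary() { // uniform over {-1,0,1}
    return (int)uniform_mod(3) - 1;
  }
  double unif01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // rounded continuous Gaussian, stdev sigma (discrete-Gaussian stand-in,
  // Box-Muller so the stream is platform-independent)
  i64 gauss(double sigma) {
    double u1 = unif01(), u2 = unif01();
    if (u1 < 1e-300) u1 = 1e-300;
    double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
    return (i64)std::llround(sigma * z);
  }
};

// ---------------------------------------------------------------- NTT tables

struct NttTab {
  u64 q;
  int N, logN;
  std::vector<u64> psis, ipsis; // bit-reversed powers of psi (2N-th root)
  u64 Ninv;
};

static int bitrev(int x, int bits) {
  int r = 0;
  for (int i = 0; i < bits; ++i) { r = (r << 1) | (x & 1); x >>= 1; }
  return r;
}

static void build_tab(NttTab& T, u64 q, int logN) {
  int N = 1 << logN;
  T.q = q; T.N = N; T.logN = logN;
  u64 twoN = (u64)N << 1;
  if ((q - 1) % twoN != 0) stop("prime not NTT-friendly for this ring dimension");
  // find a primitive 2N-th root of unity
  u64 psi = 0;
  for (u64 h = 2;; ++h) {
    u64 cand = powmod(h, (q - 1) / twoN, q);
    if (powmod(cand, (u64)N, q) == q - 1) { psi = cand; break; }
    if (h > 1000) stop("no 2N-th root found");
  }
  T.psis.resize(N); T.ipsis.resize(N);
  u64 ipsi = invmod(psi, q);
  u64 p = 1, ip = 1;
  std::vector<u64> pw(N), ipw(N);
  for (int i = 0; i < N; ++i) { pw[i] = p; ipw[i] = ip; p = mulmod(p, psi, q); ip = mulmod(ip, ipsi, q); }
  for (int i = 0; i < N; ++i) {
    T.psis[i] = pw[bitrev(i, logN)];
    T.ipsis[i] = ipw[bitrev(i, logN)];
  }
  T.Ninv = invmod((u64)N, q);
}

static void ntt_fwd(std::vector<u64>& a, size_t off, const NttTab& T) {
  const u64 q = T.q; const int N = T.N;
  int t = N;
  for (int m = 1; m < N; m <<= 1) {
    t >>= 1;
    for (int i = 0; i < m; ++i) {
      u64 S = T.psis[m + i];
      size_t j1 = off + (size_t)2 * i * t, j2 = j1 + t;
      for (size_t j = j1; j < j2; ++j) {
        u64 U = a[j], V = mulmod(a[j + t], S, q);
        a[j] = addmod(U, V, q);
        a[j + t] = submod(U, V, q);
      }
    }
  }
}

static void ntt_inv(std::vector<u64>& a, size_t off, const NttTab& T) {
  const u64 q = T.q; const int N = T.N;
  int t = 1;
  for (int m = N; m > 1; m >>= 1) {
    size_t j1 = off;
    int h = m >> 1;
    for (int i = 0; i < h; ++i) {
      u64 S = T.ipsis[h + i];
      size_t j2 = j1 + t;
      for (size_t j = j1; j < j2; ++j) {
        u64 U = a[j], V = a[j + t];
        a[j] = addmod(U, V, q);
        a[j + t] = mulmod(submod(U, V, q), S, q);
      }
      j1 += (size_t)2 * t;
    }
    t <<= 1;
  }
  for (int j = 0; j < N; ++j) a[off + j] = mulmod(a[off + j], T.Ninv, q);
}

// ---------------------------------------------------------------- context

struct Ctx {
  int logN, N, N2;
  int L;                       // number of level primes
  std::vector<u64> primes;     // [0] special, [1..L] level primes
  std::vector<NttTab> tab;
  std::vector<std::vector<u64>> pinv; // pinv[i][j] = primes[i]^{-1} mod primes[j]
  std::vector<int> rotpow;     // 5^j mod 2N for j = 0..N2-1
  // FFT twiddles for encode/decode
  std::vector<std::complex<double>> fftw; // exp(2 pi i k / N), k=0..N-1
  std::vector<std::complex<double>> zeta; // exp(i pi k / N),  k=0..N-1
  std::vector<int> slot_t;     // slot j -> FFT index t with 2t+1 = 5^j mod 2N
};

static u64 prime_from(int bits, double delta) {
  long double v = std::ldexp((long double)1.0, bits) + (long double)delta;
  return (u64)v;
}

// [[Rcpp::export]]
SEXP cpp_ctx_new(int logN, IntegerVector bits, NumericVector delta) {
  if (bits.size() != delta.size()) stop("bits/delta length mismatch");
  Ctx* c = new Ctx();
  c->logN = logN; c->N = 1 << logN; c->N2 = c->N >> 1;
  int np = bits.size();
  c->L = np - 1;
  c->primes.resize(np);
  c->tab.resize(np);
  for (int i = 0; i < np; ++i) {
    c->primes[i] = prime_from(bits[i], delta[i]);
    build_tab(c->tab[i], c->primes[i], logN);
  }
  c->pinv.assign(np, std::vector<u64>(np, 0));
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < np; ++j)
      if (i != j) c->pinv[i][j] = invmod(c->primes[i] % c->primes[j], c->primes[j]);
  int twoN = c->N << 1;
  c->rotpow.resize(c->N2);
  long long g = 1;
  for (int j = 0; j < c->N2; ++j) { c->rotpow[j] = (int)g; g = (g * 5) % twoN; }
  c->fftw.resize(c->N); c->zeta.resize(c->N);
  for (int k = 0; k < c->N; ++k) {
    c->fftw[k] = std::polar(1.0, 2.0 * M_PI * k / c->N);
    c->zeta[k] = std::polar(1.0, M_PI * k / c->N);
  }
  c->slot_t.resize(c->N2);
  for (int j = 0; j < c->N2; ++j) c->slot_t[j] = (c->rotpow[j] - 1) / 2;
  return XPtr<Ctx>(c, true);
}

// [[Rcpp::export]]
NumericVector cpp_ctx_prime_log2(SEXP ctxp) {
  XPtr<Ctx> c(ctxp);
  NumericVector out(c->primes.size());
  for (size_t i = 0; i < c->primes.size(); ++i) out[i] = std::log2((double)c->primes[i]);
  return out;
}

// [[Rcpp::export]]
int cpp_ctx_nslots(SEXP ctxp) { XPtr<Ctx> c(ctxp); return c->N2; }

// outward scan for NTT-friendly primes near 2^bits, nearest first
// [[Rcpp::export]]
NumericVector cpp_scan_primes(int bits, int logN, int count, NumericVector avoid) {
  u64 twoN = (u64)1 << (logN + 1);
  long double base = std::ldexp((long double)1.0, bits);
  std::vector<double> found;
  // candidates are base + d with d == 1 (mod 2N) offset; base is divisible by 2N
  // (bits > logN+1), so candidate = 2^bits + (1 + k*2N) or 2^bits - (2N - 1) - k*2N.
  i64 step = (i64)twoN;
  for (i64 k = 0; (int)found.size() < count; ++k) {
    i64 cand_deltas[2] = { 1 + k * step, 1 - (k + 1) * step };
    for (i64 d : cand_deltas) {
      if ((int)found.size() >= count) break;
      long double v = base + (long double)d;
      if (v < 3) continue;
      u64 p = (u64)v;
      if (!is_prime_u64(p)) continue;
      bool used = false;
      for (double a : avoid) if ((i64)a == d) { used = true; break; }
      for (double a : found) if ((i64)a == d) { used = true; break; }
      if (used) continue;
      found.push_back((double)d);
    }
    if (k > 100000000LL) stop("no NTT-friendly prime of the requested size exists near 2^bits");
  }
  return wrap(found);
}

// [[Rcpp::export]]
bool cpp_is_prime(int bits, double delta) { return is_prime_u64(prime_from(bits, delta)); }

// ---------------------------------------------------------------- polys

struct Poly {
  int nb; // rows
  std::vector<u64> c; // nb * N
};

struct Ct { Poly c0, c1; };
struct Ext { Poly d0, d1, d2; };
struct Sk { std::vector<i64> s; };
struct Pk { Poly b, a; };                 // rows over level primes 1..L
struct Swk { std::vector<Poly> b, a; };   // per component, rows over full basis 0..L, NTT form

static Poly poly_zero(const Ctx& c, int nb) {
  Poly p; p.nb = nb; p.c.assign((size_t)nb * c.N, 0); return p;
}

// reduce small signed coeffs into row representation
static void row_from_signed(const Ctx& c, std::vector<u64>& row, size_t off,
                            const std::vector<i64>& v, u64 q) {
  for (int k = 0; k < c.N; ++k) {
    i64 x = v[k] % (i64)q;
    if (x < 0) x += (i64)q;
    row[off + k] = (u64)x;
  }
}

// negacyclic product of two rows (coeff domain in, coeff domain out)
static void row_mult(const Ctx& c, int pi, const u64* a, const u64* b, u64* out) {
  const NttTab& T = c.tab[pi];
  std::vector<u64> ta(a, a + c.N), tb(b, b + c.N);
  ntt_fwd(ta, 0, T); ntt_fwd(tb, 0, T);
  for (int k = 0; k < c.N; ++k) ta[k] = mulmod(ta[k], tb[k], T.q);
  ntt_inv(ta, 0, T);
  std::copy(ta.begin(), ta.end(), out);
}

// prime index for ciphertext row r (rows are level primes)
static inline int rowp(int r) { return r + 1; }

// ---------------------------------------------------------------- encode / decode

static void fft_inplace(std::vector<std::complex<double>>& a, const Ctx& c, bool inverse) {
  int n = a.size();
  int lg = 0; while ((1 << lg) < n) ++lg;
  for (int i = 0; i < n; ++i) {
    int j = bitrev(i, lg);
    if (j > i) std::swap(a[i], a[j]);
  }
  for (int len = 2; len <= n; len <<= 1) {
    int stride = c.N / len; // twiddle stride into fftw (length N table)
    for (int i = 0; i < n; i += len) {
      for (int j = 0; j < len / 2; ++j) {
        std::complex<double> w = c.fftw[(size_t)j * stride];
        if (inverse) w = std::conj(w);
        std::complex<double> u = a[i + j], v = a[i + j + len / 2] * w;
        a[i + j] = u + v;
        a[i + j + len / 2] = u - v;
      }
    }
  }
  if (inverse) for (auto& x : a) x /= n;
}

// scaled coefficients in two 40-bit limbs: value = hi * 2^40 + lo, so scales
// up to ~2^100 keep exact residues (the sub-integer encoding error stays at
// the long-double precision, far below the scheme noise)
struct BigCoeffs { std::vector<i64> hi, lo; };

static BigCoeffs encode_slots(const Ctx& c, const NumericVector& vals, double scale) {
  if ((int)vals.size() > c.N2) stop("slot vector longer than N/2");
  std::vector<std::complex<double>> full(c.N, 0.0);
  for (int j = 0; j < (int)vals.size(); ++j) {
    int t = c.slot_t[j];
    full[t] = std::complex<double>(vals[j], 0.0);
    full[c.N - 1 - t] = std::complex<double>(vals[j], 0.0); // conjugate slot (real)
  }
  fft_inplace(full, c, true); // inverse DFT -> b_k = m_k zeta^k
  BigCoeffs m;
  m.hi.resize(c.N); m.lo.resize(c.N);
  const long double base = 1099511627776.0L; // 2^40
  for (int k = 0; k < c.N; ++k) {
    double re = (full[k] * std::conj(c.zeta[k])).real();
    long double sc = (long double)re * (long double)scale;
    if (std::fabs((double)(sc / base)) > 4.6e18)
      stop("encoded coefficient overflows the supported scale; rescale first");
    long double h = std::floor(sc / base);
    long double l = sc - h * base;          // in [0, 2^40)
    m.hi[k] = (i64)h;
    m.lo[k] = (i64)std::llround((double)l);
  }
  return m;
}

// residues of hi * 2^40 + lo modulo q
static void row_from_big(const Ctx& c, std::vector<u64>& row, const BigCoeffs& m, u64 q) {
  u64 base_q = ((u128)1 << 40) % q;
  for (int k = 0; k < c.N; ++k) {
    i64 h = m.hi[k] % (i64)q; if (h < 0) h += (i64)q;
    i64 l = m.lo[k] % (i64)q; if (l < 0) l += (i64)q;
    row[k] = addmod(mulmod((u64)h, base_q, q), (u64)l, q);
  }
}

static NumericVector decode_coeffs(const Ctx& c, const std::vector<long double>& m,
                                   long double scale, int nvals) {
  std::vector<std::complex<double>> b(c.N);
  for (int k = 0; k < c.N; ++k) {
    double v = (double)(m[k] / scale);
    b[k] = std::complex<double>(v, 0.0) * c.zeta[k];
  }
  fft_inplace(b, c, false);
  NumericVector out(nvals);
  for (int j = 0; j < nvals; ++j) out[j] = b[c.slot_t[j]].real();
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_encode_roundtrip(SEXP ctxp, NumericVector vals, double scale) {
  XPtr<Ctx> c(ctxp);
  BigCoeffs m = encode_slots(*c, vals, scale);
  std::vector<long double> md(c->N);
  const long double base = 1099511627776.0L;
  for (int k = 0; k < c->N; ++k) md[k] = (long double)m.hi[k] * base + (long double)m.lo[k];
  return decode_coeffs(*c, md, (long double)scale, vals.size());
}

// ---------------------------------------------------------------- keys

// [[Rcpp::export]]
SEXP cpp_sk_gen(SEXP ctxp, double seed) {
  XPtr<Ctx> c(ctxp);
  Rng rng((u64)seed);
  Sk* sk = new Sk();
  sk->s.resize(c->N);
  for (int k = 0; k < c->N; ++k) sk->s[k] = rng.ternary();
  return XPtr<Sk>(sk, true);
}

// [[Rcpp::export]]
IntegerVector cpp_sk_coeffs(SEXP skp) {
  XPtr<Sk> sk(skp);
  return wrap(std::vector<int>(sk->s.begin(), sk->s.end()));
}

// [[Rcpp::export]]
SEXP cpp_sk_const(SEXP ctxp, IntegerVector coeffs) {
  XPtr<Ctx> c(ctxp);
  if ((int)coeffs.size() != c->N) stop("secret length must be N");
  Sk* sk = new Sk();
  sk->s.assign(coeffs.begin(), coeffs.end());
  return XPtr<Sk>(sk, true);
}

// [[Rcpp::export]]
SEXP cpp_pk_gen(SEXP ctxp, SEXP skp, double seed) {
  XPtr<Ctx> c(ctxp); XPtr<Sk> sk(skp);
  Rng rng((u64)seed);
  Pk* pk = new Pk();
  pk->a = poly_zero(*c, c->L);
  pk->b = poly_zero(*c, c->L);
  std::vector<i64> e(c->N);
  for (int k = 0; k < c->N; ++k) e[k] = rng.gauss(3.2);
  // sample a uniform over R_{Q_L} (independent residues via CRT bijection)
  std::vector<std::vector<u64>> arows(c->L, std::vector<u64>(c->N));
  for (int r = 0; r < c->L; ++r)
    for (int k = 0; k < c->N; ++k) arows[r][k] = rng.uniform_mod(c->primes[rowp(r)]);
  for (int r = 0; r < c->L; ++r) {
    int pi = rowp(r);
    u64 q = c->primes[pi];
    std::vector<u64> srow(c->N);
    row_from_signed(*c, srow, 0, sk->s, q);
    std::vector<u64> as(c->N);
    row_mult(*c, pi, arows[r].data(), srow.data(), as.data());
    for (int k = 0; k < c->N; ++k) {
      i64 ev = e[k] % (i64)q; if (ev < 0) ev += (i64)q;
      pk->b.c[(size_t)r * c->N + k] = addmod(submod(0, as[k], q), (u64)ev, q);
      pk->a.c[(size_t)r * c->N + k] = arows[r][k];
    }
  }
  return XPtr<Pk>(pk, true);
}

// centered residues of b + a*s (should equal the small error polynomial);
// returns max abs value, or -1 if rows disagree (relation violated)
// [[Rcpp::export]]
double cpp_pk_error(SEXP ctxp, SEXP pkp, SEXP skp) {
  XPtr<Ctx> c(ctxp); XPtr<Pk> pk(pkp); XPtr<Sk> sk(skp);
  std::vector<i64> ref(c->N);
  double mx = 0;
  for (int r = 0; r < c->L; ++r) {
    int pi = rowp(r);
    u64 q = c->primes[pi];
    std::vector<u64> srow(c->N); row_from_signed(*c, srow, 0, sk->s, q);
    std::vector<u64> as(c->N);
    row_mult(*c, pi, pk->a.c.data() + (size_t)r * c->N, srow.data(), as.data());
    for (int k = 0; k < c->N; ++k) {
      u64 v = addmod(pk->b.c[(size_t)r * c->N + k], as[k], q);
      i64 ce = (v > q / 2) ? (i64)v - (i64)q : (i64)v;
      if (r == 0) { ref[k] = ce; if (std::fabs((double)ce) > mx) mx = std::fabs((double)ce); }
      else if (ce != ref[k]) return -1.0;
    }
  }
  return mx;
}

// switching key KSGen(s1, s2): components i = 0..L-1, rows over full basis.
static Swk* ksgen_core(const Ctx& c, const std::vector<i64>& s1, const std::vector<i64>& s2,
                       Rng& rng) {
  Swk* sw = new Swk();
  int np = c.L + 1;
  sw->b.resize(c.L); sw->a.resize(c.L);
  // NTT(s2) per basis prime, reused
  std::vector<std::vector<u64>> s2ntt(np, std::vector<u64>(c.N));
  for (int j = 0; j < np; ++j) {
    row_from_signed(c, s2ntt[j], 0, s2, c.primes[j]);
    ntt_fwd(s2ntt[j], 0, c.tab[j]);
  }
  for (int i = 0; i < c.L; ++i) {
    sw->b[i] = poly_zero(c, np);
    sw->a[i] = poly_zero(c, np);
    std::vector<i64> e(c.N);
    for (int k = 0; k < c.N; ++k) e[k] = rng.gauss(3.2);
    for (int j = 0; j < np; ++j) {
      u64 q = c.primes[j];
      const NttTab& T = c.tab[j];
      size_t off = (size_t)j * c.N;
      // a sampled directly in NTT form (uniform either way)
      for (int k = 0; k < c.N; ++k) sw->a[i].c[off + k] = rng.uniform_mod(q);
      // payload: e + [j == i+1] * p0 * s1   (p0*B_i == delta_{ij} p0 mod q_j, 0 mod p0)
      std::vector<u64> pay(c.N);
      u64 p0q = c.primes[0] % q;
      for (int k = 0; k < c.N; ++k) {
        i64 ev = e[k] % (i64)q; if (ev < 0) ev += (i64)q;
        u64 v = (u64)ev;
        if (j == i + 1) {
          i64 sv = s1[k] % (i64)q; if (sv < 0) sv += (i64)q;
          v = addmod(v, mulmod(p0q, (u64)sv, q), q);
        }
        pay[k] = v;
      }
      ntt_fwd(pay, 0, T);
      for (int k = 0; k < c.N; ++k)
        sw->b[i].c[off + k] = submod(pay[k], mulmod(sw->a[i].c[off + k], s2ntt[j][k], q), q);
    }
  }
  return sw;
}

// [[Rcpp::export]]
SEXP cpp_ksgen(SEXP ctxp, SEXP sk1p, SEXP sk2p, double seed) {
  XPtr<Ctx> c(ctxp); XPtr<Sk> s1(sk1p); XPtr<Sk> s2(sk2p);
  Rng rng((u64)seed);
  return XPtr<Swk>(ksgen_core(*c, s1->s, s2->s, rng), true);
}

// evaluation key: KSGen(s^2, s)
// [[Rcpp::export]]
SEXP cpp_evk_gen(SEXP ctxp, SEXP skp, double seed) {
  XPtr<Ctx> c(ctxp); XPtr<Sk> sk(skp);
  Rng rng((u64)seed);
  // s^2 over the integers (negacyclic), coefficients bounded by N
  std::vector<i64> s2(c->N, 0);
  for (int i = 0; i < c->N; ++i) {
    if (sk->s[i] == 0) continue;
    for (int j = 0; j < c->N; ++j) {
      if (sk->s[j] == 0) continue;
      int k = i + j;
      i64 v = (i64)sk->s[i] * sk->s[j];
      if (k >= c->N) { k -= c->N; v = -v; }
      s2[k] += v;
    }
  }
  return XPtr<Swk>(ksgen_core(*c, s2, sk->s, rng), true);
}

// automorphism X -> X^g on small signed coefficients
static std::vector<i64> auto_signed(const Ctx& c, const std::vector<i64>& v, int g) {
  std::vector<i64> out(c.N, 0);
  int twoN = c.N << 1;
  for (int k = 0; k < c.N; ++k) {
    long long e = ((long long)k * g) % twoN;
    if (e < c.N) out[e] += v[k];
    else out[e - c.N] -= v[k];
  }
  return out;
}

// rotation key for amount r: KSGen(s(X^g), s), g = 5^r mod 2N
// [[Rcpp::export]]
SEXP cpp_rotkey_gen(SEXP ctxp, SEXP skp, int r, double seed) {
  XPtr<Ctx> c(ctxp); XPtr<Sk> sk(skp);
  Rng rng((u64)seed);
  int rr = ((r % c->N2) + c->N2) % c->N2;
  int g = c->rotpow[rr];
  std::vector<i64> s1 = auto_signed(*c, sk->s, g);
  return XPtr<Swk>(ksgen_core(*c, s1, sk->s, rng), true);
}

// error check: b_i + a_i s2 - p0 B_i s1 should be small and consistent mod all primes
// [[Rcpp::export]]
double cpp_swk_error(SEXP ctxp, SEXP swkp, SEXP sk1p, SEXP sk2p) {
  XPtr<Ctx> c(ctxp); XPtr<Swk> sw(swkp); XPtr<Sk> s1(sk1p); XPtr<Sk> s2(sk2p);
  int np = c->L + 1;
  double mx = 0;
  for (int i = 0; i < c->L; ++i) {
    std::vector<i64> ref(c->N);
    for (int j = 0; j < np; ++j) {
      u64 q = c->primes[j];
      const NttTab& T = c->tab[j];
      std::vector<u64> b(sw->b[i].c.begin() + (size_t)j * c->N,
                         sw->b[i].c.begin() + (size_t)(j + 1) * c->N);
      std::vector<u64> a(sw->a[i].c.begin() + (size_t)j * c->N,
                         sw->a[i].c.begin() + (size_t)(j + 1) * c->N);
      std::vector<u64> s2row(c->N); row_from_signed(*c, s2row, 0, s2->s, q);
      ntt_fwd(s2row, 0, T);
      for (int k = 0; k < c->N; ++k) b[k] = addmod(b[k], mulmod(a[k], s2row[k], q), q);
      ntt_inv(b, 0, T);
      u64 p0q = c->primes[0] % q;
      for (int k = 0; k < c->N; ++k) {
        u64 sub = 0;
        if (j == i + 1) {
          i64 sv = s1->s[k] % (i64)q; if (sv < 0) sv += (i64)q;
          sub = mulmod(p0q, (u64)sv, q);
        }
        u64 v = submod(b[k], sub, q);
        i64 ce = (v > q / 2) ? (i64)v - (i64)q : (i64)v;
        if (j == 0) { ref[k] = ce; if (std::fabs((double)ce) > mx) mx = std::fabs((double)ce); }
        else if (ce != ref[k]) return -1.0;
      }
    }
  }
  return mx;
}

// ---------------------------------------------------------------- enc / dec

// [[Rcpp::export]]
SEXP cpp_encrypt(SEXP ctxp, SEXP pkp, NumericVector vals, int lev, double scale, double seed) {
  XPtr<Ctx> c(ctxp); XPtr<Pk> pk(pkp);
  if (lev < 1 || lev > c->L) stop("level out of range");
  Rng rng((u64)seed);
  BigCoeffs m = encode_slots(*c, vals, scale);
  std::vector<i64> v(c->N), e0(c->N), e1(c->N);
  for (int k = 0; k < c->N; ++k) {
    v[k] = rng.ternary();
    e0[k] = rng.gauss(3.2);
    e1[k] = rng.gauss(3.2);
  }
  Ct* ct = new Ct();
  ct->c0 = poly_zero(*c, lev);
  ct->c1 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    int pi = rowp(r);
    u64 q = c->primes[pi];
    std::vector<u64> vrow(c->N); row_from_signed(*c, vrow, 0, v, q);
    std::vector<u64> mrow(c->N); row_from_big(*c, mrow, m, q);
    std::vector<u64> t0(c->N), t1(c->N);
    row_mult(*c, pi, vrow.data(), pk->b.c.data() + (size_t)r * c->N, t0.data());
    row_mult(*c, pi, vrow.data(), pk->a.c.data() + (size_t)r * c->N, t1.data());
    for (int k = 0; k < c->N; ++k) {
      i64 e0v = e0[k] % (i64)q; if (e0v < 0) e0v += (i64)q;
      i64 ev = e1[k] % (i64)q; if (ev < 0) ev += (i64)q;
      u64 mv = addmod(mrow[k], (u64)e0v, q);
      ct->c0.c[(size_t)r * c->N + k] = addmod(t0[k], mv, q);
      ct->c1.c[(size_t)r * c->N + k] = addmod(t1[k], (u64)ev, q);
    }
  }
  return XPtr<Ct>(ct, true);
}

static Ct* moddown_core(const Ctx& c, const Ct& ct, int lev, int target) {
  Ct* out = new Ct();
  out->c0.nb = target; out->c1.nb = target;
  out->c0.c.assign(ct.c0.c.begin(), ct.c0.c.begin() + (size_t)target * c.N);
  out->c1.c.assign(ct.c1.c.begin(), ct.c1.c.begin() + (size_t)target * c.N);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_mod_down(SEXP ctxp, SEXP ctp, int lev, int target) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp);
  if (target > lev || target < 1) stop("mod_down target out of range");
  return XPtr<Ct>(moddown_core(*c, *ct, lev, target), true);
}

// [[Rcpp::export]]
NumericVector cpp_decrypt(SEXP ctxp, SEXP ctp, SEXP skp, int lev, double scale, int nvals) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp); XPtr<Sk> sk(skp);
  const Ct* use = ct;
  Ct* tmp = nullptr;
  int ulev = lev;
  if (lev > 2) { tmp = moddown_core(*c, *ct, lev, 2); use = tmp; ulev = 2; }
  // phase = c0 + c1 * s per row
  std::vector<std::vector<u64>> ph(ulev, std::vector<u64>(c->N));
  for (int r = 0; r < ulev; ++r) {
    int pi = rowp(r);
    u64 q = c->primes[pi];
    std::vector<u64> srow(c->N); row_from_signed(*c, srow, 0, sk->s, q);
    std::vector<u64> cs(c->N);
    row_mult(*c, pi, use->c1.c.data() + (size_t)r * c->N, srow.data(), cs.data());
    for (int k = 0; k < c->N; ++k)
      ph[r][k] = addmod(use->c0.c[(size_t)r * c->N + k], cs[k], q);
  }
  std::vector<long double> m(c->N);
  if (ulev == 1) {
    u64 q = c->primes[1];
    for (int k = 0; k < c->N; ++k) {
      u64 v = ph[0][k];
      m[k] = (v > q / 2) ? (long double)v - (long double)q : (long double)v;
    }
  } else {
    u64 q0 = c->primes[1], q1 = c->primes[2];
    u64 q0inv = c->pinv[1][2];
    i128 Q = (i128)q0 * q1;
    for (int k = 0; k < c->N; ++k) {
      u64 x0 = ph[0][k], x1 = ph[1][k];
      u64 d = submod(x1, x0 % q1, q1);
      u64 y = mulmod(d, q0inv, q1);
      i64 yc = (y > q1 / 2) ? (i64)y - (i64)q1 : (i64)y;
      i128 v = (i128)x0 + (i128)q0 * yc;
      if (v > Q / 2) v -= Q;
      if (v < -Q / 2) v += Q;
      m[k] = (long double)v;
    }
  }
  if (tmp) delete tmp;
  return decode_coeffs(*c, m, (long double)scale, nvals);
}

// ---------------------------------------------------------------- arithmetic

// [[Rcpp::export]]
SEXP cpp_add(SEXP ctxp, SEXP ap, SEXP bp, int lev, bool sub) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> a(ap); XPtr<Ct> b(bp);
  Ct* out = new Ct();
  out->c0 = poly_zero(*c, lev); out->c1 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    u64 q = c->primes[rowp(r)];
    size_t off = (size_t)r * c->N;
    for (int k = 0; k < c->N; ++k) {
      if (!sub) {
        out->c0.c[off + k] = addmod(a->c0.c[off + k], b->c0.c[off + k], q);
        out->c1.c[off + k] = addmod(a->c1.c[off + k], b->c1.c[off + k], q);
      } else {
        out->c0.c[off + k] = submod(a->c0.c[off + k], b->c0.c[off + k], q);
        out->c1.c[off + k] = submod(a->c1.c[off + k], b->c1.c[off + k], q);
      }
    }
  }
  return XPtr<Ct>(out, true);
}

// [[Rcpp::export]]
SEXP cpp_negate(SEXP ctxp, SEXP ap, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> a(ap);
  Ct* out = new Ct();
  out->c0 = poly_zero(*c, lev); out->c1 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    u64 q = c->primes[rowp(r)];
    size_t off = (size_t)r * c->N;
    for (int k = 0; k < c->N; ++k) {
      out->c0.c[off + k] = submod(0, a->c0.c[off + k], q);
      out->c1.c[off + k] = submod(0, a->c1.c[off + k], q);
    }
  }
  return XPtr<Ct>(out, true);
}

// [[Rcpp::export]]
SEXP cpp_raw_mult(SEXP ctxp, SEXP ap, SEXP bp, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> a(ap); XPtr<Ct> b(bp);
  Ext* out = new Ext();
  out->d0 = poly_zero(*c, lev); out->d1 = poly_zero(*c, lev); out->d2 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    int pi = rowp(r);
    const NttTab& T = c->tab[pi];
    u64 q = T.q;
    size_t off = (size_t)r * c->N;
    std::vector<u64> a0(a->c0.c.begin() + off, a->c0.c.begin() + off + c->N);
    std::vector<u64> a1(a->c1.c.begin() + off, a->c1.c.begin() + off + c->N);
    std::vector<u64> b0(b->c0.c.begin() + off, b->c0.c.begin() + off + c->N);
    std::vector<u64> b1(b->c1.c.begin() + off, b->c1.c.begin() + off + c->N);
    ntt_fwd(a0, 0, T); ntt_fwd(a1, 0, T); ntt_fwd(b0, 0, T); ntt_fwd(b1, 0, T);
    std::vector<u64> d0(c->N), d1(c->N), d2(c->N);
    for (int k = 0; k < c->N; ++k) {
      d0[k] = mulmod(a0[k], b0[k], q);
      d1[k] = addmod(mulmod(a0[k], b1[k], q), mulmod(a1[k], b0[k], q), q);
      d2[k] = mulmod(a1[k], b1[k], q);
    }
    ntt_inv(d0, 0, T); ntt_inv(d1, 0, T); ntt_inv(d2, 0, T);
    std::copy(d0.begin(), d0.end(), out->d0.c.begin() + off);
    std::copy(d1.begin(), d1.end(), out->d1.c.begin() + off);
    std::copy(d2.begin(), d2.end(), out->d2.c.begin() + off);
  }
  return XPtr<Ext>(out, true);
}

// [[Rcpp::export]]
SEXP cpp_ext_add(SEXP ctxp, SEXP ap, SEXP bp, int lev, bool sub) {
  XPtr<Ctx> c(ctxp); XPtr<Ext> a(ap); XPtr<Ext> b(bp);
  Ext* out = new Ext();
  out->d0 = poly_zero(*c, lev); out->d1 = poly_zero(*c, lev); out->d2 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    u64 q = c->primes[rowp(r)];
    size_t off = (size_t)r * c->N;
    for (int k = 0; k < c->N; ++k) {
      if (!sub) {
        out->d0.c[off + k] = addmod(a->d0.c[off + k], b->d0.c[off + k], q);
        out->d1.c[off + k] = addmod(a->d1.c[off + k], b->d1.c[off + k], q);
        out->d2.c[off + k] = addmod(a->d2.c[off + k], b->d2.c[off + k], q);
      } else {
        out->d0.c[off + k] = submod(a->d0.c[off + k], b->d0.c[off + k], q);
        out->d1.c[off + k] = submod(a->d1.c[off + k], b->d1.c[off + k], q);
        out->d2.c[off + k] = submod(a->d2.c[off + k], b->d2.c[off + k], q);
      }
    }
  }
  return XPtr<Ext>(out, true);
}

// core of KeySwitch: given target poly d (coeff domain, lev rows), compute
// round(p0^{-1} * sum_i d_i * swk_i), returning the (b, a) pair over lev rows.
static void keyswitch_core(const Ctx& c, const Poly& d, const Swk& sw, int lev,
                           Poly& out0, Poly& out1) {
  int nb = lev + 1; // extended basis: row 0 = p0, rows 1..lev = q_0..q_{lev-1}
  std::vector<std::vector<u64>> acc0(nb, std::vector<u64>(c.N, 0));
  std::vector<std::vector<u64>> acc1(nb, std::vector<u64>(c.N, 0));
  for (int i = 0; i < lev; ++i) {
    const u64* di = d.c.data() + (size_t)i * c.N; // residues mod q_i, values < q_i
    for (int j = 0; j < nb; ++j) {
      u64 q = c.primes[j]; // j==0 special, else q_{j-1}
      const NttTab& T = c.tab[j];
      std::vector<u64> t(c.N);
      for (int k = 0; k < c.N; ++k) t[k] = di[k] % q;
      ntt_fwd(t, 0, T);
      const u64* bi = sw.b[i].c.data() + (size_t)j * c.N;
      const u64* ai = sw.a[i].c.data() + (size_t)j * c.N;
      for (int k = 0; k < c.N; ++k) {
        acc0[j][k] = addmod(acc0[j][k], mulmod(t[k], bi[k], q), q);
        acc1[j][k] = addmod(acc1[j][k], mulmod(t[k], ai[k], q), q);
      }
    }
  }
  for (int j = 0; j < nb; ++j) ntt_inv(acc0[j], 0, c.tab[j]);
  for (int j = 0; j < nb; ++j) ntt_inv(acc1[j], 0, c.tab[j]);
  // divide by p0 with rounding: subtract centered residue mod p0, then
  // multiply by p0^{-1} mod each q_j
  out0 = poly_zero(c, lev); out1 = poly_zero(c, lev);
  u64 p0 = c.primes[0];
  for (int j = 1; j <= lev; ++j) {
    u64 q = c.primes[j];
    u64 p0inv = c.pinv[0][j];
    for (int k = 0; k < c.N; ++k) {
      { // b component
        u64 r0 = acc0[0][k];
        i64 rc = (r0 > p0 / 2) ? (i64)r0 - (i64)p0 : (i64)r0;
        i64 rq = rc % (i64)q; if (rq < 0) rq += (i64)q;
        u64 v = submod(acc0[j][k], (u64)rq, q);
        out0.c[(size_t)(j - 1) * c.N + k] = mulmod(v, p0inv, q);
      }
      { // a component
        u64 r0 = acc1[0][k];
        i64 rc = (r0 > p0 / 2) ? (i64)r0 - (i64)p0 : (i64)r0;
        i64 rq = rc % (i64)q; if (rq < 0) rq += (i64)q;
        u64 v = submod(acc1[j][k], (u64)rq, q);
        out1.c[(size_t)(j - 1) * c.N + k] = mulmod(v, p0inv, q);
      }
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_relinearize(SEXP ctxp, SEXP extp, SEXP evkp, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ext> e(extp); XPtr<Swk> evk(evkp);
  Ct* out = new Ct();
  Poly k0, k1;
  keyswitch_core(*c, e->d2, *evk, lev, k0, k1);
  out->c0 = poly_zero(*c, lev); out->c1 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    u64 q = c->primes[rowp(r)];
    size_t off = (size_t)r * c->N;
    for (int k = 0; k < c->N; ++k) {
      out->c0.c[off + k] = addmod(e->d0.c[off + k], k0.c[off + k], q);
      out->c1.c[off + k] = addmod(e->d1.c[off + k], k1.c[off + k], q);
    }
  }
  return XPtr<Ct>(out, true);
}

// generic key switch of a ciphertext (c0, c1) valid under the source secret
// [[Rcpp::export]]
SEXP cpp_keyswitch(SEXP ctxp, SEXP ctp, SEXP swkp, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp); XPtr<Swk> sw(swkp);
  Ct* out = new Ct();
  Poly k0, k1;
  keyswitch_core(*c, ct->c1, *sw, lev, k0, k1);
  out->c0 = poly_zero(*c, lev); out->c1 = k1;
  for (int r = 0; r < lev; ++r) {
    u64 q = c->primes[rowp(r)];
    size_t off = (size_t)r * c->N;
    for (int k = 0; k < c->N; ++k)
      out->c0.c[off + k] = addmod(ct->c0.c[off + k], k0.c[off + k], q);
  }
  return XPtr<Ct>(out, true);
}

// true if c1 is identically zero (key switch is exact identity then)
// [[Rcpp::export]]
bool cpp_c1_is_zero(SEXP ctxp, SEXP ctp, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp);
  for (size_t k = 0; k < (size_t)lev * c->N; ++k) if (ct->c1.c[k] != 0) return false;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_rescale(SEXP ctxp, SEXP ctp, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp);
  if (lev < 2) stop("no level left to rescale");
  int nl = lev - 1;
  int dpi = rowp(lev - 1); // prime being divided out
  u64 qd = c->primes[dpi];
  Ct* out = new Ct();
  out->c0 = poly_zero(*c, nl); out->c1 = poly_zero(*c, nl);
  for (int r = 0; r < nl; ++r) {
    int pi = rowp(r);
    u64 q = c->primes[pi];
    u64 qdinv = c->pinv[dpi][pi];
    size_t off = (size_t)r * c->N, doff = (size_t)(lev - 1) * c->N;
    for (int k = 0; k < c->N; ++k) {
      { u64 rd = ct->c0.c[doff + k];
        i64 rc = (rd > qd / 2) ? (i64)rd - (i64)qd : (i64)rd;
        i64 rq = rc % (i64)q; if (rq < 0) rq += (i64)q;
        out->c0.c[off + k] = mulmod(submod(ct->c0.c[off + k], (u64)rq, q), qdinv, q); }
      { u64 rd = ct->c1.c[doff + k];
        i64 rc = (rd > qd / 2) ? (i64)rd - (i64)qd : (i64)rd;
        i64 rq = rc % (i64)q; if (rq < 0) rq += (i64)q;
        out->c1.c[off + k] = mulmod(submod(ct->c1.c[off + k], (u64)rq, q), qdinv, q); }
    }
  }
  return XPtr<Ct>(out, true);
}

// multiply by an encoded plaintext (constant vector at the given scale)
// [[Rcpp::export]]
SEXP cpp_cmult(SEXP ctxp, SEXP ctp, NumericVector vals, int lev, double cscale) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp);
  BigCoeffs m = encode_slots(*c, vals, cscale);
  Ct* out = new Ct();
  out->c0 = poly_zero(*c, lev); out->c1 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    int pi = rowp(r);
    u64 q = c->primes[pi];
    std::vector<u64> mrow(c->N); row_from_big(*c, mrow, m, q);
    size_t off = (size_t)r * c->N;
    row_mult(*c, pi, ct->c0.c.data() + off, mrow.data(), out->c0.c.data() + off);
    row_mult(*c, pi, ct->c1.c.data() + off, mrow.data(), out->c1.c.data() + off);
  }
  return XPtr<Ct>(out, true);
}

// add an encoded plaintext to c0
// [[Rcpp::export]]
SEXP cpp_add_plain(SEXP ctxp, SEXP ctp, NumericVector vals, int lev, double scale) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp);
  BigCoeffs m = encode_slots(*c, vals, scale);
  Ct* out = new Ct();
  out->c0 = ct->c0; out->c1 = ct->c1;
  for (int r = 0; r < lev; ++r) {
    u64 q = c->primes[rowp(r)];
    size_t off = (size_t)r * c->N;
    std::vector<u64> mrow(c->N); row_from_big(*c, mrow, m, q);
    for (int k = 0; k < c->N; ++k) {
      out->c0.c[off + k] = addmod(out->c0.c[off + k], mrow[k], q);
    }
  }
  return XPtr<Ct>(out, true);
}

// trivial (noiseless, keyless) encryption of an encoded constant: (m, 0)
// [[Rcpp::export]]
SEXP cpp_trivial_encrypt(SEXP ctxp, NumericVector vals, int lev, double scale) {
  XPtr<Ctx> c(ctxp);
  BigCoeffs m = encode_slots(*c, vals, scale);
  Ct* ct = new Ct();
  ct->c0 = poly_zero(*c, lev); ct->c1 = poly_zero(*c, lev);
  for (int r = 0; r < lev; ++r) {
    u64 q = c->primes[rowp(r)];
    size_t off = (size_t)r * c->N;
    std::vector<u64> mrow(c->N);
    row_from_big(*c, mrow, m, q);
    std::copy(mrow.begin(), mrow.end(), ct->c0.c.begin() + off);
  }
  return XPtr<Ct>(ct, true);
}

// rotation: apply X -> X^{5^r} to both components, then switch the key back
// [[Rcpp::export]]
SEXP cpp_rotate(SEXP ctxp, SEXP ctp, SEXP rotkeyp, int r, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> ct(ctp); XPtr<Swk> sw(rotkeyp);
  int rr = ((r % c->N2) + c->N2) % c->N2;
  if (rr == 0) { Ct* out = new Ct(); out->c0 = ct->c0; out->c1 = ct->c1; return XPtr<Ct>(out, true); }
  int g = c->rotpow[rr];
  int twoN = c->N << 1;
  Ct tmp; tmp.c0 = poly_zero(*c, lev); tmp.c1 = poly_zero(*c, lev);
  for (int row = 0; row < lev; ++row) {
    u64 q = c->primes[rowp(row)];
    size_t off = (size_t)row * c->N;
    for (int k = 0; k < c->N; ++k) {
      long long e = ((long long)k * g) % twoN;
      u64 v0 = ct->c0.c[off + k], v1 = ct->c1.c[off + k];
      if (e < c->N) {
        tmp.c0.c[off + e] = v0;
        tmp.c1.c[off + e] = v1;
      } else {
        tmp.c0.c[off + e - c->N] = submod(0, v0, q);
        tmp.c1.c[off + e - c->N] = submod(0, v1, q);
      }
    }
  }
  Ct* out = new Ct();
  Poly k0, k1;
  keyswitch_core(*c, tmp.c1, *sw, lev, k0, k1);
  out->c0 = poly_zero(*c, lev); out->c1 = k1;
  for (int row = 0; row < lev; ++row) {
    u64 q = c->primes[rowp(row)];
    size_t off = (size_t)row * c->N;
    for (int k = 0; k < c->N; ++k)
      out->c0.c[off + k] = addmod(tmp.c0.c[off + k], k0.c[off + k], q);
  }
  return XPtr<Ct>(out, true);
}

// ---------------------------------------------------------------- test helpers

// [[Rcpp::export]]
bool cpp_ntt_roundtrip(SEXP ctxp, double seed) {
  XPtr<Ctx> c(ctxp);
  Rng rng((u64)seed);
  for (size_t pi = 0; pi < c->primes.size(); ++pi) {
    const NttTab& T = c->tab[pi];
    std::vector<u64> v(c->N), w;
    for (int k = 0; k < c->N; ++k) v[k] = rng.uniform_mod(T.q);
    w = v;
    ntt_fwd(w, 0, T);
    ntt_inv(w, 0, T);
    if (w != v) return false;
  }
  return true;
}

// exact ciphertext equality (bit-level)
// [[Rcpp::export]]
bool cpp_ct_equal(SEXP ctxp, SEXP ap, SEXP bp, int lev) {
  XPtr<Ctx> c(ctxp); XPtr<Ct> a(ap); XPtr<Ct> b(bp);
  size_t n = (size_t)lev * c->N;
  for (size_t k = 0; k < n; ++k)
    if (a->c0.c[k] != b->c0.c[k] || a->c1.c[k] != b->c1.c[k]) return false;
  return true;
}
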