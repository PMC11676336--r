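// Window -> sampled-index rules for the built-in minimizer-type schemes,
// shared between exact enumeration (one window at a time) and empirical
// density on long sequences (millions of windows).
//
// Hash order: h = seed; for each symbol c: h = splitmix64(h ^ (c+1)).
// Ties in hash are broken by the string itself (lexicographic), then by the
// leftmost position.  The splitmix64 constants are fixed so results are
// reproducible across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash_seq(const int* s, int len, uint64_t seed) {
  uint64_t h = seed;
  for (int i = 0; i < len; ++i) h = splitmix64(h ^ (uint64_t)(s[i] + 1));
  return h;
}

// lexicographic comparison of equal-length substrings at a and b
static inline int lex_cmp(const int* s, int a, int b, int len) {
  for (int i = 0; i < len; ++i) {
    if (s[a + i] != s[b + i]) return s[a + i] < s[b + i] ? -1 : 1;
  }
  return 0;
}

// scheme ids (kept in sync with R/schemes.R)
enum SchemeId {
  SCHEME_RANDOM = 1,
  SCHEME_LEX = 2,
  SCHEME_MOD = 3,
  SCHEME_MINICEPTION = 4,
  SCHEME_DECYCLING = 5
};

struct Precomp {
  std::vector<uint64_t> khash;        // per k-mer position
  std::vector<uint64_t> thash;        // per t-mer position
  std::vector<unsigned char> kclass;  // decycling class 0/1/2 per k-mer
  std::vector<unsigned char> preferred; // miniception flag per k-mer
};

// true if k-mer at a precedes k-mer at b under (hash, lex) order
static inline bool kmer_less_hash(const int* s, const Precomp& pc, int a, int b, int k) {
  if (pc.khash[a] != pc.khash[b]) return pc.khash[a] < pc.khash[b];
  return lex_cmp(s, a, b, k) < 0;
}

static inline bool tmer_less(const int* s, const Precomp& pc, int a, int b, int t) {
  if (pc.thash[a] != pc.thash[b]) return pc.thash[a] < pc.thash[b];
  return lex_cmp(s, a, b, t) < 0;
}

// (class, hash, lex) order for the double-decycling scheme
static inline bool kmer_less_decycling(const int* s, const Precomp& pc, int a, int b, int k) {
  if (pc.kclass[a] != pc.kclass[b]) return pc.kclass[a] < pc.kclass[b];
  if (pc.khash[a] != pc.khash[b]) return pc.khash[a] < pc.khash[b];
  return lex_cmp(s, a, b, k) < 0;
}

static void precompute(const int* s, int L, int w, int k, int scheme,
                       uint64_t seed, int t, Precomp& pc) {
  int nk = L - k + 1;
  if (scheme == SCHEME_RANDOM || scheme == SCHEME_MINICEPTION || scheme == SCHEME_DECYCLING) {
    pc.khash.resize(nk);
    for (int i = 0; i < nk; ++i) pc.khash[i] = hash_seq(s + i, k, seed);
  }
  if (scheme == SCHEME_MOD || scheme == SCHEME_MINICEPTION) {
    int nt = L - t + 1;
    pc.thash.resize(nt);
    for (int i = 0; i < nt; ++i) pc.thash[i] = hash_seq(s + i, t, seed);
  }
  if (scheme == SCHEME_DECYCLING) {
    // Mykkeltveit embedding P(u) = sum_j u_j * exp(2*pi*i*j/k).  Rotating u
    // left multiplies P by conj(omega), so the k rotations of an aperiodic
    // k-mer sweep the k sectors and Mykkeltveit's crossing rule picks the
    // unique rotation whose embedding is about to cross the positive real
    // axis: class 0 iff P != 0, Im(P) <= 0 and Im(P*omega) > 0; class 1 the
    // same for -P (the mirrored decycling set); class 2 everything else,
    // including P == 0 (e.g. homopolymers).
    pc.kclass.resize(nk);
    std::vector<double> cs(k), sn(k);
    const double TWOPI = 2.0 * M_PI;
    for (int j = 0; j < k; ++j) {
      cs[j] = std::cos(TWOPI * j / k);
      sn[j] = std::sin(TWOPI * j / k);
    }
    const double cw = std::cos(TWOPI / k), sw = std::sin(TWOPI / k);
    const double EPS = 1e-9;
    for (int i = 0; i < nk; ++i) {
      double re = 0.0, im = 0.0;
      for (int j = 0; j < k; ++j) {
        re += s[i + j] * cs[j];
        im += s[i + j] * sn[j];
      }
      unsigned char cls = 2;
      if (re * re + im * im > 1e-18) {
        double im_rot = re * sw + im * cw;   // Im(P * omega)
        if (im <= EPS && im_rot > EPS) cls = 0;
        else if (-im <= EPS && -im_rot > EPS) cls = 1;
      }
      pc.kclass[i] = cls;
    }
  }
  if (scheme == SCHEME_MINICEPTION) {
    // a k-mer is "preferred" when its leftmost-minimal t-mer sits at
    // offset 0 or k - t
    int nk2 = L - k + 1;
    pc.preferred.resize(nk2);
    for (int i = 0; i < nk2; ++i) {
      int best = i;
      for (int p = i + 1; p <= i + k - t; ++p) {
        if (tmer_less(s, pc, p, best, t)) best = p;
      }
      pc.preferred[i] = (best == i || best == i + k - t) ? 1 : 0;
    }
  }
}

// selected k-mer index (in [0, w)) for the window starting at j
static int choose_index(const int* s, const Precomp& pc, int j,
                        int w, int k, int scheme, int t) {
  switch (scheme) {
  case SCHEME_RANDOM: {
    int best = j;
    for (int i = j + 1; i < j + w; ++i)
      if (kmer_less_hash(s, pc, i, best, k)) best = i;
    return best - j;
  }
  case SCHEME_LEX: {
    int best = j;
    for (int i = j + 1; i < j + w; ++i)
      if (lex_cmp(s, i, best, k) < 0) best = i;
    return best - j;
  }
  case SCHEME_MOD: {
    // leftmost-minimal t-mer among the w + k - t t-mers of the window
    int nt = w + k - t;
    int best = j;
    for (int p = j + 1; p < j + nt; ++p)
      if (tmer_less(s, pc, p, best, t)) best = p;
    return (best - j) % w;
  }
  case SCHEME_MINICEPTION: {
    int best = -1;
    for (int i = j; i < j + w; ++i) {
      if (!pc.preferred[i]) continue;
      if (best < 0 || kmer_less_hash(s, pc, i, best, k)) best = i;
    }
    if (best < 0) { // no preferred k-mer: plain random-minimizer choice
      best = j;
      for (int i = j + 1; i < j + w; ++i)
        if (kmer_less_hash(s, pc, i, best, k)) best = i;
    }
    return best - j;
  }
  case SCHEME_DECYCLING: {
    int best = j;
    for (int i = j + 1; i < j + w; ++i)
      if (kmer_less_decycling(s, pc, i, best, k)) best = i;
    return best - j;
  }
  }
  stop("unknown scheme id");
  return 0;
}

// [[Rcpp::export]]
int cpp_scheme_index(IntegerVector window, int w, int k, int scheme,
                     double seed, int t) {
  if (window.size() != w + k - 1) stop("window must have length w + k - 1");
  Precomp pc;
  const int* s = INTEGER(window);
  precompute(s, window.size(), w, k, scheme, (uint64_t)seed, t, pc);
  return choose_index(s, pc, 0, w, k, scheme, t);
}

// [[Rcpp::export]]
IntegerVector cpp_select_positions(IntegerVector seq, int w, int k, int scheme,
                                   double seed, int t) {
  int L = seq.size();
  int span = w + k - 1;
  if (L < span) return IntegerVector(0);
  const int* s = INTEGER(seq);
  Precomp pc;
  precompute(s, L, w, k, scheme, (uint64_t)seed, t, pc);
  int nwin = L - span + 1;
  std::vector<int> sel;
  sel.reserve(nwin / std::max(1, w / 2) + 16);
  int last = -1;
  for (int j = 0; j < nwin; ++j) {
    int idx = choose_index(s, pc, j, w, k, scheme, t);
    int pos = j + idx;
    if (pos != last) { sel.push_back(pos); last = pos; }
  }
  std::sort(sel.begin(), sel.end());
  sel.erase(std::unique(sel.begin(), sel.end()), sel.end());
  return IntegerVector(sel.begin(), sel.end());
}

// [[Rcpp::export]]
std::string cpp_hash64_hex(IntegerVector s, double seed) {
  uint64_t h = hash_seq(INTEGER(s), s.size(), (uint64_t)seed);
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
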