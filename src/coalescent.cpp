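// Hudson-style neutral coalescent with recombination.
//
// Lineages carry ancestral material as sorted disjoint segments of the
// unit interval [0,1); each segment knows the set of sampled sequences
// descending from it (a bitset). Coalescence occurs at rate k(k-1)/2,
// recombination at rate (rho/2) * sum of lineage span lengths (span =
// distance between a lineage's leftmost and rightmost ancestral
// endpoints, as in Hudson's ms). Mutations follow a Poisson process at
// rate (theta/2) * total ancestral length, placed uniformly on
// ancestral material under the infinite-sites model; a mutation's
// carriers are the descendant set of the segment it lands on. Segments
// whose descendant set reaches the full sample have found their local
// MRCA and are dropped.
//
// Randomness comes from R's RNG, so set.seed() gives full determinism.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::vector<uint64_t> Bits;

struct Seg {
  double a, b;
  Bits s;
};

struct Lin {
  std::vector<Seg> segs;
  double span() const { return segs.back().b - segs.front().a; }
  double anclen() const {
    double t = 0.0;
    for (size_t i = 0; i < segs.size(); ++i) t += segs[i].b - segs[i].a;
    return t;
  }
};

struct Mut {
  double pos;
  Bits s;
};

static inline bool bitsFull(const Bits &s, int n) {
  int full = n / 64, rem = n % 64;
  for (int w = 0; w < full; ++w)
    if (s[w] != ~0ULL) return false;
  if (rem) {
    uint64_t mask = (1ULL << rem) - 1ULL;
    if ((s[full] & mask) != mask) return false;
  }
  return true;
}

static inline bool sameBits(const Bits &x, const Bits &y) {
  for (size_t w = 0; w < x.size(); ++w)
    if (x[w] != y[w]) return false;
  return true;
}

static inline int popcountBits(const Bits &s) {
  int c = 0;
  for (size_t w = 0; w < s.size(); ++w) {
    uint64_t v = s[w];
    while (v) { v &= v - 1; ++c; }
  }
  return c;
}

// union of the segment lists of two coalescing lineages; segments whose
// merged descendant set is the full sample are dropped (local MRCA)
static Lin mergeLin(const Lin &A, const Lin &B, int n, int W) {
  std::vector<double> bp;
  bp.reserve(2 * (A.segs.size() + B.segs.size()));
  for (size_t i = 0; i < A.segs.size(); ++i) {
    bp.push_back(A.segs[i].a);
    bp.push_back(A.segs[i].b);
  }
  for (size_t i = 0; i < B.segs.size(); ++i) {
    bp.push_back(B.segs[i].a);
    bp.push_back(B.segs[i].b);
  }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  Lin out;
  size_t ia = 0, ib = 0;
  for (size_t t = 0; t + 1 < bp.size(); ++t) {
    double lo = bp[t], hi = bp[t + 1];
    double mid = 0.5 * (lo + hi);
    while (ia < A.segs.size() && A.segs[ia].b <= mid) ++ia;
    while (ib < B.segs.size() && B.segs[ib].b <= mid) ++ib;
    bool inA = ia < A.segs.size() && A.segs[ia].a <= mid;
    bool inB = ib < B.segs.size() && B.segs[ib].a <= mid;
    if (!inA && !inB) continue;
    Bits u(W, 0ULL);
    if (inA)
      for (int w = 0; w < W; ++w) u[w] |= A.segs[ia].s[w];
    if (inB)
      for (int w = 0; w < W; ++w) u[w] |= B.segs[ib].s[w];
    if (bitsFull(u, n)) continue;
    if (!out.segs.empty() && out.segs.back().b == lo &&
        sameBits(out.segs.back().s, u)) {
      out.segs.back().b = hi;  // coalesce contiguous identical pieces
    } else {
      Seg sg;
      sg.a = lo;
      sg.b = hi;
      sg.s = u;
      out.segs.push_back(sg);
    }
  }
  return out;
}

// split a lineage at breakpoint x into left (kept in place) and right
static void splitLin(Lin &L, double x, Lin &right) {
  std::vector<Seg> left;
  for (size_t i = 0; i < L.segs.size(); ++i) {
    Seg &sg = L.segs[i];
    if (sg.b <= x) {
      left.push_back(sg);
    } else if (sg.a >= x) {
      right.segs.push_back(sg);
    } else {
      Seg l = sg, r = sg;
      l.b = x;
      r.a = x;
      left.push_back(l);
      right.segs.push_back(r);
    }
  }
  L.segs.swap(left);
}

// one replicate; mutations appended to muts
static void simulateRep(int n, double theta, double rho,
                        std::vector<Mut> &muts) {
  int W = (n + 63) / 64;
  std::vector<Lin> lins(n);
  for (int i = 0; i < n; ++i) {
    Seg sg;
    sg.a = 0.0;
    sg.b = 1.0;
    sg.s.assign(W, 0ULL);
    sg.s[i / 64] = 1ULL << (i % 64);
    lins[i].segs.push_back(sg);
  }
  while (lins.size() >= 2) {
    int k = (int)lins.size();
    double spanSum = 0.0, Ltot = 0.0;
    for (int i = 0; i < k; ++i) {
      spanSum += lins[i].span();
      Ltot += lins[i].anclen();
    }
    double crate = 0.5 * (double)k * (k - 1);
    double rrate = 0.5 * rho * spanSum;
    double rate = crate + rrate;
    double dt = R::rexp(1.0 / rate);
    if (theta > 0.0 && Ltot > 0.0) {
      int nm = (int)R::rpois(0.5 * theta * dt * Ltot);
      for (int m = 0; m < nm; ++m) {
        double u = R::unif_rand() * Ltot;
        double acc = 0.0;
        bool placed = false;
        for (int i = 0; i < k && !placed; ++i) {
          for (size_t j = 0; j < lins[i].segs.size(); ++j) {
            double len = lins[i].segs[j].b - lins[i].segs[j].a;
            if (u < acc + len) {
              Mut mu;
              mu.pos = lins[i].segs[j].a + (u - acc);
              mu.s = lins[i].segs[j].s;
              muts.push_back(mu);
              placed = true;
              break;
            }
            acc += len;
          }
        }
      }
    }
    if (R::unif_rand() * rate < crate) {
      int i = (int)(R::unif_rand() * k);
      if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1));
      if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      Lin merged = mergeLin(lins[i], lins[j], n, W);
      int hi = std::max(i, j), lo = std::min(i, j);
      lins.erase(lins.begin() + hi);
      lins.erase(lins.begin() + lo);
      if (!merged.segs.empty()) lins.push_back(merged);
    } else {
      double u = R::unif_rand() * spanSum;
      double acc = 0.0;
      int pick = k - 1;
      for (int i = 0; i < k; ++i) {
        if (u < acc + lins[i].span()) {
          pick = i;
          break;
        }
        acc += lins[i].span();
      }
      double lo = lins[pick].segs.front().a;
      double hi = lins[pick].segs.back().b;
      double x = R::runif(lo, hi);
      if (x > lo && x < hi) {
        Lin right;
        splitLin(lins[pick], x, right);
        if (lins[pick].segs.empty()) lins[pick].segs.swap(right.segs);
        else if (!right.segs.empty()) lins.push_back(right);
      }
    }
  }
}

// [[Rcpp::export(name = ".simCoalescentCpp")]]
List simCoalescentCpp(int n, double theta, double rho, int reps) {
  if (n < 2) stop("n must be >= 2");
  if (theta < 0 || rho < 0) stop("theta and rho must be >= 0");
  if (reps < 1) stop("reps must be >= 1");
  List out(reps);
  for (int r = 0; r < reps; ++r) {
    std::vector<Mut> muts;
    simulateRep(n, theta, rho, muts);
    std::vector<int> ord(muts.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(), [&muts](int a, int b) {
      return muts[a].pos < muts[b].pos;
    });
    int S = (int)muts.size();
    NumericVector pos(S);
    IntegerMatrix hap(n, S);
    for (int c = 0; c < S; ++c) {
      const Mut &mu = muts[ord[c]];
      pos[c] = mu.pos;
      for (int i = 0; i < n; ++i)
        hap(i, c) = (mu.s[i / 64] >> (i % 64)) & 1ULL ? 1 : 0;
    }
    out[r] = List::create(Named("positions") = pos,
                          Named("haplotypes") = hap);
  }
  return out;
}

// Per-replicate Tajima's D under the neutral model (NA when S = 0),
// computed directly from derived-allele counts for speed.
// [[Rcpp::export(name = ".simTajimaDCpp")]]
NumericVector simTajimaDCpp(int n, double theta, double rho, int reps) {
  if (n < 4) stop("n must be >= 4 for Tajima's D");
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i < n; ++i) {
    a1 += 1.0 / i;
    a2 += 1.0 / ((double)i * i);
  }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double npairs = 0.5 * n * (n - 1.0);

  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    std::vector<Mut> muts;
    simulateRep(n, theta, rho, muts);
    int S = (int)muts.size();
    if (S == 0) {
      out[r] = NA_REAL;
      continue;
    }
    double pi = 0.0;
    for (int m = 0; m < S; ++m) {
      int c = popcountBits(muts[m].s);
      pi += (double)c * (n - c);
    }
    pi /= npairs;
    double varD = e1 * S + e2 * (double)S * (S - 1.0);
    out[r] = (pi - S / a1) / std::sqrt(varD);
  }
  return out;
}
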