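#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// 2-bit base encoding: A=0, C=1, G=2, T=3.  Callers substitute ambiguous
// bases before hashing, so anything else is a hard error.
static inline int base_code(char b) {
  switch (b) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline void check_k(int k) {
  if (k < 2 || k > 15) stop("k must be in [2, 15]");
}

// [[Rcpp::export]]
int cpp_hash_kmer(std::string kmer) {
  int k = (int) kmer.size();
  if (k < 1 || k > 15) stop("k-mer length must be in [1, 15]");
  long long h = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(kmer[i]);
    if (c < 0) stop("non-ACGT symbol in k-mer: '%s'", kmer.c_str());
    h = h * 4 + c;
  }
  return (int) h;
}

// Sorted vector of the distinct k-mer hashes of a sequence.
// Positions with any non-ACGT base must be pre-substituted by the caller.
// [[Rcpp::export]]
IntegerVector cpp_kmer_set(std::string seq, int k) {
  check_k(k);
  int n = (int) seq.size();
  if (n < k) stop("sequence shorter than k");
  std::vector<int> out;
  out.reserve(n - k + 1);
  long long h = 0, mask = ((long long)1 << (2 * k)) - 1;
  int run = 0;  // bases accumulated in current window
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) stop("non-ACGT symbol at position %d", i + 1);
    h = ((h << 2) | c) & mask;
    if (++run >= k) out.push_back((int) h);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return wrap(out);
}

// [[Rcpp::export]]
int cpp_intersect_size(IntegerVector a, IntegerVector b) {
  int i = 0, j = 0, n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
  int n = (int) seq.size();
  std::string out(n, 'N');
  for (int i = 0; i < n; ++i) {
    char b = seq[n - 1 - i], r;
    switch (b) {
    case 'A': r = 'T'; break; case 'a': r = 't'; break;
    case 'C': r = 'G'; break; case 'c': r = 'g'; break;
    case 'G': r = 'C'; break; case 'g': r = 'c'; break;
    case 'T': r = 'A'; break; case 't': r = 'a'; break;
    case 'N': r = 'N'; break; case 'n': r = 'n'; break;
    default: stop("cannot reverse-complement symbol '%c'", b);
    }
    out[i] = r;
  }
  return out;
}

// Shared-k-mer triplets (s, p1, p2), 0-based positions, sorted by (p1, p2).
// A k-mer occurring at several positions contributes one triplet per
// position pair.
// [[Rcpp::export]]
IntegerMatrix cpp_triplets(std::string seq1, std::string seq2, int k) {
  check_k(k);
  int n1 = (int) seq1.size(), n2 = (int) seq2.size();
  if (n1 < k || n2 < k) return IntegerMatrix(0, 3);
  std::unordered_map<long long, std::vector<int> > pos2;
  long long h = 0, mask = ((long long)1 << (2 * k)) - 1;
  int run = 0;
  for (int i = 0; i < n2; ++i) {
    int c = base_code(seq2[i]);
    if (c < 0) stop("non-ACGT symbol in read 2 at position %d", i + 1);
    h = ((h << 2) | c) & mask;
    if (++run >= k) pos2[h].push_back(i - k + 1);
  }
  std::vector<int> s_out, p1_out, p2_out;
  h = 0; run = 0;
  for (int i = 0; i < n1; ++i) {
    int c = base_code(seq1[i]);
    if (c < 0) stop("non-ACGT symbol in read 1 at position %d", i + 1);
    h = ((h << 2) | c) & mask;
    if (++run >= k) {
      std::unordered_map<long long, std::vector<int> >::iterator it = pos2.find(h);
      if (it != pos2.end()) {
        int p1 = i - k + 1;
        for (size_t j = 0; j < it->second.size(); ++j) {
          s_out.push_back((int) h);
          p1_out.push_back(p1);
          p2_out.push_back(it->second[j]);  // already ascending within p1
        }
      }
    }
  }
  int m = (int) s_out.size();
  IntegerMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = s_out[i]; out(i, 1) = p1_out[i]; out(i, 2) = p2_out[i];
  }
  colnames(out) = CharacterVector::create("s", "p1", "p2");
  return out;
}

// Longest chain strictly increasing in both p1 and p2; input must be sorted
// by (p1, p2).  Among equal-length chains, returns the lexicographically
// smallest in (p1, p2).  Returns 1-based row indices of the chain.
// [[Rcpp::export]]
IntegerVector cpp_lis_chain(IntegerVector p1, IntegerVector p2) {
  int n = p1.size();
  if (n == 0) return IntegerVector(0);
  // g[i]: longest valid chain starting at i
  std::vector<int> g(n, 1);
  for (int i = n - 2; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      if (p1[j] > p1[i] && p2[j] > p2[i] && g[j] + 1 > g[i]) g[i] = g[j] + 1;
    }
  }
  int L = 0;
  for (int i = 0; i < n; ++i) if (g[i] > L) L = g[i];
  std::vector<int> chain;
  chain.reserve(L);
  int prev = -1;
  for (int need = L; need >= 1; --need) {
    for (int i = (prev < 0 ? 0 : prev + 1); i < n; ++i) {
      if (g[i] != need) continue;
      if (prev >= 0 && !(p1[i] > p1[prev] && p2[i] > p2[prev])) continue;
      chain.push_back(i + 1);
      prev = i;
      break;
    }
  }
  return wrap(chain);
}

// Population variance of adjacent gap differences
// d_i = (p1[i+1]-p1[i]) - (p2[i+1]-p2[i]) along a collinear chain.
// [[Rcpp::export]]
double cpp_gap_variance(IntegerVector p1, IntegerVector p2) {
  int n = p1.size();
  if (n < 3) return 0.0;
  int m = n - 1;
  std::vector<double> d(m);
  double mu = 0.0;
  for (int i = 0; i < m; ++i) {
    d[i] = (double)(p1[i + 1] - p1[i]) - (double)(p2[i + 1] - p2[i]);
    mu += d[i];
  }
  mu /= m;
  double v = 0.0;
  for (int i = 0; i < m; ++i) v += (d[i] - mu) * (d[i] - mu);
  return v / m;
}

// Total length of the union of [p1, p1 + k) intervals for chain members.
// [[Rcpp::export]]
int cpp_covered_bases(IntegerVector p1, int k) {
  int n = p1.size();
  if (n == 0) return 0;
  int covered = 0, last_end = -1;
  for (int i = 0; i < n; ++i) {  // p1 ascending along the chain
    int s = p1[i], e = p1[i] + k;
    if (s > last_end) covered += k;
    else covered += e - last_end;
    last_end = e;
  }
  return covered;
}

// One-call LIS similarity between two oriented sequences: extracts shared
// k-mer triplets, solves the LIS, scores coverage over the shorter read and
// reports the gap-difference variance of the chain.
// [[Rcpp::export]]
List cpp_lis_similarity(std::string seq1, std::string seq2, int k) {
  IntegerMatrix tr = cpp_triplets(seq1, seq2, k);
  int m = tr.nrow();
  IntegerVector p1 = (m > 0) ? tr(_, 1) : IntegerVector(0);
  IntegerVector p2 = (m > 0) ? tr(_, 2) : IntegerVector(0);
  IntegerVector idx = cpp_lis_chain(p1, p2);
  int L = idx.size();
  IntegerMatrix chain(L, 3);
  IntegerVector cp1(L), cp2(L);
  for (int i = 0; i < L; ++i) {
    int r = idx[i] - 1;
    chain(i, 0) = tr(r, 0); chain(i, 1) = tr(r, 1); chain(i, 2) = tr(r, 2);
    cp1[i] = tr(r, 1); cp2[i] = tr(r, 2);
  }
  colnames(chain) = CharacterVector::create("s", "p1", "p2");
  int shorter = std::min((int) seq1.size(), (int) seq2.size());
  double score = (shorter > 0) ? (double) cpp_covered_bases(cp1, k) / shorter : 0.0;
  if (score > 1.0) score = 1.0;  // coverage cannot exceed the read
  return List::create(_["score"] = score,
                      _["chain"] = chain,
                      _["gap_variance"] = cpp_gap_variance(cp1, cp2),
                      _["n_triplets"] = m);
}
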