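#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A/C/G/T; -1 for anything else (N etc.)
static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Order-k Markov chain sequence sampler driven by the R RNG, so set.seed()
// in R fully determines the output.
// trans: (4^order) x 4 row-stochastic matrix, contexts in base-4 order (A=0..T=3).
// [[Rcpp::export]]
std::string cpp_markov_seq(int len, NumericMatrix trans, int order) {
  RNGScope scope;
  const char bases[5] = "ACGT";
  std::string out;
  out.reserve(len);
  int ctx = 0, mask = 1;
  for (int i = 0; i < order; ++i) mask *= 4;
  // seed the first `order` bases uniformly
  for (int i = 0; i < order && i < len; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    out.push_back(bases[b]);
    ctx = (ctx * 4 + b) % mask;
  }
  for (int i = order; i < len; ++i) {
    double u = unif_rand();
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(ctx, j);
      if (u <= acc) { b = j; break; }
    }
    out.push_back(bases[b]);
    ctx = (ctx * 4 + b) % mask;
  }
  return out;
}

// Banded semi-global edit distance: `a` is aligned end-to-end, leading and
// trailing gaps in `b` are free. Returns the minimum number of edits
// (mismatch / insertion / deletion, unit cost); N never matches.
// band is the half-width of the diagonal corridor, widened by |la - lb|.
// [[Rcpp::export]]
int cpp_banded_edit(std::string a, std::string b, int band) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0) return 0;
  if (lb == 0) return la;
  const int w = band + std::abs(la - lb) + 1;
  const int INF = la + lb + 10;
  std::vector<int> prev(lb + 1, 0), cur(lb + 1, INF);
  // row 0: free leading gaps in b
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(1, i - w), jhi = std::min(lb, i + w);
    if (jlo == 1) cur[0] = i;
    for (int j = jlo; j <= jhi; ++j) {
      bool match = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      int best = prev[j - 1] + (match ? 0 : 1);
      if (prev[j] + 1 < best) best = prev[j] + 1;      // gap in b (consume a)
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1; // gap in a (consume b)
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  int res = INF;
  for (int j = 0; j <= lb; ++j) if (prev[j] < res) res = prev[j];
  return res;
}

struct Hit { int32_t tgt; int32_t pos; };

static void kmerize(const std::string& s, int k,
                    std::vector<std::pair<uint64_t, int> >& out) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++valid >= k) out.push_back(std::make_pair(kmer, i - k + 1));
  }
}

// Map each query fragment to its best location across a set of target
// sequences: shared-k-mer diagonal voting picks (target, diagonal), then a
// banded semi-global alignment of the fragment against the padded target
// window yields an edit-distance identity. Fragments are supplied in one
// orientation; the caller handles reverse complements.
// Returns one row per fragment: target (1-based index, 0 = no seed hit),
// tstart/tend (approximate aligned interval on the target, 1-based),
// identity (percent), votes (seed count), covered (fraction of the fragment
// the target window could cover).
// [[Rcpp::export]]
DataFrame cpp_fragment_map(CharacterVector frags, CharacterVector targets,
                           int k, double band_frac) {
  // index all target k-mers
  std::unordered_multimap<uint64_t, Hit> index;
  std::vector<std::string> tg(targets.size());
  for (int t = 0; t < targets.size(); ++t) {
    tg[t] = as<std::string>(targets[t]);
    std::vector<std::pair<uint64_t, int> > kms;
    kmerize(tg[t], k, kms);
    for (size_t i = 0; i < kms.size(); ++i) {
      Hit h; h.tgt = t; h.pos = kms[i].second;
      index.insert(std::make_pair(kms[i].first, h));
    }
  }
  const int nf = frags.size();
  IntegerVector r_tgt(nf), r_start(nf), r_end(nf), r_votes(nf);
  NumericVector r_ident(nf), r_cov(nf);
  for (int f = 0; f < nf; ++f) {
    std::string fr = as<std::string>(frags[f]);
    const int lf = (int)fr.size();
    std::vector<std::pair<uint64_t, int> > kms;
    kmerize(fr, k, kms);
    // vote (target, diagonal)
    std::unordered_map<int64_t, int> votes;
    for (size_t i = 0; i < kms.size(); ++i) {
      auto range = index.equal_range(kms[i].first);
      for (auto it = range.first; it != range.second; ++it) {
        int64_t key = (int64_t)it->second.tgt * 400000000LL +
          (int64_t)(it->second.pos - kms[i].second + 100000000);
        votes[key] += 1;
      }
    }
    int best_v = 0; int64_t best_key = -1;
    for (auto& kv : votes)
      if (kv.second > best_v || (kv.second == best_v && kv.first < best_key))
        { best_v = kv.second; best_key = kv.first; }
    if (best_v == 0) {
      r_tgt[f] = 0; r_start[f] = NA_INTEGER; r_end[f] = NA_INTEGER;
      r_ident[f] = NA_REAL; r_votes[f] = 0; r_cov[f] = 0.0;
      continue;
    }
    int t = (int)(best_key / 400000000LL);
    int diag = (int)(best_key % 400000000LL) - 100000000;
    int band = std::max(8, (int)(band_frac * lf));
    int ws = std::max(0, diag - band);
    int we = std::min((int)tg[t].size(), diag + lf + band);
    std::string window = tg[t].substr(ws, we - ws);
    double covered = std::min((double)window.size(), (double)lf) / lf;
    int edits = cpp_banded_edit(fr, window, band);
    double ident = 100.0 * std::max(0.0, (double)(lf - edits)) / lf;
    r_tgt[f] = t + 1;
    r_start[f] = std::max(1, diag + 1);
    r_end[f] = std::min((int)tg[t].size(), diag + lf);
    r_ident[f] = ident; r_votes[f] = best_v; r_cov[f] = covered;
  }
  return DataFrame::create(_["target"] = r_tgt, _["tstart"] = r_start,
                           _["tend"] = r_end, _["identity"] = r_ident,
                           _["votes"] = r_votes, _["covered"] = r_cov);
}

// Best shared-k-mer diagonal between two sequences (single orientation).
// diag d means position p of `a` pairs with position p + d of `b` (0-based).
// [[Rcpp::export]]
List cpp_best_diagonal(std::string a, std::string b, int k) {
  std::vector<std::pair<uint64_t, int> > ka, kb;
  kmerize(a, k, ka);
  kmerize(b, k, kb);
  std::unordered_multimap<uint64_t, int> idx;
  for (size_t i = 0; i < kb.size(); ++i)
    idx.insert(std::make_pair(kb[i].first, kb[i].second));
  std::unordered_map<int, int> votes;
  for (size_t i = 0; i < ka.size(); ++i) {
    auto range = idx.equal_range(ka[i].first);
    for (auto it = range.first; it != range.second; ++it)
      votes[it->second - ka[i].second] += 1;
  }
  int best_v = 0, best_d = 0;
  for (auto& kv : votes)
    if (kv.second > best_v || (kv.second == best_v && kv.first < best_d))
      { best_v = kv.second; best_d = kv.first; }
  return List::create(_["diag"] = best_d, _["votes"] = best_v);
}
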