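#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Full Wagner-Fischer edit distance (unit-cost sub/ins/del), two rolling rows.
static int lv_full(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Banded (Ukkonen) edit distance with threshold: returns the distance if it is
// <= k, otherwise any value > k. Early-abandons when a whole band row exceeds k.
static int lv_banded(const std::string &a, const std::string &b, int k) {
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > k) return k + 1;
  const int INF = k + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, k); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - k), hi = std::min(m, i + k);
    std::fill(cur.begin(), cur.end(), INF);
    if (i - k <= 0) cur[0] = i;
    int rowmin = cur[0];
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = (prev[j] < INF) ? prev[j] + 1 : INF;
      int ins = (cur[j - 1] < INF) ? cur[j - 1] + 1 : INF;
      cur[j] = std::min(sub, std::min(del, ins));
      if (cur[j] < rowmin) rowmin = cur[j];
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[m], INF);
}

// [[Rcpp::export]]
IntegerVector lv_dist_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = lv_full(sa, sb);
  }
  return out;
}

// Nearest-unique match of each query against refs under a distance cutoff.
// Returns, per query: best index (1-based, NA if none within cutoff), best
// distance, and whether the minimum was tied (ambiguous).
// [[Rcpp::export]]
List lv_nearest_cpp(CharacterVector queries, CharacterVector refs, int max_dist) {
  R_xlen_t nq = queries.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (R_xlen_t j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  IntegerVector idx(nq, NA_INTEGER), dist(nq, NA_INTEGER);
  LogicalVector tie(nq, false);
  for (R_xlen_t i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    int best = max_dist + 1, besti = -1;
    bool tied = false;
    for (R_xlen_t j = 0; j < nr; ++j) {
      // search with the current best as threshold so strictly-nearer hits win
      int d = lv_banded(q, rs[j], std::min(max_dist, best));
      if (d < best) { best = d; besti = j; tied = false; }
      else if (d == best && best <= max_dist) tied = true;
      if (best == 0 && !tied) {
        // a second exact match could still tie; keep scanning only for ties
        for (R_xlen_t j2 = j + 1; j2 < nr; ++j2)
          if (lv_banded(q, rs[j2], 0) == 0) { tied = true; break; }
        break;
      }
    }
    if (besti >= 0 && best <= max_dist) {
      idx[i] = besti + 1;
      dist[i] = best;
      tie[i] = tied;
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist, _["tie"] = tie);
}

// Greedy generation of n random length-len ACGT barcodes with pairwise
// Levenshtein distance >= min_dist. Uses R's RNG (respects set.seed).
// [[Rcpp::export]]
CharacterVector generate_separated_barcodes_cpp(int n, int len, int min_dist,
                                                int max_tries) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::vector<std::string> kept;
  kept.reserve(n);
  GetRNGstate();
  int tries = 0;
  std::string cand(len, 'A');
  while ((int)kept.size() < n) {
    if (++tries > max_tries) {
      PutRNGstate();
      stop("could not place %d barcodes of length %d at pairwise distance >= %d",
           n, len, min_dist);
    }
    for (int p = 0; p < len; ++p)
      cand[p] = bases[(int)(unif_rand() * 4) % 4];
    bool ok = true;
    for (size_t j = 0; j < kept.size(); ++j) {
      if (lv_banded(cand, kept[j], min_dist - 1) < min_dist) { ok = false; break; }
    }
    if (ok) kept.push_back(cand);
  }
  PutRNGstate();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = kept[i];
  return out;
}
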