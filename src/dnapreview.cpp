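#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Banded Levenshtein distance with cap; returns cap + 1 when the true
// distance exceeds cap. Standard DP restricted to a diagonal band of
// half-width cap, with early abandon when the whole band exceeds cap.
static int lev_banded(const std::string &a, const std::string &b, int cap) {
  int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > cap) return cap + 1;
  if (n == 0) return m;
  if (m == 0) return n;
  const int INF = cap + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, cap); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - cap), hi = std::min(m, i + cap);
    cur.assign(m + 1, INF);
    if (i - cap <= 0) cur[0] = i;
    int rowmin = INF;
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int v = std::min(sub, std::min(del, ins));
      if (v > INF) v = INF;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (i - cap <= 0 && cur[0] < rowmin) rowmin = cur[0];
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
  }
  return prev[m] <= cap ? prev[m] : cap + 1;
}

// [[Rcpp::export]]
IntegerVector levenshtein_pairwise(CharacterVector a, CharacterVector b,
                                   int cap) {
  if (a.size() != b.size()) stop("length mismatch");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    out[i] = lev_banded(sa, sb, cap);
  }
  return out;
}

// [[Rcpp::export]]
int levenshtein_bounded(std::string a, std::string b, int cap) {
  return lev_banded(a, b, cap);
}

// Substitution walk to an exact Hamming distance, repeat-until semantics
// (positions may be revisited; distance may temporarily decrease). Uses the
// R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
String mutate_walk(std::string primer, int target_hd, int max_iter) {
  const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string cur = primer;
  int L = (int)primer.size();
  int hd = 0;
  int iter = 0;
  while (hd != target_hd) {
    if (++iter > max_iter) stop("mutate_walk: iteration cap exceeded");
    int pos = (int)(unif_rand() * L);
    if (pos >= L) pos = L - 1;
    char old = cur[pos];
    // pick uniformly among the three other bases
    char nb;
    do {
      nb = bases[(int)(unif_rand() * 4) % 4];
    } while (nb == old);
    bool was_mut = cur[pos] != primer[pos];
    cur[pos] = nb;
    bool is_mut = cur[pos] != primer[pos];
    hd += (int)is_mut - (int)was_mut;
  }
  return String(cur);
}

// Minimum Hamming distance between every window of each strand (window
// length = probe length) and any probe.
// [[Rcpp::export]]
IntegerVector window_min_hd(CharacterVector strands, CharacterVector probes) {
  int np = probes.size();
  std::vector<std::string> pr(np);
  for (int p = 0; p < np; ++p) pr[p] = as<std::string>(probes[p]);
  int k = (int)pr[0].size();
  IntegerVector out(strands.size());
  for (R_xlen_t s = 0; s < strands.size(); ++s) {
    std::string str = as<std::string>(strands[s]);
    int best = INT_MAX;
    int nwin = (int)str.size() - k + 1;
    for (int w = 0; w < nwin && best > 0; ++w) {
      for (int p = 0; p < np && best > 0; ++p) {
        int hd = 0;
        const std::string &pp = pr[p];
        for (int i = 0; i < k; ++i) {
          if (str[w + i] != pp[i]) { if (++hd >= best) break; }
        }
        if (hd < best) best = hd;
      }
    }
    out[s] = (best == INT_MAX) ? NA_INTEGER : best;
  }
  return out;
}

// Message-passing Levenshtein clustering (Starcode-like semantics).
//
// Inputs are UNIQUE sequences sorted by descending multiplicity (ties broken
// lexicographically upstream). A sequence joins an existing centroid V when
// lev(seq, V) <= max_dist and count(V) >= ratio * count(seq); otherwise it
// becomes a centroid itself. Candidate centroids are retrieved through an
// inverted index of disjoint k-mers: a read within max_dist edits of a
// centroid must contain at least one of the centroid's disjoint k-mers
// intact (pigeonhole), so recall is exact while probing stays cheap.
//
// Returns 0-based index of the winning centroid for each sequence, or -1 if
// the sequence founded its own cluster.
// [[Rcpp::export]]
IntegerVector cluster_core(CharacterVector seqs, NumericVector counts,
                           int max_dist, double ratio, int kmer) {
  int n = seqs.size();
  std::vector<std::string> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<std::string>(seqs[i]);
  IntegerVector assign(n);
  std::unordered_map<std::string, std::vector<int>> index;
  std::vector<int> stamp;   // centroid id -> last query that saw it
  std::vector<int> votes;   // shared-kmer tally for the current query
  std::vector<int> nkmers;  // disjoint kmers indexed per centroid
  std::vector<int> cents;   // centroid input indices
  std::vector<int> cand;    // candidate ids for the current query
  int query = 0;
  for (int i = 0; i < n; ++i) {
    const std::string &s = sv[i];
    ++query;
    cand.clear();
    int L = (int)s.size();
    // vote: how many of each centroid's disjoint kmers occur in this read.
    // A read within max_dist edits of a centroid retains at least
    // (floor(Lc/kmer) - max_dist) of its disjoint kmers intact (pigeonhole),
    // so thresholding on votes preserves exact recall while skipping
    // centroids that merely share the primer regions.
    for (int off = 0; off + kmer <= L; ++off) {
      auto it = index.find(s.substr(off, kmer));
      if (it == index.end()) continue;
      for (int cid : it->second) {
        if (stamp[cid] != query) { stamp[cid] = query; votes[cid] = 0; cand.push_back(cid); }
        ++votes[cid];
      }
    }
    // verify high-vote candidates first; among highly repetitive strand
    // families (e.g. zero-padding rows sharing payload codewords) cap the
    // number of full distance computations once a near-exact hit is in hand
    std::sort(cand.begin(), cand.end(),
              [&](int a, int b) { return votes[a] > votes[b]; });
    int best = -1, bestd = max_dist + 1;
    double bestc = -1.0;
    int checked = 0;
    for (int cid : cand) {
      if (votes[cid] < std::max(1, nkmers[cid] - max_dist)) continue;
      int ci = cents[cid];
      if (counts[ci] < ratio * counts[i]) continue;
      int d = lev_banded(s, sv[ci], max_dist);
      ++checked;
      if (d <= max_dist) {
        bool better = d < bestd ||
          (d == bestd && (counts[ci] > bestc ||
                          (counts[ci] == bestc && best >= 0 && sv[ci] < sv[cents[best]])));
        if (better) { best = cid; bestd = d; bestc = counts[ci]; }
      }
      if (bestd <= 2 || checked >= 48) break;
    }
    if (best >= 0) {
      assign[i] = cents[best];
    } else {
      assign[i] = -1;
      int cid = (int)cents.size();
      cents.push_back(i);
      stamp.push_back(0);
      votes.push_back(0);
      int nk = 0;
      for (int off = 0; off + kmer <= L; off += kmer) {
        auto &slot = index[s.substr(off, kmer)];
        // repeat masking: ubiquitous kmers stop indexing new centroids (the
        // per-centroid nkmers tally only counts kmers actually indexed)
        if ((int)slot.size() < 48) { slot.push_back(cid); ++nk; }
      }
      nkmers.push_back(nk);
    }
  }
  return assign;
}
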