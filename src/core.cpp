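#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// N is treated as matching nothing, including another N, so exact matches,
// repeats and SSR runs never cross ambiguous positions.
static inline bool chr_eq(char a, char b) { return a == b && a != 'N'; }

static inline int code2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// All maximal exact matches of length >= min_match between ref and qry
// (forward strand of both as given; the caller handles orientation by
// transforming qry). Seeds are packed k-mers with k = min(min_match, 31);
// every MEM of length >= min_match contains the seed at its start, and a
// per-diagonal coverage map keeps each MEM from being re-derived from every
// seed inside it. Diagonals listed in exclude_diags (pos_ref - pos_qry) are
// skipped, which self-comparisons use to drop the trivial identity match.
// [[Rcpp::export]]
DataFrame cpp_find_mems(std::string ref, std::string qry, int min_match,
                        IntegerVector exclude_diags) {
  std::vector<int> out_i, out_j, out_l;
  const int nr = (int) ref.size(), nq = (int) qry.size();
  const int k = min_match < 31 ? min_match : 31;
  if (nr == 0 || nq == 0 || min_match < 1 || k > nr || k > nq)
    return DataFrame::create(_["pos_ref"] = out_i, _["pos_qry"] = out_j,
                             _["length"] = out_l);

  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  std::unordered_map<uint64_t, std::vector<int> > idx;
  idx.reserve((size_t) nr * 2);
  {
    uint64_t key = 0; int valid = 0;
    for (int i = 0; i < nr; i++) {
      int c = code2(ref[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      valid++;
      if (valid >= k) idx[key].push_back(i - k + 1);
    }
  }
  std::unordered_set<long long> excl(exclude_diags.begin(), exclude_diags.end());
  std::unordered_map<long long, int> covered;  // diagonal -> qry end already explained

  uint64_t key = 0; int valid = 0;
  for (int j = 0; j < nq; j++) {
    int c = code2(qry[j]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) c) & mask;
    valid++;
    if (valid < k) continue;
    const int j0 = j - k + 1;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    for (size_t h = 0; h < it->second.size(); h++) {
      const int i0 = it->second[h];
      const long long d = (long long) i0 - (long long) j0;
      if (excl.count(d)) continue;
      std::unordered_map<long long, int>::iterator cit = covered.find(d);
      if (cit != covered.end() && j0 < cit->second) continue;
      int is = i0, js = j0;
      while (is > 0 && js > 0 && chr_eq(ref[is - 1], qry[js - 1])) { is--; js--; }
      int ie = i0 + k, je = j0 + k;
      while (ie < nr && je < nq && chr_eq(ref[ie], qry[je])) { ie++; je++; }
      covered[d] = je;
      const int L = ie - is;
      if (L >= min_match) {
        out_i.push_back(is); out_j.push_back(js); out_l.push_back(L);
      }
    }
  }
  return DataFrame::create(_["pos_ref"] = out_i, _["pos_qry"] = out_j,
                           _["length"] = out_l);
}

// Global alignment under unit edit costs (match 0, mismatch 1, gap 1/base),
// returning a run-length transcript. Op codes: 0 = match, 1 = substitution,
// 2 = qry-gap (consumes a only), 3 = ref-gap (consumes b only). Ties prefer
// the diagonal, then the qry-gap, so output is deterministic; indel placement
// is canonicalised later by left-normalisation at the variant level.
// [[Rcpp::export]]
List cpp_edit_align(std::string a, std::string b) {
  const size_t m = a.size(), n = b.size();
  if ((m + 1) * (n + 1) > 120000000ULL)
    stop("alignment problem too large (%d x %d)", (int) m, (int) n);
  std::vector<int> prev(n + 1), cur(n + 1);
  std::vector<uint8_t> tb((m + 1) * (n + 1));
  for (size_t j = 0; j <= n; j++) { prev[j] = (int) j; tb[j] = j ? 2 : 0; }
  for (size_t i = 1; i <= m; i++) {
    cur[0] = (int) i;
    tb[i * (n + 1)] = 1;
    for (size_t j = 1; j <= n; j++) {
      const int cd = prev[j - 1] + (chr_eq(a[i - 1], b[j - 1]) ? 0 : 1);
      const int cu = prev[j] + 1;
      const int cl = cur[j - 1] + 1;
      int best = cd; uint8_t t = 0;
      if (cu < best) { best = cu; t = 1; }
      if (cl < best) { best = cl; t = 2; }
      cur[j] = best;
      tb[i * (n + 1) + j] = t;
    }
    std::swap(prev, cur);
  }
  const int dist = prev[n];
  std::vector<int> rev_ops;
  rev_ops.reserve(m + n);
  size_t i = m, j = n;
  while (i > 0 || j > 0) {
    const uint8_t t = tb[i * (n + 1) + j];
    if (t == 0) { rev_ops.push_back(chr_eq(a[i - 1], b[j - 1]) ? 0 : 1); i--; j--; }
    else if (t == 1) { rev_ops.push_back(2); i--; }
    else { rev_ops.push_back(3); j--; }
  }
  std::vector<int> ops, lens;
  for (int p = (int) rev_ops.size() - 1; p >= 0; p--) {
    const int op = rev_ops[p];
    if (!ops.empty() && ops.back() == op) lens.back()++;
    else { ops.push_back(op); lens.push_back(1); }
  }
  return List::create(_["ops"] = ops, _["lens"] = lens, _["dist"] = dist);
}

static bool motif_primitive(const std::string& s, int start, int u) {
  for (int d = 1; d < u; d++) {
    if (u % d != 0) continue;
    bool periodic = true;
    for (int t = d; t < u && periodic; t++)
      if (s[start + t] != s[start + t - d]) periodic = false;
    if (periodic) return false;
  }
  return true;
}

// Candidate perfect tandem repeats for motif sizes 1-6. For every maximal
// period-u run the u left-maximal phases are emitted (start offsets 0..u-1
// inside the run), each with its count of complete copies; phases further
// right are extendable by a full unit on the left and therefore not maximal.
// Thresholding and non-overlap selection happen in R.
// [[Rcpp::export]]
DataFrame cpp_find_ssr_runs(std::string s) {
  const int n = (int) s.size();
  std::vector<int> starts, units, copies;
  for (int u = 1; u <= 6; u++) {
    int i = 0;
    while (i + u < n) {
      if (!chr_eq(s[i], s[i + u])) { i++; continue; }
      int r = i;
      while (r + u < n && chr_eq(s[r], s[r + u])) r++;
      // period-u run spans [i, r + u)
      const int span = (r - i) + u;
      for (int t = 0; t < u && t < span; t++) {
        const int cp = (span - t) / u;
        if (cp >= 2 && motif_primitive(s, i + t, u)) {
          starts.push_back(i + t); units.push_back(u); copies.push_back(cp);
        }
      }
      i = r + 1;
    }
  }
  return DataFrame::create(_["start"] = starts, _["unit_len"] = units,
                           _["copies"] = copies);
}
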