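// Ungapped seed-and-extend pairwise alignment of DNA contigs.
// Exact k-mer seeds are grouped per diagonal; diagonals carrying at least
// min_seed_hits seeds are extended ungapped in both directions with an
// x-drop criterion (+1 match / -1 mismatch).  Substitution-dominated
// similarity (the regime relevant for species-level dereplication) lies on
// a single diagonal, so no gapped chaining is attempted.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void build_index(const std::string& s, int k, KmerIndex& idx) {
  const uint64_t mask = (k == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
}

struct Hit {
  int qs, qe, ts, te, matches;
  char strand;
};

// extend ungapped around seed (qi, ti) of length k; clip query start at
// min_q (coverage already claimed by an earlier extension on this diagonal)
static bool extend_seed(const std::string& a, const std::string& b,
                        int qi, int ti, int k, int xdrop, int min_len,
                        int min_q, Hit& out) {
  const int la = (int)a.size(), lb = (int)b.size();
  // right extension
  int score = k, best = k;
  int qr = qi + k, best_qr = qr;
  int tr = ti + k;
  while (qr < la && tr < lb) {
    score += (a[qr] == b[tr]) ? 1 : -1;
    ++qr; ++tr;
    if (score > best) { best = score; best_qr = qr; }
    if (score < best - xdrop) break;
  }
  // left extension
  score = best;
  int ql = qi, best_ql = ql;
  int tl = ti;
  while (ql > min_q && tl > 0) {
    score += (a[ql - 1] == b[tl - 1]) ? 1 : -1;
    --ql; --tl;
    if (score > best) { best = score; best_ql = ql; }
    if (score < best - xdrop) break;
  }
  int qs = best_ql, qe = best_qr;
  if (qe - qs < min_len) return false;
  int ts = ti - (qi - qs);
  int matches = 0;
  for (int i = 0; i < qe - qs; ++i) {
    if (a[qs + i] == b[ts + i]) ++matches;
  }
  out.qs = qs; out.qe = qe; out.ts = ts; out.te = ts + (qe - qs);
  out.matches = matches;
  return true;
}

static void align_one_strand(const std::string& a, const std::string& b,
                             const KmerIndex& idx_a, int k, int min_seed,
                             int xdrop, int min_len, char strand,
                             std::vector<Hit>& hits) {
  // collect seeds grouped by diagonal d = t - q
  std::unordered_map<long, std::vector<std::pair<int, int> > > diag;
  const uint64_t mask = (k == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
  uint64_t key = 0;
  int run = 0;
  for (int j = 0; j < (int)b.size(); ++j) {
    int c = base_code(b[j]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    KmerIndex::const_iterator it = idx_a.find(key);
    if (it == idx_a.end()) continue;
    int t = j - k + 1;
    for (size_t m = 0; m < it->second.size(); ++m) {
      int q = it->second[m];
      diag[(long)t - q].push_back(std::make_pair(q, t));
    }
  }
  std::vector<long> keys;
  keys.reserve(diag.size());
  for (std::unordered_map<long, std::vector<std::pair<int, int> > >::iterator
         it = diag.begin(); it != diag.end(); ++it) {
    keys.push_back(it->first);
  }
  std::sort(keys.begin(), keys.end());
  for (size_t d = 0; d < keys.size(); ++d) {
    std::vector<std::pair<int, int> >& seeds = diag[keys[d]];
    if ((int)seeds.size() < min_seed) continue;
    std::sort(seeds.begin(), seeds.end());
    int covered = 0;  // query position up to which this diagonal is explained
    for (size_t s = 0; s < seeds.size(); ++s) {
      if (seeds[s].first < covered) continue;
      Hit h;
      h.strand = strand;
      if (extend_seed(a, b, seeds[s].first, seeds[s].second, k, xdrop,
                      min_len, covered, h)) {
        hits.push_back(h);
        covered = h.qe;
      } else {
        // even a failed extension claims its seed so we do not re-extend
        covered = std::max(covered, seeds[s].first + k);
      }
    }
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default: break;
    }
  }
  return r;
}

// Shared canonical k-mer occurrence counts between every pair of contigs.
// Used as a candidate screen before full seed-and-extend alignment: related
// contigs share k-mers in proportion to their identity, unrelated contigs
// only at the random-collision background la*lb/4^k.
// [[Rcpp::export(name = ".cppSharedKmerCounts")]]
NumericMatrix cpp_shared_kmer_counts(CharacterVector seqs, int k) {
  if (k < 5 || k > 31) stop("k must be in [5, 31]");
  const int n = seqs.size();
  const uint64_t mask = (uint64_t(1) << (2 * k)) - 1;
  std::vector<std::pair<uint64_t, uint32_t> > entries;
  for (int s = 0; s < n; ++s) {
    std::string seq = as<std::string>(seqs[s]);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < (int)seq.size(); ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        entries.push_back(std::make_pair(std::min(fwd, rev), (uint32_t)s));
      }
    }
  }
  std::sort(entries.begin(), entries.end());
  NumericMatrix counts(n, n);
  size_t i = 0;
  std::vector<std::pair<uint32_t, int> > occ;
  while (i < entries.size()) {
    size_t j = i;
    occ.clear();
    while (j < entries.size() && entries[j].first == entries[i].first) {
      if (!occ.empty() && occ.back().first == entries[j].second) {
        ++occ.back().second;
      } else {
        occ.push_back(std::make_pair(entries[j].second, 1));
      }
      ++j;
    }
    for (size_t a = 0; a + 1 < occ.size(); ++a) {
      for (size_t b = a + 1; b < occ.size(); ++b) {
        double add = (double)occ[a].second * occ[b].second;
        counts(occ[a].first, occ[b].first) += add;
        counts(occ[b].first, occ[a].first) += add;
      }
    }
    i = j;
  }
  return counts;
}

// [[Rcpp::export(name = ".cppSeedExtend")]]
DataFrame cpp_seed_extend(std::string a, std::string b, int k, int min_seed,
                          int xdrop, int min_len, bool both_strands) {
  if (k < 5 || k > 32) stop("k must be in [5, 32]");
  KmerIndex idx;
  build_index(a, k, idx);
  std::vector<Hit> hits;
  align_one_strand(a, b, idx, k, min_seed, xdrop, min_len, '+', hits);
  if (both_strands) {
    std::string brc = revcomp(b);
    std::vector<Hit> rhits;
    align_one_strand(a, brc, idx, k, min_seed, xdrop, min_len, '-', rhits);
    const int lb = (int)b.size();
    for (size_t i = 0; i < rhits.size(); ++i) {
      Hit h = rhits[i];
      int ts = lb - h.te, te = lb - h.ts;  // map back to forward coordinates
      h.ts = ts; h.te = te;
      hits.push_back(h);
    }
  }
  int n = (int)hits.size();
  IntegerVector qs(n), qe(n), ts(n), te(n), matches(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ts[i] = hits[i].ts; te[i] = hits[i].te;
    matches[i] = hits[i].matches;
    strand[i] = std::string(1, hits[i].strand);
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe,
    _["t_start"] = ts, _["t_end"] = te,
    _["matches"] = matches, _["strand"] = strand,
    _["stringsAsFactors"] = false);
}
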