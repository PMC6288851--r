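#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Exact-overlap core. Two reads are linked when they share an exact common
// substring of at least b bases, in either orientation. Any shared substring
// of length >= b contains a shared window of length exactly b, so indexing
// every length-b window is complete. Orientation is folded in by keying each
// window on the lexicographic minimum of (window, reverse complement).
// Windows containing a non-ACGT character never match anything (N is a
// match breaker).

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

struct WindowIndex {
  int b;
  bool use_revcomp;
  std::vector<std::string> seqs;
  // canonical window -> ordinals (0-based) of reads containing it; a read
  // appears once per key no matter how many of its windows share the key
  std::unordered_map<std::string, std::vector<int>> table;
};

static inline bool window_clean(const std::string& s, size_t pos, int b) {
  for (int k = 0; k < b; ++k) {
    char c = s[pos + k];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

static void index_read(WindowIndex& ix, int i) {
  const std::string& s = ix.seqs[i];
  const int b = ix.b;
  if ((int)s.size() < b) return;
  for (size_t pos = 0; pos + b <= s.size(); ++pos) {
    if (!window_clean(s, pos, b)) continue;
    std::string w = s.substr(pos, b);
    if (ix.use_revcomp) {
      std::string rc = revcomp(w);
      if (rc < w) w.swap(rc);
    }
    std::vector<int>& v = ix.table[w];
    if (v.empty() || v.back() != i) v.push_back(i);
  }
}

static WindowIndex* build_window_index(const std::vector<std::string>& seqs,
                                       int b, bool use_revcomp) {
  WindowIndex* ix = new WindowIndex();
  ix->b = b;
  ix->use_revcomp = use_revcomp;
  ix->seqs = seqs;
  size_t total = 0;
  for (const auto& s : seqs) if ((int)s.size() >= b) total += s.size() - b + 1;
  ix->table.reserve(total);
  for (int i = 0; i < (int)seqs.size(); ++i) index_read(*ix, i);
  return ix;
}

static std::vector<std::string> as_seq_vector(const CharacterVector& x) {
  std::vector<std::string> out;
  out.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out.push_back(as<std::string>(x[i]));
  return out;
}

// [[Rcpp::export(name = ".ob_index_build")]]
SEXP ob_index_build(CharacterVector seqs, int b, bool use_revcomp) {
  XPtr<WindowIndex> p(build_window_index(as_seq_vector(seqs), b, use_revcomp),
                      true);
  return p;
}

// [[Rcpp::export(name = ".ob_index_neighbors")]]
IntegerVector ob_index_neighbors(SEXP xp, int ordinal0) {
  XPtr<WindowIndex> ix(xp);
  const std::string& s = ix->seqs[ordinal0];
  const int b = ix->b;
  std::vector<int> hits;
  if ((int)s.size() >= b) {
    for (size_t pos = 0; pos + b <= s.size(); ++pos) {
      if (!window_clean(s, pos, b)) continue;
      std::string w = s.substr(pos, b);
      if (ix->use_revcomp) {
        std::string rc = revcomp(w);
        if (rc < w) w.swap(rc);
      }
      auto it = ix->table.find(w);
      if (it == ix->table.end()) continue;
      for (int j : it->second) if (j != ordinal0) hits.push_back(j);
    }
  }
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
  IntegerVector out(hits.size());
  for (size_t k = 0; k < hits.size(); ++k) out[k] = hits[k] + 1; // 1-based
  return out;
}

// Reads containing `pattern` (length >= b) in the indexed orientations.
// Candidates come from the pattern's first window; each candidate is then
// verified by direct substring search, so hits are exact.
// [[Rcpp::export(name = ".ob_index_locate")]]
IntegerVector ob_index_locate(SEXP xp, std::string pattern) {
  XPtr<WindowIndex> ix(xp);
  const int b = ix->b;
  if ((int)pattern.size() < b)
    stop("pattern shorter than the index window length b = %d", b);
  std::string w = pattern.substr(0, b);
  if (!window_clean(w, 0, b)) return IntegerVector(0);
  std::string key = w;
  if (ix->use_revcomp) {
    std::string rc = revcomp(w);
    if (rc < key) key = rc;
  }
  auto it = ix->table.find(key);
  std::vector<int> hits;
  if (it != ix->table.end()) {
    std::string prc = revcomp(pattern);
    for (int j : it->second) {
      const std::string& s = ix->seqs[j];
      if (s.find(pattern) != std::string::npos ||
          (ix->use_revcomp && s.find(prc) != std::string::npos))
        hits.push_back(j);
    }
  }
  std::sort(hits.begin(), hits.end());
  IntegerVector out(hits.size());
  for (size_t k = 0; k < hits.size(); ++k) out[k] = hits[k] + 1;
  return out;
}

// [[Rcpp::export(name = ".ob_index_params")]]
List ob_index_params(SEXP xp) {
  XPtr<WindowIndex> ix(xp);
  return List::create(_["b"] = ix->b,
                      _["include_revcomp"] = ix->use_revcomp,
                      _["n_reads"] = (int)ix->seqs.size());
}

// Full adjacency list: per-node window queries against the index, with a
// stamp array deduplicating neighbors on the fly (a pair sharing many
// windows still yields one edge, so degree = distinct neighbors). Every
// shared canonical window is seen from both endpoints, so the result is
// symmetric by construction.
// [[Rcpp::export(name = ".ob_build_adjacency")]]
List ob_build_adjacency(CharacterVector seqs, int b, bool use_revcomp) {
  std::vector<std::string> sv = as_seq_vector(seqs);
  const int n = (int)sv.size();
  WindowIndex* ix = build_window_index(sv, b, use_revcomp);
  std::vector<int> stamp(n, -1);
  List out(n);
  std::vector<int> nbrs;
  for (int i = 0; i < n; ++i) {
    nbrs.clear();
    const std::string& s = sv[i];
    if ((int)s.size() >= b) {
      for (size_t pos = 0; pos + b <= s.size(); ++pos) {
        if (!window_clean(s, pos, b)) continue;
        std::string w = s.substr(pos, b);
        if (use_revcomp) {
          std::string rc = revcomp(w);
          if (rc < w) w.swap(rc);
        }
        auto it = ix->table.find(w);
        if (it == ix->table.end()) continue;
        for (int j : it->second) {
          if (j != i && stamp[j] != i) {
            stamp[j] = i;
            nbrs.push_back(j);
          }
        }
      }
    }
    std::sort(nbrs.begin(), nbrs.end());
    IntegerVector nb(nbrs.size());
    for (size_t k = 0; k < nbrs.size(); ++k) nb[k] = nbrs[k] + 1; // 1-based
    out[i] = nb;
  }
  delete ix;
  return out;
}
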