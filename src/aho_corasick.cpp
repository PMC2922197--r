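#include <Rcpp.h>
#include <array>
#include <queue>
#include <vector>
#include <string>

using namespace Rcpp;

// Aho-Corasick automaton over the amino-acid alphabet A-Z.
// Characters outside A-Z ('*', 'X' in queries) reset the scan to the root,
// which is correct because no dictionary pattern may contain them.

struct ACAutomaton {
  // node-major transition table, 26 columns
  std::vector<std::array<int, 26> > next_;
  std::vector<int> fail_;
  // patterns ending at each node (dictionary links flattened at build time)
  std::vector<std::vector<int> > out_;
  std::vector<int> pat_len_;
  int n_patterns_;

  ACAutomaton() : n_patterns_(0) { add_node(); }

  int add_node() {
    std::array<int, 26> blank;
    blank.fill(-1);
    next_.push_back(blank);
    fail_.push_back(0);
    out_.push_back(std::vector<int>());
    return (int)next_.size() - 1;
  }

  void add_pattern(const std::string& pat, int id) {
    int cur = 0;
    for (size_t i = 0; i < pat.size(); ++i) {
      char c = pat[i];
      if (c < 'A' || c > 'Z')
        stop("pattern %d contains character '%c' outside A-Z", id + 1, c);
      int k = c - 'A';
      if (next_[cur][k] == -1) next_[cur][k] = add_node();
      cur = next_[cur][k];
    }
    out_[cur].push_back(id);
    pat_len_[id] = (int)pat.size();
  }

  void build_links() {
    std::queue<int> q;
    for (int k = 0; k < 26; ++k) {
      int v = next_[0][k];
      if (v == -1) {
        next_[0][k] = 0;
      } else {
        fail_[v] = 0;
        q.push(v);
      }
    }
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      // merge suffix outputs so every match is reported at scan time
      const std::vector<int>& fo = out_[fail_[u]];
      out_[u].insert(out_[u].end(), fo.begin(), fo.end());
      for (int k = 0; k < 26; ++k) {
        int v = next_[u][k];
        if (v == -1) {
          next_[u][k] = next_[fail_[u]][k];
        } else {
          fail_[v] = next_[fail_[u]][k];
          q.push(v);
        }
      }
    }
  }
};

// [[Rcpp::export(name = ".ac_build")]]
SEXP ac_build(CharacterVector patterns) {
  if (patterns.size() == 0) stop("cannot build a matcher from an empty dictionary");
  ACAutomaton* ac = new ACAutomaton();
  ac->n_patterns_ = patterns.size();
  ac->pat_len_.resize(patterns.size(), 0);
  for (int i = 0; i < patterns.size(); ++i) {
    std::string p = as<std::string>(patterns[i]);
    if (p.empty()) {
      delete ac;
      stop("pattern %d is empty", i + 1);
    }
    ac->add_pattern(p, i);
  }
  ac->build_links();
  XPtr<ACAutomaton> ptr(ac, true);
  return ptr;
}

// Scan subject strings; returns all (subject, pattern, start) triples,
// 1-based start positions, overlapping occurrences included.
// [[Rcpp::export(name = ".ac_scan")]]
DataFrame ac_scan(SEXP handle, CharacterVector subjects) {
  XPtr<ACAutomaton> ac(handle);
  std::vector<int> subj_idx, pat_idx, start_pos;
  for (int s = 0; s < subjects.size(); ++s) {
    if (subjects[s] == NA_STRING) continue;
    std::string txt = as<std::string>(subjects[s]);
    int cur = 0;
    for (size_t i = 0; i < txt.size(); ++i) {
      char c = txt[i];
      if (c < 'A' || c > 'Z') {
        cur = 0;  // '*', 'X', etc. break any match
        continue;
      }
      cur = ac->next_[cur][c - 'A'];
      const std::vector<int>& hits = ac->out_[cur];
      for (size_t h = 0; h < hits.size(); ++h) {
        int id = hits[h];
        subj_idx.push_back(s + 1);
        pat_idx.push_back(id + 1);
        start_pos.push_back((int)i - ac->pat_len_[id] + 2);
      }
    }
  }
  return DataFrame::create(_["subject"] = subj_idx,
                           _["pattern"] = pat_idx,
                           _["start"] = start_pos);
}

// [[Rcpp::export(name = ".ac_size")]]
int ac_size(SEXP handle) {
  XPtr<ACAutomaton> ac(handle);
  return ac->n_patterns_;
}
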