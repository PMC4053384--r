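#include "hex_common.h"
using namespace Rcpp;

// Compressed (Patricia) prefix tree over the 4-letter alphabet.
// Edges carry multi-base labels; sibling edges start with distinct bases;
// terminals carry redundancy counts and the original read ordinals they
// absorbed. Duplicate detection is exact string equality.

struct PTNode {
  std::string edge;          // label on the edge from the parent
  int child[4];
  bool terminal;
  int count;                 // redundancy count (>=1 at terminals)
  std::vector<int> ordinals; // original read ordinals (1-based, R side)
  explicit PTNode(std::string e) : edge(std::move(e)), terminal(false), count(0) {
    child[0] = child[1] = child[2] = child[3] = -1;
  }
};

struct PrefixTree {
  std::vector<PTNode> nodes;
  long long total_inserted = 0;
  long long n_unique = 0;
  PrefixTree() { nodes.emplace_back(std::string()); } // root, empty edge
};

static bool insert_impl(PrefixTree& T, const std::string& seq, int ordinal) {
  if (seq.empty()) stop("cannot insert an empty sequence into the prefix tree");
  for (char ch : seq)
    if (base_code(ch) < 0)
      stop("prefix tree accepts A/C/G/T only (apply the N policy upstream)");
  int cur = 0;
  size_t pos = 0;
  for (;;) {
    if (pos == seq.size()) {
      PTNode& nd = T.nodes[(size_t)cur];
      T.total_inserted++;
      if (nd.terminal) {
        nd.count++;
        nd.ordinals.push_back(ordinal);
        return false; // duplicate
      }
      nd.terminal = true;
      nd.count = 1;
      nd.ordinals.push_back(ordinal);
      T.n_unique++;
      return true;
    }
    int b = base_code(seq[pos]);
    int ch = T.nodes[(size_t)cur].child[b];
    if (ch < 0) {
      T.nodes.emplace_back(seq.substr(pos));
      int leaf = (int)T.nodes.size() - 1;
      T.nodes[(size_t)leaf].terminal = true;
      T.nodes[(size_t)leaf].count = 1;
      T.nodes[(size_t)leaf].ordinals.push_back(ordinal);
      T.nodes[(size_t)cur].child[b] = leaf;
      T.total_inserted++;
      T.n_unique++;
      return true;
    }
    const std::string e = T.nodes[(size_t)ch].edge; // copy: vector may grow
    size_t m = 0;
    while (m < e.size() && pos + m < seq.size() && e[m] == seq[pos + m]) ++m;
    if (m == e.size()) { cur = ch; pos += m; continue; }
    // split the edge at m (1 <= m < |e|): at most one node split per insert
    T.nodes.emplace_back(e.substr(0, m));
    int mid = (int)T.nodes.size() - 1;
    T.nodes[(size_t)ch].edge = e.substr(m);
    T.nodes[(size_t)mid].child[base_code(e[m])] = ch;
    T.nodes[(size_t)cur].child[b] = mid;
    cur = mid;
    pos += m;
  }
}

// Left-maze (A < C < G < T, prefix-terminal before its extensions) traversal;
// every node visited exactly once.
static List traverse_impl(const PrefixTree& T) {
  std::vector<std::string> seqs;
  std::vector<int> counts;
  std::vector<const std::vector<int>*> ords;
  seqs.reserve((size_t)T.n_unique);

  struct Frame { int node; int next; size_t plen; };
  std::string prefix;
  std::vector<Frame> st;
  st.push_back({0, -1, 0});
  while (!st.empty()) {
    size_t top = st.size() - 1;
    if (st[top].next == -1) {
      const PTNode& nd = T.nodes[(size_t)st[top].node];
      prefix.append(nd.edge);
      if (nd.terminal) {
        seqs.push_back(prefix);
        counts.push_back(nd.count);
        ords.push_back(&nd.ordinals);
      }
      st[top].next = 0;
    }
    bool pushed = false;
    while (st[top].next < 4) {
      int b = st[top].next++;
      int c = T.nodes[(size_t)st[top].node].child[b];
      if (c >= 0) {
        st.push_back({c, -1, prefix.size()});
        pushed = true;
        break;
      }
    }
    if (!pushed) {
      prefix.resize(st[top].plen);
      st.pop_back();
    }
  }

  R_xlen_t n = (R_xlen_t)seqs.size();
  CharacterVector rseq(n);
  IntegerVector rcount(n), rcs(n);
  List rords(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    rseq[i] = seqs[(size_t)i];
    rcount[i] = counts[(size_t)i];
    rords[i] = IntegerVector(ords[(size_t)i]->begin(), ords[(size_t)i]->end());
    if (i == 0) { rcs[i] = 0; continue; }
    const std::string& a = seqs[(size_t)i - 1];
    const std::string& b = seqs[(size_t)i];
    size_t m = 0, lim = std::min(a.size(), b.size());
    while (m < lim && a[m] == b[m]) ++m;
    rcs[i] = (int)m;
  }
  return List::create(_["seq"] = rseq, _["count"] = rcount,
                      _["cross_similarity"] = rcs, _["ordinals"] = rords);
}

// [[Rcpp::export]]
SEXP cpp_pt_new() {
  XPtr<PrefixTree> xp(new PrefixTree(), true);
  return xp;
}

// [[Rcpp::export]]
bool cpp_pt_insert(SEXP tree, std::string seq, int ordinal) {
  XPtr<PrefixTree> xp(tree);
  return insert_impl(*xp, seq, ordinal);
}

// [[Rcpp::export]]
LogicalVector cpp_pt_insert_many(SEXP tree, CharacterVector seqs,
                                 IntegerVector ordinals) {
  if (seqs.size() != ordinals.size()) stop("seqs/ordinals length mismatch");
  XPtr<PrefixTree> xp(tree);
  LogicalVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = insert_impl(*xp, as<std::string>(seqs[i]), ordinals[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_pt_traverse(SEXP tree) {
  XPtr<PrefixTree> xp(tree);
  return traverse_impl(*xp);
}

// [[Rcpp::export]]
List cpp_pt_stats(SEXP tree) {
  XPtr<PrefixTree> xp(tree);
  return List::create(_["nodes"] = (double)xp->nodes.size(),
                      _["total_inserted"] = (double)xp->total_inserted,
                      _["unique"] = (double)xp->n_unique);
}
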