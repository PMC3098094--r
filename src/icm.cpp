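#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <stack>

using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else (N) = 4
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<std::vector<uint8_t>> encode_seqs(const CharacterVector& seqs) {
  std::vector<std::vector<uint8_t>> out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = strlen(s);
    out[i].resize(n);
    for (size_t j = 0; j < n; ++j) out[i][j] = (uint8_t) enc(s[j]);
  }
  return out;
}

// chi-square goodness of fit of counts against n * expected, df = 3,
// upper-tail p-value; expected entries must be > 0
static double chisq_pval(const double cnt[4], double n, const double expd[4]) {
  if (n <= 0) return 1.0;
  double x2 = 0.0;
  for (int b = 0; b < 4; ++b) {
    double e = n * expd[b];
    if (e <= 0) {
      if (cnt[b] > 0) return 0.0; // impossible under parent -> maximal evidence
      continue;
    }
    double d = cnt[b] - e;
    x2 += d * d / e;
  }
  return R::pchisq(x2, 3.0, 0, 0);
}

struct IcmNodeRec {
  int split_pos;      // 1..w, 0 = leaf
  int child[4];       // 0 = none (1-based indices)
  double n;           // windows mapped here
  double lambda;
  double pval;        // chi-square p-value vs parent distribution
  double raw[4];
  double interp[4];
};

// Train an interpolated context model.
//
// Windows are the (w+1)-mers of the training sequences; position w+1 is the
// predicted base.  The tree splits greedily on the context position with the
// greatest (conditional) mutual information with the outcome, never reusing a
// position along a path.  Each node's outcome distribution is blended with
// its parent's via lambda = (1 - pval) * n/(n + n0) where pval comes from a
// chi-square test of the node's counts against the parent distribution.
// With interpolate = false lambda is forced to 1 (pure empirical +
// pseudocounts), which together with min_split = 1 reduces the model to a
// fixed order-w Markov chain.
// [[Rcpp::export(name = ".icm_train_cpp")]]
List icm_train_cpp(CharacterVector seqs, int w, int min_split,
                   double pseudo, double n0, double stop_alpha,
                   bool interpolate) {
  if (w < 0 || w > 15) stop("window width w must be in 0..15");
  std::vector<std::vector<uint8_t>> es = encode_seqs(seqs);

  // collect N-free windows: packed context (2 bits per position) + outcome
  std::vector<uint32_t> ctx;
  std::vector<uint8_t> out;
  double trained_bp = 0;
  for (const auto& s : es) {
    trained_bp += s.size();
    if ((int) s.size() < w + 1) continue;
    for (size_t i = (size_t) w; i < s.size(); ++i) {
      bool hasN = false;
      uint32_t c = 0;
      for (int p = 1; p <= w; ++p) {
        uint8_t b = s[i - w + (p - 1)];
        if (b > 3) { hasN = true; break; }
        c |= ((uint32_t) b) << (2 * (p - 1));
      }
      if (hasN || s[i] > 3) continue;
      ctx.push_back(c);
      out.push_back(s[i]);
    }
  }
  size_t nw = ctx.size();
  if (nw == 0)
    stop("no usable training windows at width w=%d; use a smaller w", w);

  std::vector<uint32_t> perm(nw);
  for (size_t i = 0; i < nw; ++i) perm[i] = (uint32_t) i;

  std::vector<IcmNodeRec> nodes;
  nodes.reserve(1024);

  struct Task {
    size_t lo, hi;       // range in perm
    int depth;
    uint32_t used;       // bitmask of used positions (bit p-1)
    int self;            // node index
    double parent[4];    // parent interpolated distribution
  };

  // create root placeholder
  nodes.push_back(IcmNodeRec());
  std::stack<Task> todo;
  Task rootT;
  rootT.lo = 0; rootT.hi = nw; rootT.depth = 0; rootT.used = 0; rootT.self = 0;
  for (int b = 0; b < 4; ++b) rootT.parent[b] = 0.25;
  todo.push(rootT);

  while (!todo.empty()) {
    Task t = todo.top(); todo.pop();
    IcmNodeRec& nd = nodes[t.self];
    nd.split_pos = 0;
    for (int b = 0; b < 4; ++b) nd.child[b] = 0;

    double cnt[4] = {0, 0, 0, 0};
    for (size_t i = t.lo; i < t.hi; ++i) cnt[out[perm[i]]] += 1.0;
    double n = (double) (t.hi - t.lo);
    nd.n = n;

    for (int b = 0; b < 4; ++b)
      nd.raw[b] = (n > 0) ? cnt[b] / n : 0.25;
    double emp[4];
    for (int b = 0; b < 4; ++b)
      emp[b] = (cnt[b] + pseudo) / (n + 4.0 * pseudo);

    double pval = chisq_pval(cnt, n, t.parent);
    nd.pval = pval;
    double q = 1.0 - pval;
    nd.lambda = interpolate ? q * n / (n + n0) : 1.0;
    for (int b = 0; b < 4; ++b)
      nd.interp[b] = nd.lambda * emp[b] + (1.0 - nd.lambda) * t.parent[b];

    bool stop_similar = interpolate && t.depth > 0 && pval > stop_alpha;
    if (t.depth >= w || n < (double) min_split || stop_similar)
      continue; // leaf

    // choose the unused position with maximal mutual information with the
    // outcome; ties go to the position closest to the predicted base
    int best_pos = -1;
    double best_mi = -1.0;
    for (int p = 1; p <= w; ++p) {
      if (t.used & (1u << (p - 1))) continue;
      double joint[4][4] = {{0}};
      for (size_t i = t.lo; i < t.hi; ++i) {
        uint32_t cc = ctx[perm[i]];
        int x = (cc >> (2 * (p - 1))) & 3u;
        joint[x][out[perm[i]]] += 1.0;
      }
      double rx[4] = {0, 0, 0, 0}, ry[4] = {0, 0, 0, 0};
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y) { rx[x] += joint[x][y]; ry[y] += joint[x][y]; }
      double mi = 0.0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y) {
          double f = joint[x][y];
          if (f > 0)
            mi += (f / n) * std::log2(f * n / (rx[x] * ry[y]));
        }
      if (mi > best_mi + 1e-12 ||
          (mi > best_mi - 1e-12 && p > best_pos)) {
        best_mi = mi;
        best_pos = p;
      }
    }
    if (best_pos < 0) continue;

    nd.split_pos = best_pos;
    double interp_copy[4];
    for (int b = 0; b < 4; ++b) interp_copy[b] = nd.interp[b];

    // stable counting sort of perm[lo,hi) by base at best_pos
    size_t start[5] = {0, 0, 0, 0, 0};
    {
      size_t c4[4] = {0, 0, 0, 0};
      for (size_t i = t.lo; i < t.hi; ++i)
        c4[(ctx[perm[i]] >> (2 * (best_pos - 1))) & 3u]++;
      start[0] = t.lo;
      for (int b = 0; b < 4; ++b) start[b + 1] = start[b] + c4[b];
      std::vector<uint32_t> tmp(t.hi - t.lo);
      size_t pos[4] = {start[0] - t.lo, start[1] - t.lo, start[2] - t.lo,
                       start[3] - t.lo};
      for (size_t i = t.lo; i < t.hi; ++i) {
        int b = (ctx[perm[i]] >> (2 * (best_pos - 1))) & 3u;
        tmp[pos[b]++] = perm[i];
      }
      for (size_t i = t.lo; i < t.hi; ++i) perm[i] = tmp[i - t.lo];
    }

    for (int b = 0; b < 4; ++b) {
      nodes.push_back(IcmNodeRec());
      int ci = (int) nodes.size() - 1;
      nodes[t.self].child[b] = ci + 1; // 1-based
      Task ct;
      ct.lo = start[b];
      ct.hi = (b < 3) ? start[b + 1] : t.hi;
      ct.depth = t.depth + 1;
      ct.used = t.used | (1u << (best_pos - 1));
      ct.self = ci;
      for (int bb = 0; bb < 4; ++bb) ct.parent[bb] = interp_copy[bb];
      todo.push(ct);
    }
  }

  // post-prune uninformative splits: a node whose four children are all
  // leaves indistinguishable from it (pval > stop_alpha) becomes a leaf.
  // children were pushed after their parent, so a reverse sweep cascades.
  if (interpolate) {
    for (int i = (int) nodes.size() - 1; i >= 0; --i) {
      if (nodes[i].split_pos == 0) continue;
      bool all_similar = true;
      for (int b = 0; b < 4; ++b) {
        const IcmNodeRec& ch = nodes[nodes[i].child[b] - 1];
        if (ch.split_pos != 0 || ch.pval <= stop_alpha) {
          all_similar = false;
          break;
        }
      }
      if (all_similar) {
        nodes[i].split_pos = 0;
        for (int b = 0; b < 4; ++b) nodes[i].child[b] = 0;
      }
    }
  }

  // compact to reachable nodes (pruning orphans subtrees)
  std::vector<int> keep;
  std::vector<int> remap(nodes.size(), -1);
  {
    std::vector<int> bfs;
    bfs.push_back(0);
    for (size_t h = 0; h < bfs.size(); ++h) {
      int i = bfs[h];
      remap[i] = (int) keep.size();
      keep.push_back(i);
      if (nodes[i].split_pos != 0)
        for (int b = 0; b < 4; ++b) bfs.push_back(nodes[i].child[b] - 1);
    }
  }

  int nn = (int) keep.size();
  IntegerVector split_pos(nn);
  IntegerMatrix children(nn, 4);
  NumericVector nwin(nn), lambda(nn);
  NumericMatrix raw(nn, 4), interp(nn, 4);
  for (int ii = 0; ii < nn; ++ii) {
    const IcmNodeRec& nd = nodes[keep[ii]];
    split_pos[ii] = nd.split_pos;
    nwin[ii] = nd.n;
    lambda[ii] = nd.lambda;
    for (int b = 0; b < 4; ++b) {
      children(ii, b) = nd.split_pos == 0 ? 0 : remap[nd.child[b] - 1] + 1;
      raw(ii, b) = nd.raw[b];
      interp(ii, b) = nd.interp[b];
    }
  }
  return List::create(
      _["split_pos"] = split_pos, _["children"] = children,
      _["n_windows"] = nwin, _["lambda"] = lambda, _["raw_dist"] = raw,
      _["interp_dist"] = interp, _["n_windows_total"] = (double) nw,
      _["trained_bp"] = trained_bp);
}

static double score_one(const std::vector<uint8_t>& s, int w,
                        const IntegerVector& split_pos,
                        const IntegerMatrix& children,
                        const NumericMatrix& interp) {
  const double LOG_Q = std::log(0.25);
  double total = 0.0;
  int lastN = -1; // most recent N position seen (0-based)
  // prime: scan context of first window
  for (int j = 0; j < w && j < (int) s.size(); ++j)
    if (s[j] > 3) lastN = j;
  for (size_t i = (size_t) w; i < s.size(); ++i) {
    if (s[i] > 3) lastN = (int) i;
    if (lastN >= (int) i - w) { total += LOG_Q; continue; }
    int node = 0;
    while (split_pos[node] != 0) {
      int p = split_pos[node];
      int b = s[i - w + (p - 1)];
      node = children(node, b) - 1;
    }
    total += std::log(interp(node, s[i]));
  }
  return total;
}

static std::vector<uint8_t> revcomp_enc(const std::vector<uint8_t>& s) {
  std::vector<uint8_t> r(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    uint8_t b = s[s.size() - 1 - i];
    r[i] = (b > 3) ? 4 : (uint8_t) (3 - b);
  }
  return r;
}

// [[Rcpp::export(name = ".icm_score_cpp")]]
NumericVector icm_score_cpp(CharacterVector seqs, int w,
                            IntegerVector split_pos, IntegerMatrix children,
                            NumericMatrix interp, bool both_max) {
  std::vector<std::vector<uint8_t>> es = encode_seqs(seqs);
  NumericVector res(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if ((int) es[i].size() <= w)
      stop("sequence %d has length <= w = %d and cannot be scored", (int) i + 1, w);
    double fwd = score_one(es[i], w, split_pos, children, interp);
    if (both_max) {
      std::vector<uint8_t> rc = revcomp_enc(es[i]);
      double rev = score_one(rc, w, split_pos, children, interp);
      res[i] = std::max(fwd, rev);
    } else {
      res[i] = fwd;
    }
  }
  return res;
}
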