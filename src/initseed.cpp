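#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// m-mer counts of a sequence's forward strand plus its reverse complement,
// rolling over N-free stretches
static void count_mers(const char* s, size_t n, int m, std::vector<double>& cnt) {
  uint32_t mask = (m >= 16) ? 0xffffffffu : ((1u << (2 * m)) - 1u);
  uint32_t fwd = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = enc(s[i]);
    if (b > 3) { run = 0; fwd = 0; continue; }
    fwd = ((fwd << 2) | (uint32_t) b) & mask;
    if (++run >= m) {
      cnt[fwd] += 1.0;
      // reverse complement of this m-mer
      uint32_t rc = 0, x = fwd;
      for (int j = 0; j < m; ++j) { rc = (rc << 2) | (3u - (x & 3u)); x >>= 2; }
      cnt[rc] += 1.0;
    }
  }
}

// [[Rcpp::export(name = ".kmer_profiles_cpp")]]
NumericMatrix kmer_profiles_cpp(CharacterVector seqs, int m) {
  if (m < 1 || m > 12) stop("k-mer size m must be in 1..12");
  size_t ncol = (size_t) 1 << (2 * m);
  NumericMatrix out(seqs.size(), (int) ncol);
  std::vector<double> cnt(ncol);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    const char* s = CHAR(STRING_ELT(seqs, i));
    count_mers(s, strlen(s), m, cnt);
    double tot = 0;
    for (size_t j = 0; j < ncol; ++j) tot += cnt[j];
    if (tot == 0) {
      for (size_t j = 0; j < ncol; ++j) out(i, j) = 1.0 / ncol;
    } else {
      for (size_t j = 0; j < ncol; ++j) out(i, j) = cnt[j] / tot;
    }
  }
  return out;
}

// per-sequence (context, outcome) transition counts for a fixed-order chain;
// column index = context * 4 + outcome.  With both_strands the reverse
// complement is counted too, so the profile is independent of which strand
// was sequenced.
// [[Rcpp::export(name = ".markov_counts_cpp")]]
NumericMatrix markov_counts_cpp(CharacterVector seqs, int order,
                                bool both_strands) {
  if (order < 0 || order > 8) stop("order must be in 0..8");
  size_t nctx = (size_t) 1 << (2 * order);
  NumericMatrix out(seqs.size(), (int) (nctx * 4));
  uint32_t mask = (order == 0) ? 0u : ((1u << (2 * order)) - 1u);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = strlen(s);
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      uint32_t ctx = 0;
      int run = 0;
      for (size_t j = 0; j < n; ++j) {
        int b = strand == 0 ? enc(s[j]) : enc(s[n - 1 - j]);
        if (strand == 1 && b <= 3) b = 3 - b; // complement
        if (b > 3) { run = 0; ctx = 0; continue; }
        if (run >= order) out(i, (int) (ctx * 4 + b)) += 1.0;
        ctx = ((ctx << 2) | (uint32_t) b) & mask;
        ++run;
      }
    }
  }
  return out;
}

// brute-force k nearest neighbours (Euclidean); ties broken by input order
// [[Rcpp::export(name = ".knn_cpp")]]
List knn_cpp(NumericMatrix pts, int k) {
  int n = pts.nrow(), d = pts.ncol();
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<std::pair<double, int>> cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0;
      for (int t = 0; t < d; ++t) {
        double df = pts(i, t) - pts(j, t);
        s += df * df;
      }
      cand[c++] = std::make_pair(s, j);
    }
    std::stable_sort(cand.begin(), cand.end(),
                     [](const std::pair<double, int>& a,
                        const std::pair<double, int>& b) {
                       if (a.first != b.first) return a.first < b.first;
                       return a.second < b.second;
                     });
    for (int t = 0; t < k; ++t) {
      idx(i, t) = cand[t].second + 1;
      dist(i, t) = std::sqrt(cand[t].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// log-likelihood contribution of one context row of transition counts under
// its own ML distribution with pseudocounts
static inline double row_llk(const double* c, double ps) {
  double tot = c[0] + c[1] + c[2] + c[3];
  if (tot == 0) return 0.0;
  double denom = tot + 4.0 * ps;
  double ll = 0.0;
  for (int b = 0; b < 4; ++b)
    if (c[b] > 0) ll += c[b] * std::log((c[b] + ps) / denom);
  return ll;
}

// Metropolis search over hard assignments: per-cluster fixed-order chains
// (ML counts + pseudocounts), priors = cluster bp share.  Proposals move one
// sequence to another cluster; moves that would empty a cluster are rejected
// so exactly k clusters survive.  Uses R's RNG: seed with set.seed().
// [[Rcpp::export(name = ".likelybin_cpp")]]
List likelybin_cpp(NumericMatrix counts, NumericVector bp, int k,
                   int steps, int n_starts, double pseudo) {
  int n = counts.nrow();
  int ncell = counts.ncol();
  int nctx = ncell / 4;
  if (k < 1) stop("k must be >= 1");
  if (n < k) stop("need at least k sequences");
  double total_bp = 0;
  for (int i = 0; i < n; ++i) total_bp += bp[i];

  // sparse per-sequence context rows
  std::vector<std::vector<int>> seq_rows(n);
  for (int i = 0; i < n; ++i)
    for (int r = 0; r < nctx; ++r)
      for (int b = 0; b < 4; ++b)
        if (counts(i, r * 4 + b) > 0) { seq_rows[i].push_back(r); break; }

  IntegerVector best_z(n);
  double best_ll = R_NegInf;

  for (int st = 0; st < n_starts; ++st) {
    std::vector<int> z(n);
    std::vector<int> nk(k, 0);
    std::vector<double> bpk(k, 0.0);
    // random start guaranteeing non-empty clusters
    for (int i = 0; i < n; ++i)
      z[i] = (i < k) ? i : (int) (unif_rand() * k);
    for (int i = 0; i < n; ++i) { nk[z[i]]++; bpk[z[i]] += bp[i]; }

    std::vector<std::vector<double>> M(k, std::vector<double>(ncell, 0.0));
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < ncell; ++c) M[z[i]][c] += counts(i, c);

    std::vector<double> llk(k, 0.0); // emission term per cluster
    for (int c = 0; c < k; ++c)
      for (int r = 0; r < nctx; ++r) llk[c] += row_llk(&M[c][r * 4], pseudo);
    auto prior_term = [&](int c) {
      return (nk[c] > 0) ? nk[c] * std::log(bpk[c] / total_bp) : 0.0;
    };

    for (int it = 0; k > 1 && it < steps; ++it) {
      int i = (int) (unif_rand() * n);
      if (i >= n) i = n - 1;
      int a = z[i];
      if (nk[a] == 1) continue; // would empty cluster a
      int b = (int) (unif_rand() * (k - 1));
      if (b >= a) ++b;

      double delta = -prior_term(a) - prior_term(b);
      double d_em = 0.0;
      for (int r : seq_rows[i]) {
        d_em -= row_llk(&M[a][r * 4], pseudo) + row_llk(&M[b][r * 4], pseudo);
        double ra[4], rb[4];
        for (int bb = 0; bb < 4; ++bb) {
          double c = counts(i, r * 4 + bb);
          ra[bb] = M[a][r * 4 + bb] - c;
          rb[bb] = M[b][r * 4 + bb] + c;
        }
        d_em += row_llk(ra, pseudo) + row_llk(rb, pseudo);
      }
      // prior after the move
      nk[a]--; nk[b]++; bpk[a] -= bp[i]; bpk[b] += bp[i];
      delta += prior_term(a) + prior_term(b) + d_em;

      bool accept = (delta >= 0) || (unif_rand() < std::exp(delta));
      if (accept) {
        z[i] = b;
        for (int r : seq_rows[i]) {
          d_em = 0; // reuse loop to update cluster matrices and llk
          llk[a] -= row_llk(&M[a][r * 4], pseudo);
          llk[b] -= row_llk(&M[b][r * 4], pseudo);
          for (int bb = 0; bb < 4; ++bb) {
            double c = counts(i, r * 4 + bb);
            M[a][r * 4 + bb] -= c;
            M[b][r * 4 + bb] += c;
          }
          llk[a] += row_llk(&M[a][r * 4], pseudo);
          llk[b] += row_llk(&M[b][r * 4], pseudo);
        }
      } else {
        nk[a]++; nk[b]--; bpk[a] += bp[i]; bpk[b] -= bp[i];
      }
    }

    double total = 0;
    for (int c = 0; c < k; ++c) total += llk[c] + prior_term(c);
    if (total > best_ll) {
      best_ll = total;
      for (int i = 0; i < n; ++i) best_z[i] = z[i];
    }
  }
  return List::create(_["z"] = best_z, _["loglik"] = best_ll);
}
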