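#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Ungapped global identity of two sequences: matching columns / max(length).
// Overhang beyond the shorter sequence counts as mismatched columns; any
// character pair that is not an exact uppercase match (including N) is a
// mismatch. Valid for the equal-length structured-read setting where the
// error model is substitution-only.
static double ungapped_identity(const char *a, int la, const char *b, int lb) {
  int lmin = la < lb ? la : lb;
  int lmax = la < lb ? lb : la;
  if (lmax == 0) return 0.0;
  int m = 0;
  for (int i = 0; i < lmin; ++i)
    if (a[i] == b[i]) ++m;
  return (double)m / (double)lmax;
}

// [[Rcpp::export]]
NumericMatrix identity_matrix_cpp(CharacterVector queries, CharacterVector refs) {
  int n = queries.size(), m = refs.size();
  NumericMatrix out(n, m);
  std::vector<const char *> rp(m);
  std::vector<int> rl(m);
  for (int j = 0; j < m; ++j) {
    rp[j] = CHAR(STRING_ELT(refs, j));
    rl[j] = (int)std::strlen(rp[j]);
  }
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(queries, i));
    int lq = (int)std::strlen(q);
    for (int j = 0; j < m; ++j)
      out(i, j) = ungapped_identity(q, lq, rp[j], rl[j]);
  }
  return out;
}

// Greedy first-fit centroid clustering. `seqs` must already be ordered by
// decreasing abundance (dereplicated uniques). Returns a 1-based cluster id
// per sequence; the first member of each cluster is its centroid.
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double cutoff) {
  int n = seqs.size();
  IntegerVector cl(n);
  std::vector<int> centroid_idx;
  std::vector<const char *> sp(n);
  std::vector<int> sl(n);
  for (int i = 0; i < n; ++i) {
    sp[i] = CHAR(STRING_ELT(seqs, i));
    sl[i] = (int)std::strlen(sp[i]);
  }
  for (int i = 0; i < n; ++i) {
    int hit = -1;
    for (size_t c = 0; c < centroid_idx.size(); ++c) {
      int j = centroid_idx[c];
      if (ungapped_identity(sp[i], sl[i], sp[j], sl[j]) >= cutoff) {
        hit = (int)c;
        break;
      }
    }
    if (hit < 0) {
      centroid_idx.push_back(i);
      hit = (int)centroid_idx.size() - 1;
    }
    cl[i] = hit + 1;
  }
  return cl;
}

// Naive Bayes scoring with bootstrap confidence.
//
// words:   0-based word codes of all queries, concatenated (distinct words
//          per query)
// offsets: length n+1, 0-based offsets into `words` delimiting each query
// logp:    V x G matrix of log conditional word probabilities
// n_boot:  bootstrap trials; each draws floor(W / word_size) (min 1) words
//          with replacement from the query's W distinct words
//
// Returns list(top = 1-based full-score argmax genus (NA if no words),
//              boot = n x G matrix of bootstrap top-genus counts).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List classify_kernel(IntegerVector words, IntegerVector offsets,
                     NumericMatrix logp, int n_boot, int word_size) {
  int n = offsets.size() - 1;
  int G = logp.ncol();
  IntegerVector top(n);
  IntegerMatrix boot(n, G);
  std::vector<double> sc(G);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    int a = offsets[i], b = offsets[i + 1], W = b - a;
    if (W <= 0) {
      top[i] = NA_INTEGER;
      continue;
    }
    for (int g = 0; g < G; ++g) {
      double s = 0.0;
      for (int k = a; k < b; ++k)
        s += logp(words[k], g);
      sc[g] = s;
    }
    int best = 0;
    for (int g = 1; g < G; ++g)
      if (sc[g] > sc[best]) best = g;
    top[i] = best + 1;
    int draw = W / word_size;
    if (draw < 1) draw = 1;
    for (int t = 0; t < n_boot; ++t) {
      for (int g = 0; g < G; ++g) sc[g] = 0.0;
      for (int d = 0; d < draw; ++d) {
        int k = (int)(unif_rand() * W);
        if (k >= W) k = W - 1;
        for (int g = 0; g < G; ++g)
          sc[g] += logp(words[a + k], g);
      }
      int bt = 0;
      for (int g = 1; g < G; ++g)
        if (sc[g] > sc[bt]) bt = g;
      boot(i, bt) += 1;
    }
  }
  return List::create(_["top"] = top, _["boot"] = boot);
}

// Encode all overlapping k-mers of each sequence as base-4 integer codes,
// returning the *distinct* codes per sequence (windows containing non-ACGT
// characters are skipped). Output: list(words = concatenated codes,
// offsets = length n+1).
// [[Rcpp::export]]
List encode_words_cpp(CharacterVector seqs, int k) {
  int n = seqs.size();
  std::vector<int> words;
  IntegerVector offsets(n + 1);
  offsets[0] = 0;
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int)std::strlen(s);
    buf.clear();
    int code = 0, valid = 0; // valid = length of current clean run
    int mask = 1;
    for (int j = 0; j < k - 1; ++j) mask *= 4; // 4^(k-1)
    for (int j = 0; j < L; ++j) {
      int b;
      switch (s[j]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: b = -1;
      }
      if (b < 0) {
        valid = 0;
        code = 0;
        continue;
      }
      if (valid >= k) code -= (code / mask) * mask; // drop leading base
      code = code * 4 + b;
      if (valid < k) ++valid;
      if (valid >= k) buf.push_back(code);
    }
    std::sort(buf.begin(), buf.end());
    buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
    for (size_t j = 0; j < buf.size(); ++j) words.push_back(buf[j]);
    offsets[i + 1] = (int)words.size();
  }
  return List::create(_["words"] = wrap(words), _["offsets"] = offsets);
}
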