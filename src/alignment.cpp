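#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

const double NEG = -1e30;

// One pairwise alignment. Positions are 1-based; 0 in qa/sa marks a gap.
struct Aln {
  double score = 0.0;
  int matches = 0, aln_len = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;
  std::vector<int> qa, sa;
};

// Affine gap convention: a gap run of length L costs open + L * extend.
// Three-state DP (M: residue pair, X: gap in b consuming a, Y: gap in a
// consuming b); all state-to-state transitions allowed.
void local_align(const int* a, int n, const int* b, int m,
                 const double* S, int ns, double go, double ge,
                 bool keep_path, Aln& out) {
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  std::vector<signed char> tM, tX, tY;
  tM.assign((n + 1) * W, 0);
  tX.assign((n + 1) * W, 0);
  tY.assign((n + 1) * W, 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int dg = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j;
      const int lf = i * W + (j - 1);
      const double s = S[ai * ns + b[j - 1]];

      double pm = 0.0;  // local alignments may start anywhere
      signed char tc = 0;
      if (M[dg] > pm) { pm = M[dg]; tc = 1; }
      if (X[dg] > pm) { pm = X[dg]; tc = 2; }
      if (Y[dg] > pm) { pm = Y[dg]; tc = 3; }
      M[idx] = pm + s;
      tM[idx] = tc;

      double px = M[up] - go - ge;
      signed char tx = 1;
      if (X[up] - ge > px) { px = X[up] - ge; tx = 2; }
      if (Y[up] - go - ge > px) { px = Y[up] - go - ge; tx = 3; }
      X[idx] = px;
      tX[idx] = tx;

      double py = M[lf] - go - ge;
      signed char ty = 1;
      if (X[lf] - go - ge > py) { py = X[lf] - go - ge; ty = 2; }
      if (Y[lf] - ge > py) { py = Y[lf] - ge; ty = 3; }
      Y[idx] = py;
      tY[idx] = ty;

      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }

  out.score = best;
  out.matches = 0;
  out.aln_len = 0;
  out.qstart = out.qend = out.sstart = out.send = 0;
  out.qa.clear();
  out.sa.clear();
  if (best <= 0.0) return;

  // Traceback from the best M cell.
  std::vector<int> qa, sa;
  int i = bi, j = bj;
  int state = 1;  // 1=M, 2=X, 3=Y
  while (true) {
    if (state == 1) {
      qa.push_back(i);
      sa.push_back(j);
      if (a[i - 1] == b[j - 1]) ++out.matches;
      signed char tc = tM[i * W + j];
      --i; --j;
      if (tc == 0) break;
      state = tc;
    } else if (state == 2) {
      qa.push_back(i);
      sa.push_back(0);
      signed char tc = tX[i * W + j];
      --i;
      state = tc;
    } else {
      qa.push_back(0);
      sa.push_back(j);
      signed char tc = tY[i * W + j];
      --j;
      state = tc;
    }
  }
  out.aln_len = (int)qa.size();
  out.qstart = i + 1;
  out.qend = bi;
  out.sstart = j + 1;
  out.send = bj;
  if (keep_path) {
    out.qa.assign(qa.rbegin(), qa.rend());
    out.sa.assign(sa.rbegin(), sa.rend());
  }
}

// Global (Needleman-Wunsch) variant, same scoring convention.
void global_align(const int* a, int n, const int* b, int m,
                  const double* S, int ns, double go, double ge,
                  Aln& out) {
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  std::vector<signed char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(go + i * ge);
    tX[i * W] = (signed char)(i == 1 ? 1 : 2);
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(go + j * ge);
    tY[j] = (signed char)(j == 1 ? 1 : 3);
  }
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      const int dg = (i - 1) * W + (j - 1);
      const int up = (i - 1) * W + j;
      const int lf = i * W + (j - 1);
      const double s = S[ai * ns + b[j - 1]];

      double pm = M[dg];
      signed char tc = 1;
      if (X[dg] > pm) { pm = X[dg]; tc = 2; }
      if (Y[dg] > pm) { pm = Y[dg]; tc = 3; }
      M[idx] = pm + s;
      tM[idx] = tc;

      double px = M[up] - go - ge;
      signed char tx = 1;
      if (X[up] - ge > px) { px = X[up] - ge; tx = 2; }
      if (Y[up] - go - ge > px) { px = Y[up] - go - ge; tx = 3; }
      X[idx] = px;
      tX[idx] = tx;

      double py = M[lf] - go - ge;
      signed char ty = 1;
      if (X[lf] - go - ge > py) { py = X[lf] - go - ge; ty = 2; }
      if (Y[lf] - ge > py) { py = Y[lf] - ge; ty = 3; }
      Y[idx] = py;
      tY[idx] = ty;
    }
  }
  int state = 1;
  double sc = M[n * W + m];
  if (X[n * W + m] > sc) { sc = X[n * W + m]; state = 2; }
  if (Y[n * W + m] > sc) { sc = Y[n * W + m]; state = 3; }
  out.score = sc;
  out.matches = 0;

  std::vector<int> qa, sa;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      qa.push_back(i);
      sa.push_back(j);
      if (a[i - 1] == b[j - 1]) ++out.matches;
      state = tM[i * W + j];
      --i; --j;
    } else if (state == 2) {
      qa.push_back(i);
      sa.push_back(0);
      state = tX[i * W + j];
      --i;
    } else {
      qa.push_back(0);
      sa.push_back(j);
      state = tY[i * W + j];
      --j;
    }
  }
  out.aln_len = (int)qa.size();
  out.qstart = 1; out.qend = n; out.sstart = 1; out.send = m;
  out.qa.assign(qa.rbegin(), qa.rend());
  out.sa.assign(sa.rbegin(), sa.rend());
}

}  // namespace

// [[Rcpp::export]]
List cpp_local_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                     double gap_open, double gap_extend, bool keep_path) {
  Aln r;
  local_align(a.begin(), a.size(), b.begin(), b.size(), S.begin(), S.nrow(),
              gap_open, gap_extend, keep_path, r);
  List out = List::create(
      _["score"] = r.score, _["matches"] = r.matches,
      _["aln_length"] = r.aln_len, _["qstart"] = r.qstart,
      _["qend"] = r.qend, _["sstart"] = r.sstart, _["send"] = r.send);
  if (keep_path) {
    out["qa"] = IntegerVector(r.qa.begin(), r.qa.end());
    out["sa"] = IntegerVector(r.sa.begin(), r.sa.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_global_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                      double gap_open, double gap_extend) {
  Aln r;
  global_align(a.begin(), a.size(), b.begin(), b.size(), S.begin(), S.nrow(),
               gap_open, gap_extend, r);
  return List::create(
      _["score"] = r.score, _["matches"] = r.matches,
      _["aln_length"] = r.aln_len,
      _["qa"] = IntegerVector(r.qa.begin(), r.qa.end()),
      _["sa"] = IntegerVector(r.sa.begin(), r.sa.end()));
}

// Batch local alignment over candidate pairs (1-based indices into seqs).
// [[Rcpp::export]]
DataFrame cpp_align_pairs(List seqs, IntegerMatrix pairs, NumericMatrix S,
                          double gap_open, double gap_extend) {
  const int P = pairs.nrow();
  NumericVector score(P);
  IntegerVector matches(P), aln_len(P), qs(P), qe(P), ss(P), se(P);
  std::vector<IntegerVector> sv(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) sv[i] = seqs[i];
  Aln r;
  for (int p = 0; p < P; ++p) {
    const IntegerVector& a = sv[pairs(p, 0) - 1];
    const IntegerVector& b = sv[pairs(p, 1) - 1];
    local_align(a.begin(), a.size(), b.begin(), b.size(), S.begin(), S.nrow(),
                gap_open, gap_extend, false, r);
    score[p] = r.score;
    matches[p] = r.matches;
    aln_len[p] = r.aln_len;
    qs[p] = r.qstart; qe[p] = r.qend; ss[p] = r.sstart; se[p] = r.send;
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["i"] = pairs(_, 0), _["j"] = pairs(_, 1), _["score"] = score,
      _["matches"] = matches, _["aln_length"] = aln_len, _["qstart"] = qs,
      _["qend"] = qe, _["sstart"] = ss, _["send"] = se);
}

// Candidate pair generation from shared k-mers.  Sequences are encoded
// integer vectors over an alphabet of size ns.  A pair (i, j) is emitted
// when the number of distinct shared k-mers reaches
// max(min_abs, ceil(min_frac * min(n_kmers_i, n_kmers_j))).
// [[Rcpp::export]]
IntegerMatrix cpp_candidate_pairs(List seqs, int k, int ns, int min_abs,
                                  double min_frac) {
  const int N = seqs.size();
  std::vector<std::vector<uint64_t>> kmers(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector s = seqs[i];
    const int L = s.size();
    std::vector<uint64_t>& ki = kmers[i];
    if (L >= k) {
      ki.reserve(L - k + 1);
      for (int p = 0; p + k <= L; ++p) {
        uint64_t key = 0;
        for (int q = 0; q < k; ++q) key = key * (uint64_t)ns + (uint64_t)s[p + q];
        ki.push_back(key);
      }
      std::sort(ki.begin(), ki.end());
      ki.erase(std::unique(ki.begin(), ki.end()), ki.end());
    }
  }

  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(1 << 18);
  for (int i = 0; i < N; ++i)
    for (uint64_t key : kmers[i]) index[key].push_back(i);

  std::vector<int> cnt(N, 0), touched;
  std::vector<int> out_i, out_j;
  for (int i = 0; i < N; ++i) {
    touched.clear();
    for (uint64_t key : kmers[i]) {
      const std::vector<int>& lst = index[key];
      for (int j : lst) {
        if (j <= i) continue;
        if (cnt[j] == 0) touched.push_back(j);
        ++cnt[j];
      }
    }
    const double nki = (double)kmers[i].size();
    for (int j : touched) {
      const double nkj = (double)kmers[j].size();
      const double need_f = std::ceil(min_frac * std::min(nki, nkj));
      int need = min_abs > (int)need_f ? min_abs : (int)need_f;
      if (need < 1) need = 1;
      if (cnt[j] >= need) {
        out_i.push_back(i + 1);
        out_j.push_back(j + 1);
      }
      cnt[j] = 0;
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t p = 0; p < out_i.size(); ++p) {
    out(p, 0) = out_i[p];
    out(p, 1) = out_j[p];
  }
  return out;
}
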