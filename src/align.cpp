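// Affine-gap pairwise alignment (Gotoh), global and local, with
// deterministic tie-breaking: diagonal (match/mismatch) preferred over a
// gap in the subject, preferred over a gap in the query. Gap of length L
// costs gap_open + L * gap_ext.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e30;
static const double NEG_CUT = -1e29;   // values below: unreachable state

// [[Rcpp::export(name = ".align_core")]]
List align_core(std::string q, std::string s, NumericMatrix sub,
                double gap_open, double gap_ext, bool local) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // char -> matrix index lookup from dimnames
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(sub);
  for (int i = 0; i < rn.size(); ++i) {
    std::string ch = as<std::string>(rn[i]);
    if (ch.size() == 1) lut[(unsigned char)ch[0]] = i;
  }
  std::vector<int> qi(n), si(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = lut[(unsigned char)q[i]];
    if (qi[i] < 0) stop("character '%s' not in substitution matrix",
                        std::string(1, q[i]));
  }
  for (int j = 0; j < m; ++j) {
    si[j] = lut[(unsigned char)s[j]];
    if (si[j] < 0) stop("character '%s' not in substitution matrix",
                        std::string(1, s[j]));
  }

  const int nA = sub.nrow();
  std::vector<double> SUB(nA * nA);
  for (int a = 0; a < nA; ++a)
    for (int b = 0; b < nA; ++b) SUB[a * nA + b] = sub(a, b);

  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // pointers: 0 none/start, 1 from M, 2 from X, 3 from Y
  std::vector<unsigned char> pm((n + 1) * W, 0), px((n + 1) * W, 0),
      py((n + 1) * W, 0);

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[i * W] = -gap_open - i * gap_ext;
      px[i * W] = (i == 1) ? 1 : 2;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = -gap_open - j * gap_ext;
      py[j] = (j == 1) ? 1 : 3;
    }
  } else {
    for (int i = 1; i <= n; ++i) M[i * W] = NEG;
    for (int j = 1; j <= m; ++j) M[j] = NEG;
  }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: q[i] aligned to s[j]
      double sc = SUB[qi[i - 1] * nA + si[j - 1]];
      double vm = M[d], vx = X[d], vy = Y[d];
      double pv = vm; unsigned char pt = 1;
      if (vx > pv) { pv = vx; pt = 2; }
      if (vy > pv) { pv = vy; pt = 3; }
      if (local && pv < 0.0) { pv = 0.0; pt = 0; }
      M[c] = (pv < NEG_CUT) ? NEG : pv + sc;
      pm[c] = pt;
      if (local && M[c] < 0.0) { M[c] = NEG; pm[c] = 0; }
      // X: q[i] aligned to a gap (gap in subject string)
      double xo = M[u] - gap_open - gap_ext;
      double xe = X[u] - gap_ext;
      double xy = Y[u] - gap_open - gap_ext;
      X[c] = xo; px[c] = 1;
      if (xe > X[c]) { X[c] = xe; px[c] = 2; }
      if (xy > X[c]) { X[c] = xy; px[c] = 3; }
      // Y: s[j] aligned to a gap (gap in query string)
      double yo = M[l] - gap_open - gap_ext;
      double ye = Y[l] - gap_ext;
      double yx = X[l] - gap_open - gap_ext;
      Y[c] = yo; py[c] = 1;
      if (ye > Y[c]) { Y[c] = ye; py[c] = 3; }
      if (yx > Y[c]) { Y[c] = yx; py[c] = 2; }
      if (local && M[c] > best && M[c] > NEG_CUT) {
        best = M[c]; bi = i; bj = j;
      }
    }
  }

  // choose traceback start
  int i, j, state; // state 1 M, 2 X, 3 Y
  double score;
  if (local) {
    if (bi == 0) { // no positive-scoring cell
      return List::create(_["score"] = 0.0, _["empty"] = true);
    }
    i = bi; j = bj; state = 1; score = best;
  } else {
    i = n; j = m;
    const int c = n * W + m;
    score = M[c]; state = 1;
    if (X[c] > score) { score = X[c]; state = 2; }
    if (Y[c] > score) { score = Y[c]; state = 3; }
  }

  std::string a1, a2;
  int qe = i, se = j;
  bool done = false;
  while (!done && (i > 0 || j > 0)) {
    const int c = i * W + j;
    unsigned char pt;
    if (state == 1) {
      pt = pm[c];
      a1.push_back(q[i - 1]);
      a2.push_back(s[j - 1]);
      --i; --j;
      if (local && pt == 0) done = true;   // fresh start of a local chain
      state = (pt == 0) ? 1 : pt;
    } else if (state == 2) {
      pt = px[c];
      a1.push_back(q[i - 1]);
      a2.push_back('-');
      --i;
      state = pt;
    } else {
      pt = py[c];
      a1.push_back('-');
      a2.push_back(s[j - 1]);
      --j;
      state = pt;
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());

  int matches = 0, mismatches = 0, gap_opens = 0;
  bool in1 = false, in2 = false;
  for (size_t k = 0; k < a1.size(); ++k) {
    if (a1[k] == '-') { if (!in1) { ++gap_opens; in1 = true; } in2 = false; }
    else if (a2[k] == '-') { if (!in2) { ++gap_opens; in2 = true; } in1 = false; }
    else {
      in1 = in2 = false;
      if (a1[k] == a2[k]) ++matches; else ++mismatches;
    }
  }
  int qs = i + 1, ss = j + 1;
  return List::create(
      _["score"] = score, _["a1"] = a1, _["a2"] = a2,
      _["q_start"] = local ? qs : 1, _["q_end"] = local ? qe : n,
      _["s_start"] = local ? ss : 1, _["s_end"] = local ? se : m,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gap_opens"] = gap_opens, _["aln_length"] = (int)a1.size(),
      _["empty"] = false);
}
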