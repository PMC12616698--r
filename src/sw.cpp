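#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh).
// A gap of length k costs gapOpen + k * gapExtend.
// Deterministic: among equally scoring end cells the smallest row, then
// smallest column wins; within a traceback cell the preference is
// diagonal > up (gap in b) > left (gap in a).
//
// Strategy: a linear-memory score-only forward pass locates the optimal
// end cell; a reverse pass locates the start cell; the full
// traceback matrix is then built only on that subrectangle, so low-scoring
// pairs cost little more than two linear passes.

namespace {

const int NEG = -1000000000;

struct ScoreTable {
  int tab[128][128];
  bool legal[128];

  ScoreTable(const IntegerMatrix& mat, const std::string& alphabet) {
    std::memset(tab, 0, sizeof(tab));
    std::memset(legal, 0, sizeof(legal));
    const int n = alphabet.size();
    for (int i = 0; i < n; ++i) legal[(unsigned char)alphabet[i]] = true;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        tab[(unsigned char)alphabet[i]][(unsigned char)alphabet[j]] =
            mat(i, j);
  }

  void check(const std::string& s, const char* which) const {
    for (size_t i = 0; i < s.size(); ++i)
      if (!legal[(unsigned char)s[i]])
        stop("illegal character '%s' at position %d of %s sequence",
             std::string(1, s[i]).c_str(), (int)(i + 1), which);
  }
};

struct BestCell {
  int score = 0, i = 0, j = 0;
};

// linear-memory forward pass; if `last` is false the first best cell in
// (row, column) order is kept, otherwise the last one
BestCell sw_forward(const char* a, int n, const char* b, int m,
                    const ScoreTable& st, int gapOpen, int gapExtend,
                    bool last) {
  const int gapFirst = gapOpen + gapExtend;
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  BestCell best;
  for (int i = 1; i <= n; ++i) {
    const int ai = (unsigned char)a[i - 1];
    int Hdiag = 0, E = NEG;
    for (int j = 1; j <= m; ++j) {
      E = std::max(H[j - 1] - gapFirst, E - gapExtend);
      F[j] = std::max(H[j] - gapFirst, F[j] - gapExtend);
      int h = Hdiag + st.tab[ai][(unsigned char)b[j - 1]];
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      if (h > best.score || (last && h == best.score && h > 0)) {
        best.score = h; best.i = i; best.j = j;
      }
    }
  }
  return best;
}

enum { PTR_STOP = 0, PTR_DIAG = 1, PTR_UP = 2, PTR_LEFT = 3 };

struct AlnStats {
  int score = 0, matches = 0, columns = 0;
  int qstart = 0, qend = 0, tstart = 0, tend = 0;
};

// full DP with traceback on a (sub)sequence pair; coordinates are local
AlnStats sw_traceback(const char* a, int n, const char* b, int m,
                      const ScoreTable& st, int gapOpen, int gapExtend) {
  const int gapFirst = gapOpen + gapExtend;
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> F((size_t)(n + 1) * (m + 1), NEG);
  std::vector<unsigned char> ptrH((size_t)(n + 1) * (m + 1), PTR_STOP);
  std::vector<unsigned char> extE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> extF((size_t)(n + 1) * (m + 1), 0);

  AlnStats out;
  int bi = 0, bj = 0, best = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = (unsigned char)a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t k = (size_t)i * (m + 1) + j;
      const size_t kup = k - (m + 1), kleft = k - 1, kdiag = kup - 1;

      int eOpen = H[kleft] - gapFirst, eExt = E[kleft] - gapExtend;
      E[k] = eOpen >= eExt ? eOpen : eExt;
      extE[k] = eOpen >= eExt ? 0 : 1;

      int fOpen = H[kup] - gapFirst, fExt = F[kup] - gapExtend;
      F[k] = fOpen >= fExt ? fOpen : fExt;
      extF[k] = fOpen >= fExt ? 0 : 1;

      int diag = H[kdiag] + st.tab[ai][(unsigned char)b[j - 1]];
      int h = 0;
      unsigned char p = PTR_STOP;
      if (diag > h) { h = diag; p = PTR_DIAG; }
      if (F[k] > h) { h = F[k]; p = PTR_UP; }
      if (E[k] > h) { h = E[k]; p = PTR_LEFT; }
      H[k] = h;
      ptrH[k] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return out;

  int i = bi, j = bj;
  out.score = best;
  out.qend = bi; out.tend = bj; out.qstart = bi; out.tstart = bj;
  while (i > 0 && j > 0) {
    const size_t k = (size_t)i * (m + 1) + j;
    unsigned char p = ptrH[k];
    if (p == PTR_STOP) break;
    if (p == PTR_DIAG) {
      out.qstart = i; out.tstart = j;
      ++out.columns;
      if (a[i - 1] == b[j - 1]) ++out.matches;
      --i; --j;
    } else if (p == PTR_UP) {
      while (true) {
        const size_t kk = (size_t)i * (m + 1) + j;
        ++out.columns;
        out.qstart = i;
        bool ext = extF[kk];
        --i;
        if (!ext) break;
      }
    } else {
      while (true) {
        const size_t kk = (size_t)i * (m + 1) + j;
        ++out.columns;
        out.tstart = j;
        bool ext = extE[kk];
        --j;
        if (!ext) break;
      }
    }
  }
  return out;
}

// end cell by forward pass, start cell by reverse pass, traceback on the
// subrectangle only
AlnStats sw_stats(const std::string& a, const std::string& b,
                  const ScoreTable& st, int gapOpen, int gapExtend) {
  const int n = a.size(), m = b.size();
  AlnStats none;
  BestCell fwd = sw_forward(a.c_str(), n, b.c_str(), m, st, gapOpen,
                            gapExtend, false);
  if (fwd.score <= 0) return none;

  std::string ar(a.rbegin() + (n - fwd.i), a.rend());
  std::string br(b.rbegin() + (m - fwd.j), b.rend());
  // keep the LAST cell reaching the score: largest reversed indices give
  // the smallest start, so the subrectangle covers the longest optimum
  BestCell rev = sw_forward(ar.c_str(), fwd.i, br.c_str(), fwd.j, st,
                            gapOpen, gapExtend, true);
  int qs = fwd.i - rev.i + 1, ts = fwd.j - rev.j + 1;

  AlnStats s = sw_traceback(a.c_str() + (qs - 1), fwd.i - qs + 1,
                            b.c_str() + (ts - 1), fwd.j - ts + 1, st,
                            gapOpen, gapExtend);
  s.qstart += qs - 1; s.qend += qs - 1;
  s.tstart += ts - 1; s.tend += ts - 1;
  return s;
}

List statsToList(const AlnStats& s) {
  if (s.score <= 0) return List::create(_["score"] = 0);
  return List::create(
      _["score"] = s.score, _["matches"] = s.matches,
      _["columns"] = s.columns, _["qstart"] = s.qstart,
      _["qend"] = s.qend, _["tstart"] = s.tstart, _["tend"] = s.tend);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(std::string a, std::string b, IntegerMatrix mat,
                  std::string alphabet, int gapOpen, int gapExtend) {
  ScoreTable st(mat, alphabet);
  st.check(a, "query");
  st.check(b, "target");
  return statsToList(sw_stats(a, b, st, gapOpen, gapExtend));
}

// All query x target pairs whose alignment score is >= minScore, with
// alignment statistics. The engine behind panel search, duplication
// indexing and core detection.
// [[Rcpp::export(name = ".cpp_sw_table")]]
DataFrame cpp_sw_table(CharacterVector queries, CharacterVector targets,
                       IntegerMatrix mat, std::string alphabet, int gapOpen,
                       int gapExtend, int minScore) {
  ScoreTable st(mat, alphabet);
  std::vector<std::string> qs(queries.size()), ts(targets.size());
  for (int i = 0; i < queries.size(); ++i) {
    qs[i] = as<std::string>(queries[i]);
    st.check(qs[i], "query");
  }
  for (int j = 0; j < targets.size(); ++j) {
    ts[j] = as<std::string>(targets[j]);
    st.check(ts[j], "target");
  }
  std::vector<int> qi, ti, score, matches, cols, q1, q2, t1, t2;
  for (size_t i = 0; i < qs.size(); ++i) {
    for (size_t j = 0; j < ts.size(); ++j) {
      AlnStats s = sw_stats(qs[i], ts[j], st, gapOpen, gapExtend);
      if (s.score < minScore || s.score <= 0) continue;
      qi.push_back(i + 1);
      ti.push_back(j + 1);
      score.push_back(s.score);
      matches.push_back(s.matches);
      cols.push_back(s.columns);
      q1.push_back(s.qstart);
      q2.push_back(s.qend);
      t1.push_back(s.tstart);
      t2.push_back(s.tend);
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["qi"] = qi, _["ti"] = ti, _["score"] = score, _["matches"] = matches,
      _["columns"] = cols, _["qstart"] = q1, _["qend"] = q2, _["tstart"] = t1,
      _["tend"] = t2);
}

// Does `query` have any target passing identity (percent, over aligned
// columns) and query-side coverage (fraction) thresholds? Exhaustive scan
// with early exit on the first qualifying hit.
// [[Rcpp::export(name = ".cpp_any_hit")]]
bool cpp_any_hit(std::string query, CharacterVector targets, IntegerMatrix mat,
                 std::string alphabet, int gapOpen, int gapExtend,
                 double minIdentity, double minQueryCoverage) {
  ScoreTable st(mat, alphabet);
  st.check(query, "query");
  const int qlen = query.size();
  for (int j = 0; j < targets.size(); ++j) {
    std::string t = as<std::string>(targets[j]);
    st.check(t, "target");
    AlnStats s = sw_stats(query, t, st, gapOpen, gapExtend);
    if (s.score <= 0 || s.columns == 0) continue;
    double ident = 100.0 * s.matches / s.columns;
    double cov = (double)(s.qend - s.qstart + 1) / qlen;
    if (ident >= minIdentity && cov >= minQueryCoverage) return true;
    if (j % 16 == 15) Rcpp::checkUserInterrupt();
  }
  return false;
}
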