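#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Gap of length L costs
// gap_open + (L - 1) * gap_ext, both passed as positive penalties.
// Identity bookkeeping: matches / alignment columns, gaps count as columns.

namespace {

const double NEG_INF = -1e18;

struct TB {
  // 0 = stop/none, 1 = diagonal, 2 = up (gap in b), 3 = left (gap in a)
  std::vector<unsigned char> h, e, f; // e/f: 1 = came from H (open), 0 = extend
  int ncol;
  TB(int m, int n) : h((m + 1) * (n + 1), 0), e((m + 1) * (n + 1), 0),
                     f((m + 1) * (n + 1), 0), ncol(n + 1) {}
  inline int at(int i, int j) const { return i * ncol + j; }
};

inline double subst(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch; // ambiguous base never counts as match
  return (a == b) ? match : mismatch;
}

List traceback(const std::string& a, const std::string& b, const TB& tb,
               int bi, int bj, bool local, double score) {
  int i = bi, j = bj;
  int matches = 0, columns = 0;
  int state = 0; // 0 = H, 1 = E (left), 2 = F (up)
  std::string qa, qb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char d = tb.h[tb.at(i, j)];
      if (d == 0) break; // local start
      if (d == 1) {
        ++columns;
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ++matches;
        qa.push_back(a[i - 1]); qb.push_back(b[j - 1]);
        --i; --j;
      } else if (d == 3) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in a, consume b[j]
      ++columns;
      qa.push_back('-'); qb.push_back(b[j - 1]);
      unsigned char opened = tb.e[tb.at(i, j)];
      --j;
      if (opened) state = 0;
    } else { // gap in b, consume a[i]
      ++columns;
      qa.push_back(a[i - 1]); qb.push_back('-');
      unsigned char opened = tb.f[tb.at(i, j)];
      --i;
      if (opened) state = 0;
    }
    if (!local && i == 0 && j == 0) break;
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(qb.begin(), qb.end());
  double pid = columns > 0 ? 100.0 * matches / columns : 0.0;
  return List::create(
    _["score"] = score,
    _["q_start"] = i + 1, _["q_end"] = bi,
    _["s_start"] = j + 1, _["s_end"] = bj,
    _["matches"] = matches, _["columns"] = columns,
    _["pct_identity"] = pid,
    _["aligned_a"] = qa, _["aligned_b"] = qb);
}

} // namespace

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, double match, double mismatch,
                    double gap_open, double gap_ext, bool local) {
  int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  std::vector<double> Hprev(n + 1), Hcur(n + 1), Eprev(n + 1), Ecur(n + 1),
      Fprev(n + 1), Fcur(n + 1);
  TB tb(m, n);

  // row 0
  for (int j = 0; j <= n; ++j) {
    Eprev[j] = NEG_INF; Fprev[j] = NEG_INF;
    if (local) {
      Hprev[j] = 0.0;
    } else {
      if (j == 0) Hprev[j] = 0.0;
      else {
        Hprev[j] = -(gap_open + (j - 1) * gap_ext);
        tb.h[tb.at(0, j)] = 3;
        tb.e[tb.at(0, j)] = (j == 1) ? 1 : 0;
        Eprev[j] = Hprev[j];
      }
    }
  }

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    Ecur[0] = NEG_INF;
    if (local) {
      Hcur[0] = 0.0; Fcur[0] = NEG_INF;
    } else {
      Hcur[0] = -(gap_open + (i - 1) * gap_ext);
      tb.h[tb.at(i, 0)] = 2;
      tb.f[tb.at(i, 0)] = (i == 1) ? 1 : 0;
      Fcur[0] = Hcur[0];
    }
    for (int j = 1; j <= n; ++j) {
      // E: gap in a (move left)
      double e_open = Hcur[j - 1] - gap_open;
      double e_ext = Ecur[j - 1] - gap_ext;
      if (e_open >= e_ext) { Ecur[j] = e_open; tb.e[tb.at(i, j)] = 1; }
      else { Ecur[j] = e_ext; tb.e[tb.at(i, j)] = 0; }
      // F: gap in b (move up)
      double f_open = Hprev[j] - gap_open;
      double f_ext = Fprev[j] - gap_ext;
      if (f_open >= f_ext) { Fcur[j] = f_open; tb.f[tb.at(i, j)] = 1; }
      else { Fcur[j] = f_ext; tb.f[tb.at(i, j)] = 0; }

      double diag = Hprev[j - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      double h = diag; unsigned char dir = 1;
      if (Ecur[j] > h) { h = Ecur[j]; dir = 3; }
      if (Fcur[j] > h) { h = Fcur[j]; dir = 2; }
      if (local && h <= 0.0) { h = 0.0; dir = 0; }
      Hcur[j] = h; tb.h[tb.at(i, j)] = dir;
      if (local) {
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (!local) { best = Hprev[n]; bi = m; bj = n; }
  if (local && best <= 0.0)
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["matches"] = 0,
                        _["columns"] = 0, _["pct_identity"] = 0.0,
                        _["aligned_a"] = "", _["aligned_b"] = "");
  return traceback(a, b, tb, bi, bj, local, best);
}
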