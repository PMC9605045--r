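#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Global pairwise alignment with an asymmetric affine gap model in which
// gaps are scored by which sequence they fall in (target = first sequence,
// query = second) and by where they fall (left overhang, internal, right
// overhang). A gap of length L costs open + (L-1) * extend. A dash in the
// target row is a "target gap" (query residue unmatched); a dash in the
// query row is a "query gap".
//
// States: M  (a[i-1] ~ b[j-1]),
//         X  (a[i-1] ~ '-',  gap in query row; class decided by j),
//         Y  ('-' ~ b[j-1],  gap in target row; class decided by i).
//
// An optional diagonal band (|j - i*m/n| <= band) restricts the search to
// near-colinear alignments; band <= 0 means the full matrix.

static const double NEG_INF = -1e30;

static inline int code_of(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N and anything else never matches
  }
}

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b, List params,
                    bool traceback = true, int band = 0) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  if (n == 0 || m == 0)
    stop("align_pair: both sequences must be non-empty");

  const double match    = as<double>(params["match"]);
  const double mismatch = as<double>(params["mismatch"]);
  const double tl_open = as<double>(params["target_left_open"]);
  const double tl_ext  = as<double>(params["target_left_extend"]);
  const double ti_open = as<double>(params["target_internal_open"]);
  const double ti_ext  = as<double>(params["target_internal_extend"]);
  const double tr_open = as<double>(params["target_right_open"]);
  const double tr_ext  = as<double>(params["target_right_extend"]);
  const double ql_open = as<double>(params["query_left_open"]);
  const double ql_ext  = as<double>(params["query_left_extend"]);
  const double qi_open = as<double>(params["query_internal_open"]);
  const double qi_ext  = as<double>(params["query_internal_extend"]);
  const double qr_open = as<double>(params["query_right_open"]);
  const double qr_ext  = as<double>(params["query_right_extend"]);

  std::vector<int> ac(n), bc(m);
  for (int i = 0; i < n; ++i) ac[i] = code_of(a[(size_t)i]);
  for (int j = 0; j < m; ++j) bc[j] = code_of(b[(size_t)j]);
  double smat[25];
  for (int u = 0; u < 5; ++u)
    for (int v = 0; v < 5; ++v)
      smat[u * 5 + v] = (u == v && u < 4) ? match : mismatch;

  const size_t W = (size_t)(m + 1);
  std::vector<double> Mp(W, NEG_INF), Xp(W, NEG_INF), Yp(W, NEG_INF),
                      Mc(W, NEG_INF), Xc(W, NEG_INF), Yc(W, NEG_INF);
  std::vector<uint8_t> tbM, tbX, tbY;
  if (traceback) {
    tbM.assign((size_t)(n + 1) * W, 3);
    tbX.assign((size_t)(n + 1) * W, 3);
    tbY.assign((size_t)(n + 1) * W, 3);
  }

  // row i = 0: leading gaps in target (target-left class)
  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Yp[j] = (j == 1) ? tl_open : Yp[j - 1] + tl_ext;
    if (traceback) tbY[(size_t)j] = (j == 1) ? 0 : 2;
  }

  int prev_jhi = m;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band > 0) {
      const int jc = (int)(((long long)i * m) / n);
      jlo = jc - band; if (jlo < 1) jlo = 1;
      jhi = jc + band; if (jhi > m) jhi = m;
    }
    const int ai = ac[(size_t)i - 1];
    const double* srow = smat + ai * 5;
    // Y gap class is constant within the row
    const double ty_open = (i == n) ? tr_open : ti_open;
    const double ty_ext  = (i == n) ? tr_ext : ti_ext;

    // j = 0 column: leading gap in query (query-left class)
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    if (jlo == 1) {
      Xc[0] = (i == 1) ? ql_open : Xp[0] + ql_ext;
      if (traceback) tbX[(size_t)i * W] = (i == 1) ? 0 : 1;
    } else {
      Xc[0] = NEG_INF;
      Mc[jlo - 1] = Xc[jlo - 1] = Yc[jlo - 1] = NEG_INF;
    }

    for (int j = jlo; j <= jhi; ++j) {
      // M from diagonal
      double diag = Mp[j - 1]; uint8_t st = 0;
      if (Xp[j - 1] > diag) { diag = Xp[j - 1]; st = 1; }
      if (Yp[j - 1] > diag) { diag = Yp[j - 1]; st = 2; }
      const double mcur = diag + srow[bc[(size_t)j - 1]];
      Mc[j] = mcur;

      // X: gap in query row (class by j; j >= 1 here)
      const double gxo = (j == m) ? qr_open : qi_open;
      const double gxe = (j == m) ? qr_ext : qi_ext;
      double xbest = Mp[j] + gxo; uint8_t xs = 0;
      if (Yp[j] + gxo > xbest) { xbest = Yp[j] + gxo; xs = 2; }
      if (Xp[j] + gxe > xbest) { xbest = Xp[j] + gxe; xs = 1; }
      Xc[j] = xbest;

      // Y: gap in target row (class by i, hoisted)
      double ybest = mcur + ty_open; uint8_t ys = 0;
      if (Xc[j - 1] + ty_open > ybest) { ybest = Xc[j - 1] + ty_open; ys = 1; }
      if (Yc[j - 1] + ty_ext > ybest) { ybest = Yc[j - 1] + ty_ext; ys = 2; }
      Yc[j] = ybest;

      if (traceback) {
        const size_t off = (size_t)i * W + j;
        tbM[off] = st; tbX[off] = xs; tbY[off] = ys;
      }
    }
    // invalidate stale cells beyond this row's band that the next row
    // might read (the band center advances by at most a few columns)
    if (band > 0) {
      for (int j = jhi + 1; j <= m && j <= jhi + 8; ++j)
        Mc[j] = Xc[j] = Yc[j] = NEG_INF;
    }
    prev_jhi = jhi;
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  (void) prev_jhi;

  double score = Mp[m]; uint8_t final_st = 0;
  if (Xp[m] > score) { score = Xp[m]; final_st = 1; }
  if (Yp[m] > score) { score = Yp[m]; final_st = 2; }
  if (score <= NEG_INF / 2)
    stop("align_pair: band too narrow for these sequences");

  if (!traceback)
    return List::create(_["score"] = score);

  std::string ag, bg;
  ag.reserve((size_t)(n + m)); bg.reserve((size_t)(n + m));
  int i = n, j = m; uint8_t st = final_st;
  int matches = 0, mismatches = 0, aligned_cols = 0;
  while (i > 0 || j > 0) {
    if (st == 0) {
      uint8_t prev = tbM[(size_t)i * W + j];
      ag.push_back(a[(size_t)i - 1]); bg.push_back(b[(size_t)j - 1]);
      ++aligned_cols;
      if (ac[(size_t)i - 1] == bc[(size_t)j - 1] && ac[(size_t)i - 1] < 4)
        ++matches;
      else ++mismatches;
      --i; --j; st = prev;
    } else if (st == 1) {
      uint8_t prev = tbX[(size_t)i * W + j];
      ag.push_back(a[(size_t)i - 1]); bg.push_back('-');
      --i; st = prev;
    } else {
      uint8_t prev = tbY[(size_t)i * W + j];
      ag.push_back('-'); bg.push_back(b[(size_t)j - 1]);
      --j; st = prev;
    }
  }
  std::reverse(ag.begin(), ag.end());
  std::reverse(bg.begin(), bg.end());

  // query (b) interval spanned by the target's residues (0-based half-open)
  int b_start = -1, b_end = -1, bcount = 0;
  for (size_t k = 0; k < ag.size(); ++k) {
    const bool bres = bg[k] != '-';
    if (ag[k] != '-') {
      if (b_start < 0) b_start = bcount;
      b_end = bcount + (bres ? 1 : 0);
    }
    if (bres) ++bcount;
  }

  return List::create(
    _["score"] = score,
    _["target_gapped"] = ag,
    _["query_gapped"] = bg,
    _["query_start"] = b_start,
    _["query_end"] = b_end,
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["aligned_cols"] = aligned_cols);
}
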