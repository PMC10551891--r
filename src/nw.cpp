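#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Needleman-Wunsch / Gotoh, three states).
// Gap cost convention: a gap of length L costs gap_open + (L-1)*gap_extend.
// End gaps are penalized (true global alignment).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct AlnResult {
  double score;
  double identity;
  std::string al_a, al_b;
};

static AlnResult align_one(const std::string& a, const std::string& b,
                           const std::vector<std::vector<double> >& S,
                           const int* code, double go, double ge) {
  const int n = a.size(), m = b.size();
  // state 0 = M (match/mismatch), 1 = Ix (gap in b / consume a),
  // 2 = Iy (gap in a / consume b)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tb(3 * (n + 1) * (m + 1), 0);
  const int W = m + 1;
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * W] = -(go + (i - 1) * ge);
    tb[1 * (n + 1) * W + i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -(go + (j - 1) * ge);
    tb[2 * (n + 1) * W + j] = (j == 1) ? 0 : 2;
  }
  std::vector<int> ca(n), cb(m);
  for (int i = 0; i < n; ++i) ca[i] = code[(unsigned char)a[i]];
  for (int j = 0; j < m; ++j) cb[j] = code[(unsigned char)b[j]];
  unsigned char* tbM = &tb[0];
  unsigned char* tbX = &tb[(size_t)(n + 1) * W];
  unsigned char* tbY = &tb[2 * (size_t)(n + 1) * W];
  for (int i = 1; i <= n; ++i) {
    const std::vector<double>& srow = S[ca[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j, d = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M
      double best = M[d]; unsigned char who = 0;
      if (Ix[d] > best) { best = Ix[d]; who = 1; }
      if (Iy[d] > best) { best = Iy[d]; who = 2; }
      M[ij] = best + srow[cb[j - 1]];
      tbM[ij] = who;
      // Ix: consume a[i], gap in b
      best = M[up] - go; who = 0;
      if (Ix[up] - ge > best) { best = Ix[up] - ge; who = 1; }
      if (Iy[up] - go > best) { best = Iy[up] - go; who = 2; }
      Ix[ij] = best; tbX[ij] = who;
      // Iy: consume b[j], gap in a
      best = M[lf] - go; who = 0;
      if (Ix[lf] - go > best) { best = Ix[lf] - go; who = 1; }
      if (Iy[lf] - ge > best) { best = Iy[lf] - ge; who = 2; }
      Iy[ij] = best; tbY[ij] = who;
    }
  }
  const int end = n * W + m;
  int state = 0; double sc = M[end];
  if (Ix[end] > sc) { sc = Ix[end]; state = 1; }
  if (Iy[end] > sc) { sc = Iy[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (state == 0) {
      unsigned char prev = tbM[ij];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      unsigned char prev = tbX[ij];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      unsigned char prev = tbY[ij];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int ident = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] == rb[k] && ra[k] != '-') ++ident;
  AlnResult res;
  res.score = sc;
  res.identity = ra.empty() ? 0.0 : (double)ident / ra.size();
  res.al_a = ra; res.al_b = rb;
  return res;
}

// [[Rcpp::export(name = ".nw_align_batch")]]
List nw_align_batch(CharacterVector a, CharacterVector b, NumericMatrix sub,
                    std::string alphabet, double gap_open, double gap_extend) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  const int na = alphabet.size();
  if (sub.nrow() != na || sub.ncol() != na)
    stop("substitution matrix does not match alphabet");
  int code[256];
  for (int k = 0; k < 256; ++k) code[k] = -1;
  for (int k = 0; k < na; ++k) code[(unsigned char)alphabet[k]] = k;
  std::vector<std::vector<double> > S(na, std::vector<double>(na));
  for (int x = 0; x < na; ++x)
    for (int y = 0; y < na; ++y) S[x][y] = sub(x, y);
  const int N = a.size();
  NumericVector score(N), identity(N);
  CharacterVector al_a(N), al_b(N);
  for (int k = 0; k < N; ++k) {
    std::string sa = as<std::string>(a[k]), sb = as<std::string>(b[k]);
    if (sa.empty() || sb.empty()) stop("sequences must be non-empty");
    for (size_t t = 0; t < sa.size(); ++t)
      if (code[(unsigned char)sa[t]] < 0) stop("invalid residue in sequence");
    for (size_t t = 0; t < sb.size(); ++t)
      if (code[(unsigned char)sb[t]] < 0) stop("invalid residue in sequence");
    AlnResult r = align_one(sa, sb, S, code, gap_open, gap_extend);
    score[k] = r.score; identity[k] = r.identity;
    al_a[k] = r.al_a; al_b[k] = r.al_b;
  }
  return List::create(_["aligned_a"] = al_a, _["aligned_b"] = al_b,
                      _["score"] = score, _["identity"] = identity);
}
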