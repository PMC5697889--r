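// Exact affine-gap Smith-Waterman local alignment (Gotoh recurrences) over
// an integer substitution matrix.
//
// Two kernels share the recurrences: a lean score-only pass used for the
// all-vs-all score matrix, and a counter-propagating pass that carries the
// number of exact residue matches and aligned columns (gap columns
// included) of the optimal path through the DP, so percent identity and
// alignable-region coverage come out without traceback storage. Reciprocal
// best-hit search scores every pair but evaluates identity/coverage only
// for best-hit candidates, in descending score order. Ties prefer
// substitution continuation over gap states within the DP; candidate ties
// prefer higher identity, then lower subject index.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

static const int NEG = -1000000000;

static std::vector<int> encode(const char* s, const int* lut) {
  size_t n = std::strlen(s);
  std::vector<int> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = lut[(unsigned char)s[i]];
  return v;
}

static void build_lut(const std::string& alphabet, int* lut) {
  int x_idx = 0;
  for (size_t k = 0; k < alphabet.size(); ++k)
    if (alphabet[k] == 'X') x_idx = (int)k;
  for (int c = 0; c < 256; ++c) lut[c] = x_idx;
  for (size_t k = 0; k < alphabet.size(); ++k)
    lut[(unsigned char)alphabet[k]] = (int)k;
}

struct SWResult { int score; int nmatch; int ncols; };

// score-only pass
static int sw_score(const std::vector<int>& a, const std::vector<int>& b,
                    const int* mat, int nalpha, int go, int ge) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> H(lb + 1, 0), F(lb + 1, NEG);
  int best = 0;
  for (int i = 1; i <= la; ++i) {
    const int* row = mat + (size_t)a[i - 1] * nalpha;
    int diag = H[0];
    int e = NEG;
    int hleft = 0;
    for (int j = 1; j <= lb; ++j) {
      int f = (std::max)(H[j] - go, F[j]) - ge;
      F[j] = f;
      e = (std::max)(hleft - go, e) - ge;
      int h = diag + row[b[j - 1]];
      if (h < 0) h = 0;
      if (h < e) h = e;
      if (h < f) h = f;
      diag = H[j];
      H[j] = h;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// counter-propagating pass
static SWResult sw_full(const std::vector<int>& a, const std::vector<int>& b,
                        const int* mat, int nalpha, int go, int ge) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> Hs(lb + 1, 0), Hm(lb + 1, 0), Hc(lb + 1, 0);
  std::vector<int> Fs(lb + 1, NEG), Fm(lb + 1, 0), Fc(lb + 1, 0);
  int best_s = 0, best_m = 0, best_c = 0;
  for (int i = 1; i <= la; ++i) {
    int diag_s = Hs[0], diag_m = Hm[0], diag_c = Hc[0];
    Hs[0] = 0; Hm[0] = 0; Hc[0] = 0;
    int Es = NEG, Em = 0, Ec = 0;
    const int* row = mat + (size_t)a[i - 1] * nalpha;
    for (int j = 1; j <= lb; ++j) {
      int f_open = Hs[j] - go - ge;
      if (f_open >= Fs[j]) { Fs[j] = f_open; Fm[j] = Hm[j]; Fc[j] = Hc[j] + 1; }
      else { Fs[j] -= ge; Fc[j] += 1; }
      int e_open = Hs[j - 1] - go - ge;
      if (e_open >= Es) { Es = e_open; Em = Hm[j - 1]; Ec = Hc[j - 1] + 1; }
      else { Es -= ge; Ec += 1; }
      int sub = row[b[j - 1]];
      int d_s = diag_s + sub;
      int match = (a[i - 1] == b[j - 1]) ? 1 : 0;
      int h_s, h_m, h_c;
      if (d_s >= Es && d_s >= Fs[j] && d_s > 0) {
        h_s = d_s; h_m = diag_m + match; h_c = diag_c + 1;
      } else if (Es >= Fs[j] && Es > 0) {
        h_s = Es; h_m = Em; h_c = Ec;
      } else if (Fs[j] > 0) {
        h_s = Fs[j]; h_m = Fm[j]; h_c = Fc[j];
      } else {
        h_s = 0; h_m = 0; h_c = 0;
      }
      diag_s = Hs[j]; diag_m = Hm[j]; diag_c = Hc[j];
      Hs[j] = h_s; Hm[j] = h_m; Hc[j] = h_c;
      if (h_s > best_s) { best_s = h_s; best_m = h_m; best_c = h_c; }
    }
  }
  SWResult r; r.score = best_s; r.nmatch = best_m; r.ncols = best_c;
  return r;
}

// [[Rcpp::export(name = ".sw_align_pair")]]
List sw_align_pair(std::string a, std::string b, IntegerMatrix mat,
                   std::string alphabet, int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("empty sequence");
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> ea = encode(a.c_str(), lut), eb = encode(b.c_str(), lut);
  SWResult r = sw_full(ea, eb, INTEGER(mat), mat.nrow(), gap_open,
                       gap_extend);
  double ident = r.ncols > 0 ? 100.0 * r.nmatch / r.ncols : 0.0;
  double cover = r.ncols > 0 ?
    (double)r.ncols / (std::min)(ea.size(), eb.size()) : 0.0;
  return List::create(_["score"] = r.score, _["identity"] = ident,
                      _["coverage"] = cover, _["nmatch"] = r.nmatch,
                      _["ncols"] = r.ncols);
}

// all-vs-all with full counters (brute-force route; O(n^2 L^2) with the
// heavier kernel — intended for small proteomes and cross-checks)
// [[Rcpp::export(name = ".sw_align_all")]]
List sw_align_all(CharacterVector qa, CharacterVector qb, IntegerMatrix mat,
                  std::string alphabet, int gap_open, int gap_extend) {
  int lut[256];
  build_lut(alphabet, lut);
  const int na = qa.size(), nb = qb.size();
  std::vector<std::vector<int> > ea(na), eb(nb);
  for (int i = 0; i < na; ++i) {
    if (CHAR(STRING_ELT(qa, i))[0] == '\0') stop("empty sequence in query");
    ea[i] = encode(CHAR(STRING_ELT(qa, i)), lut);
  }
  for (int j = 0; j < nb; ++j) {
    if (CHAR(STRING_ELT(qb, j))[0] == '\0') stop("empty sequence in subject");
    eb[j] = encode(CHAR(STRING_ELT(qb, j)), lut);
  }
  NumericMatrix score(na, nb), ident(na, nb), cover(na, nb);
  const int* m = INTEGER(mat);
  const int nalpha = mat.nrow();
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      SWResult r = sw_full(ea[i], eb[j], m, nalpha, gap_open, gap_extend);
      score(i, j) = r.score;
      if (r.ncols > 0 && r.score > 0) {
        ident(i, j) = 100.0 * r.nmatch / r.ncols;
        cover(i, j) = (double)r.ncols /
          (std::min)(ea[i].size(), eb[j].size());
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["identity"] = ident,
                      _["coverage"] = cover);
}

struct Hit { int q, s; double score, id, cov; };

// best passing hit per query given the score matrix; counters evaluated
// lazily in descending score order, cached across directions
static std::vector<Hit> direction_hits(
    bool forward, int nq, int ns,
    const std::vector<std::vector<int> >& ea,
    const std::vector<std::vector<int> >& eb,
    const std::vector<int>& S, int na,
    std::map<std::pair<int, int>, SWResult>& cache,
    const int* mat, int nalpha, int go, int ge,
    double min_id, double min_cov) {
  std::vector<Hit> out;
  for (int q = 0; q < nq; ++q) {
    std::vector<int> cand;
    cand.reserve(ns);
    for (int s = 0; s < ns; ++s) {
      int sc = forward ? S[q + (size_t)na * s] : S[s + (size_t)na * q];
      if (sc > 0) cand.push_back(s);
    }
    std::stable_sort(cand.begin(), cand.end(), [&](int x, int y) {
      int sx = forward ? S[q + (size_t)na * x] : S[x + (size_t)na * q];
      int sy = forward ? S[q + (size_t)na * y] : S[y + (size_t)na * q];
      if (sx != sy) return sx > sy;
      return x < y;
    });
    bool found = false;
    size_t k = 0;
    while (k < cand.size() && !found) {
      // evaluate the whole equal-score group, pick highest identity
      int sc0 = forward ? S[q + (size_t)na * cand[k]]
                        : S[cand[k] + (size_t)na * q];
      Hit best_hit; best_hit.id = -1;
      size_t k2 = k;
      for (; k2 < cand.size(); ++k2) {
        int s = cand[k2];
        int sc = forward ? S[q + (size_t)na * s] : S[s + (size_t)na * q];
        if (sc != sc0) break;
        int i = forward ? q : s, j = forward ? s : q;
        std::pair<int, int> key(i, j);
        std::map<std::pair<int, int>, SWResult>::iterator it =
          cache.find(key);
        SWResult r;
        if (it == cache.end()) {
          r = sw_full(ea[i], eb[j], mat, nalpha, go, ge);
          cache[key] = r;
        } else r = it->second;
        if (r.ncols <= 0 || r.score <= 0) continue;
        double id = 100.0 * r.nmatch / r.ncols;
        double cov = (double)r.ncols /
          (std::min)(ea[i].size(), eb[j].size());
        if (id / 100.0 >= min_id && cov >= min_cov && id > best_hit.id) {
          best_hit.q = q; best_hit.s = s; best_hit.score = sc0;
          best_hit.id = id; best_hit.cov = cov;
        }
      }
      if (best_hit.id >= 0) { out.push_back(best_hit); found = true; }
      k = k2;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sw_rbh")]]
List sw_rbh(CharacterVector qa, CharacterVector qb, IntegerMatrix mat,
            std::string alphabet, int gap_open, int gap_extend,
            double min_id, double min_cov) {
  int lut[256];
  build_lut(alphabet, lut);
  const int na = qa.size(), nb = qb.size();
  std::vector<std::vector<int> > ea(na), eb(nb);
  for (int i = 0; i < na; ++i) {
    if (CHAR(STRING_ELT(qa, i))[0] == '\0') stop("empty sequence in query");
    ea[i] = encode(CHAR(STRING_ELT(qa, i)), lut);
  }
  for (int j = 0; j < nb; ++j) {
    if (CHAR(STRING_ELT(qb, j))[0] == '\0') stop("empty sequence in subject");
    eb[j] = encode(CHAR(STRING_ELT(qb, j)), lut);
  }
  const int* m = INTEGER(mat);
  const int nalpha = mat.nrow();
  std::vector<int> S((size_t)na * nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j)
      S[i + (size_t)na * j] = sw_score(ea[i], eb[j], m, nalpha, gap_open,
                                       gap_extend);
    Rcpp::checkUserInterrupt();
  }
  std::map<std::pair<int, int>, SWResult> cache;
  std::vector<Hit> fwd = direction_hits(true, na, nb, ea, eb, S, na, cache,
                                        m, nalpha, gap_open, gap_extend,
                                        min_id, min_cov);
  std::vector<Hit> rev = direction_hits(false, nb, na, ea, eb, S, na, cache,
                                        m, nalpha, gap_open, gap_extend,
                                        min_id, min_cov);
  NumericMatrix score(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) score(i, j) = S[i + (size_t)na * j];
  IntegerVector fq(fwd.size()), fs(fwd.size());
  NumericVector fsc(fwd.size()), fid(fwd.size()), fcv(fwd.size());
  for (size_t k = 0; k < fwd.size(); ++k) {
    fq[k] = fwd[k].q + 1; fs[k] = fwd[k].s + 1;
    fsc[k] = fwd[k].score; fid[k] = fwd[k].id; fcv[k] = fwd[k].cov;
  }
  IntegerVector rq(rev.size()), rs(rev.size());
  NumericVector rsc(rev.size()), rid(rev.size()), rcv(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) {
    rq[k] = rev[k].q + 1; rs[k] = rev[k].s + 1;
    rsc[k] = rev[k].score; rid[k] = rev[k].id; rcv[k] = rev[k].cov;
  }
  return List::create(
    _["score"] = score,
    _["fwd"] = List::create(_["query"] = fq, _["subject"] = fs,
                            _["score"] = fsc, _["identity"] = fid,
                            _["coverage"] = fcv),
    _["rev"] = List::create(_["query"] = rq, _["subject"] = rs,
                            _["score"] = rsc, _["identity"] = rid,
                            _["coverage"] = rcv));
}
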