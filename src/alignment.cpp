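#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Exact word matches between query and subject (both forward orientation).
// Returns a two-column integer matrix of 0-based (qpos, spos).
// [[Rcpp::export]]
IntegerMatrix seed_hits_cpp(std::string query, std::string subject, int word) {
  const int qn = (int) query.size(), sn = (int) subject.size();
  std::vector<int> qp, sp;
  if (word < 1 || word > 15 || qn < word || sn < word) {
    IntegerMatrix out(0, 2);
    return out;
  }
  const long mask = (1L << (2 * word)) - 1;
  std::unordered_map<long, std::vector<int> > index;
  index.reserve(qn * 2);
  long code = 0; int valid = 0;
  for (int i = 0; i < qn; ++i) {
    int b = base_code(query[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= word) index[code].push_back(i - word + 1);
  }
  code = 0; valid = 0;
  for (int i = 0; i < sn; ++i) {
    int b = base_code(subject[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= word) {
      std::unordered_map<long, std::vector<int> >::iterator it = index.find(code);
      if (it != index.end()) {
        for (size_t k = 0; k < it->second.size(); ++k) {
          qp.push_back(it->second[k]);
          sp.push_back(i - word + 1);
        }
      }
    }
  }
  IntegerMatrix out((int) qp.size(), 2);
  for (size_t k = 0; k < qp.size(); ++k) {
    out(k, 0) = qp[k];
    out(k, 1) = sp[k];
  }
  return out;
}

// Ungapped X-drop extension of word seeds. Coordinates 0-based half-open.
// [[Rcpp::export]]
DataFrame ungapped_extend_cpp(std::string query, std::string subject,
                              IntegerVector qpos, IntegerVector spos, int word,
                              double match, double mismatch, double xdrop) {
  const int qn = (int) query.size(), sn = (int) subject.size();
  const int n = qpos.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), nmatch(n);
  NumericVector score(n);
  for (int k = 0; k < n; ++k) {
    const int q0 = qpos[k], s0 = spos[k];
    double best = word * match;  // the seed word matches exactly
    // extend right
    double cur = best; int i = word, best_r = word;
    while (q0 + i < qn && s0 + i < sn) {
      int a = base_code(query[q0 + i]), b = base_code(subject[s0 + i]);
      cur += (a >= 0 && a == b) ? match : mismatch;
      ++i;
      if (cur > best) { best = cur; best_r = i; }
      if (best - cur > xdrop) break;
    }
    // extend left
    cur = best; double best2 = best; int j = 1, best_l = 0;
    while (q0 - j >= 0 && s0 - j >= 0) {
      int a = base_code(query[q0 - j]), b = base_code(subject[s0 - j]);
      cur += (a >= 0 && a == b) ? match : mismatch;
      if (cur > best2) { best2 = cur; best_l = j; }
      if (best2 - cur > xdrop) break;
      ++j;
    }
    int nm = 0;
    for (int t = -best_l; t < best_r; ++t) {
      int a = base_code(query[q0 + t]), b = base_code(subject[s0 + t]);
      if (a >= 0 && a == b) ++nm;
    }
    qs[k] = q0 - best_l; qe[k] = q0 + best_r;
    ss[k] = s0 - best_l; se[k] = s0 + best_r;
    score[k] = best2; nmatch[k] = nm;
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se,
                           _["score"] = score, _["nmatch"] = nmatch);
}

// Affine-gap pairwise alignment, three-state DP with traceback.
// mode: 0 = global, 1 = semiglobal (terminal gaps free), 2 = local.
// A gap of length L costs gap_open + L * gap_extend.
// [[Rcpp::export]]
List affine_align_cpp(std::string a, std::string b, double match,
                      double mismatch, double gap_open, double gap_extend,
                      int mode) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const double NEG = -1e30;
  const double gofirst = gap_open + gap_extend;
  const size_t W = (size_t) (m + 1);
  std::vector<float> M((n + 1) * W, (float) NEG), X((n + 1) * W, (float) NEG),
                     Y((n + 1) * W, (float) NEG);
  // predecessor state per (cell, state): 0=M, 1=X, 2=Y, 3=fresh start (local)
  std::vector<unsigned char> tM((n + 1) * W), tX((n + 1) * W), tY((n + 1) * W);
  const bool global = (mode == 0), semi = (mode == 1), local = (mode == 2);

  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    size_t c = i * W;
    if (local) { M[c] = 0; tM[c] = 3; }
    else { X[c] = global ? (float) (-(gap_open + i * gap_extend)) : 0.0f; tX[c] = 1; }
  }
  for (int j = 1; j <= m; ++j) {
    if (local) { M[j] = 0; tM[j] = 3; }
    else { Y[j] = global ? (float) (-(gap_open + j * gap_extend)) : 0.0f; tY[j] = 2; }
  }

  double best_loc = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ca = base_code(a[i - 1]);
    const size_t r = i * W, rp = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const int cb = base_code(b[j - 1]);
      const double s = (ca >= 0 && ca == cb) ? match : mismatch;
      // M state
      double pv; unsigned char pc;
      double vM = M[rp + j - 1], vX = X[rp + j - 1], vY = Y[rp + j - 1];
      if (vM >= vX && vM >= vY) { pv = vM; pc = 0; }
      else if (vX >= vY) { pv = vX; pc = 1; }
      else { pv = vY; pc = 2; }
      if (local && pv <= 0) { pv = 0; pc = 3; }
      double mv = pv + s;
      if (local && mv < 0) { mv = 0; pc = 3; }
      M[r + j] = (float) mv; tM[r + j] = pc;
      // X state: gap in b, consumes a[i-1]
      double x1 = M[rp + j] - gofirst, x2 = X[rp + j] - gap_extend,
             x3 = Y[rp + j] - gofirst;
      if (x1 >= x2 && x1 >= x3) { X[r + j] = (float) x1; tX[r + j] = 0; }
      else if (x2 >= x3) { X[r + j] = (float) x2; tX[r + j] = 1; }
      else { X[r + j] = (float) x3; tX[r + j] = 2; }
      // Y state: gap in a, consumes b[j-1]
      double y1 = M[r + j - 1] - gofirst, y2 = Y[r + j - 1] - gap_extend,
             y3 = X[r + j - 1] - gofirst;
      if (y1 >= y2 && y1 >= y3) { Y[r + j] = (float) y1; tY[r + j] = 0; }
      else if (y2 >= y3) { Y[r + j] = (float) y2; tY[r + j] = 2; }
      else { Y[r + j] = (float) y3; tY[r + j] = 1; }
      if (local && mv > best_loc) { best_loc = mv; bi = i; bj = j; }
    }
  }

  // end cell and state
  int ei = n, ej = m, estate = 0;
  double best;
  if (local) {
    ei = bi; ej = bj; best = best_loc; estate = 0;
    if (best <= 0)
      return List::create(_["score"] = 0.0, _["a_aligned"] = "",
                          _["b_aligned"] = "", _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
  } else if (global) {
    best = M[n * W + m]; estate = 0;
    if (X[n * W + m] > best) { best = X[n * W + m]; estate = 1; }
    if (Y[n * W + m] > best) { best = Y[n * W + m]; estate = 2; }
  } else {
    best = NEG;
    for (int j = 0; j <= m; ++j) {
      size_t c = (size_t) n * W + j;
      double v = std::max((double) M[c], std::max((double) X[c], (double) Y[c]));
      if (v > best) { best = v; ei = n; ej = j; }
    }
    for (int i2 = 0; i2 <= n; ++i2) {
      size_t c = (size_t) i2 * W + m;
      double v = std::max((double) M[c], std::max((double) X[c], (double) Y[c]));
      if (v > best) { best = v; ei = i2; ej = m; }
    }
    size_t c = (size_t) ei * W + ej;
    if ((double) M[c] >= best) estate = 0;
    else if ((double) X[c] >= best) estate = 1;
    else estate = 2;
  }

  // traceback (built backwards, reversed at the end)
  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  if (semi) { // trailing free gaps: only one of these loops can run
    for (int t = n; t > ei; --t) { aa.push_back(a[t - 1]); bb.push_back('-'); }
    for (int t = m; t > ej; --t) { aa.push_back('-'); bb.push_back(b[t - 1]); }
  }
  int i = ei, j = ej, st = estate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      unsigned char pt = tM[(size_t) i * W + j];
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      --i; --j;
      if (pt == 3) break; // local alignment start
      st = pt;
    } else if (st == 1) {
      unsigned char pt = tX[(size_t) i * W + j];
      aa.push_back(a[i - 1]); bb.push_back('-');
      --i; st = pt;
    } else {
      unsigned char pt = tY[(size_t) i * W + j];
      aa.push_back('-'); bb.push_back(b[j - 1]);
      --j; st = pt;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = best,
                      _["a_aligned"] = aa, _["b_aligned"] = bb,
                      _["a_start"] = local ? i : 0, _["a_end"] = local ? ei : n,
                      _["b_start"] = local ? j : 0, _["b_end"] = local ? ej : m);
}

// Best ungapped terminal inverted repeat between a 5' window and the
// reverse complement of the 3' window. Maximizes match count subject to
// length in [min_len, max_len] and identity >= min_identity.
// [[Rcpp::export]]
List best_inverted_repeat_cpp(std::string prefix, std::string rc_suffix,
                              int min_len, int max_len, double min_identity) {
  const int pn = (int) prefix.size(), sn = (int) rc_suffix.size();
  int best_s = INT_MIN, best_m = -1, best_i = -1, best_j = -1, best_L = -1;
  for (int i = 0; i + min_len <= pn; ++i) {
    for (int j = 0; j + min_len <= sn; ++j) {
      int lim = std::min(max_len, std::min(pn - i, sn - j));
      int matches = 0;
      for (int L = 1; L <= lim; ++L) {
        int a = base_code(prefix[i + L - 1]), b = base_code(rc_suffix[j + L - 1]);
        if (a >= 0 && a == b) ++matches;
        int sc = 2 * matches - L; // matches minus mismatches
        if (L >= min_len && matches >= min_identity * L - 1e-9) {
          bool better = sc > best_s ||
            (sc == best_s && (L > best_L ||
             (L == best_L && (i < best_i || (i == best_i && j < best_j)))));
          if (better) { best_s = sc; best_m = matches; best_i = i;
                        best_j = j; best_L = L; }
        }
      }
    }
  }
  if (best_m < 0)
    return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["i"] = best_i, _["j"] = best_j,
                      _["length"] = best_L, _["matches"] = best_m,
                      _["mismatches"] = best_L - best_m,
                      _["identity"] = (double) best_m / best_L);
}
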