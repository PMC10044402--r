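// Affine-gap alignment kernels used by the search, genemodel and clustering
// modules. Substitution matrices are passed in from R (Biostrings' BLOSUM62);
// gap costs follow the gapOpening/gapExtension convention where a gap of
// length g costs open + g * ext.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// 256-slot lookup from the sub matrix dimnames; unknown residues map to 'X'
// (or to the last row if no 'X' present).
struct SubLookup {
  int idx[256];
  std::vector<double> s;
  int n;
  SubLookup(const NumericMatrix& sub) {
    List dn = sub.attr("dimnames");
    CharacterVector rn = dn[0];
    n = sub.nrow();
    int xi = n - 1;
    for (int i = 0; i < n; ++i) {
      if (as<std::string>(rn[i]) == "X") xi = i;
    }
    for (int i = 0; i < 256; ++i) idx[i] = xi;
    for (int i = 0; i < n; ++i) {
      std::string nm = as<std::string>(rn[i]);
      if (nm.size() == 1) idx[(unsigned char)nm[0]] = i;
    }
    s.resize(n * n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) s[i * n + j] = sub(i, j);
  }
  inline double score(char a, char b) const {
    return s[idx[(unsigned char)a] * n + idx[(unsigned char)b]];
  }
};

// Global Needleman-Wunsch-Gotoh; returns score plus match/column counts from
// the traceback (ties resolved diagonal > up > left).
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, NumericMatrix sub,
                      double gap_open, double gap_ext) {
  SubLookup S(sub);
  int m = a.size(), n = b.size();
  double go = gap_open + gap_ext;
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF); // gap in a (move in b)
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF); // gap in b (move in a)
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= n; ++j) X[at(0, j)] = -gap_open - gap_ext * j;
  for (int i = 1; i <= m; ++i) Y[at(i, 0)] = -gap_open - gap_ext * i;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double prev = std::max(M[at(i - 1, j - 1)],
                    std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = prev + S.score(a[i - 1], b[j - 1]);
      X[at(i, j)] = std::max(std::max(M[at(i, j - 1)] - go,
                                      Y[at(i, j - 1)] - go),
                             X[at(i, j - 1)] - gap_ext);
      Y[at(i, j)] = std::max(std::max(M[at(i - 1, j)] - go,
                                      X[at(i - 1, j)] - go),
                             Y[at(i - 1, j)] - gap_ext);
    }
  }
  double best = std::max(M[at(m, n)], std::max(X[at(m, n)], Y[at(m, n)]));
  // traceback counting matches and alignment columns
  int i = m, j = n, matches = 0, columns = 0;
  int state; // 0 = M, 1 = X, 2 = Y
  if (best == M[at(m, n)]) state = 0;
  else if (best == Y[at(m, n)]) state = 2;
  else state = 1;
  while (i > 0 || j > 0) {
    if (i == 0) { state = 1; }
    if (j == 0) { state = 2; }
    ++columns;
    if (state == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      double prev = M[at(i, j)] - S.score(a[i - 1], b[j - 1]);
      --i; --j;
      if (std::abs(prev - M[at(i, j)]) < 1e-9) state = 0;
      else if (std::abs(prev - Y[at(i, j)]) < 1e-9) state = 2;
      else state = 1;
    } else if (state == 1) {
      double cur = X[at(i, j)];
      --j;
      if (std::abs(cur - (X[at(i, j)] - gap_ext)) < 1e-9) state = 1;
      else if (std::abs(cur - (M[at(i, j)] - go)) < 1e-9) state = 0;
      else state = 2;
    } else {
      double cur = Y[at(i, j)];
      --i;
      if (std::abs(cur - (Y[at(i, j)] - gap_ext)) < 1e-9) state = 2;
      else if (std::abs(cur - (M[at(i, j)] - go)) < 1e-9) state = 0;
      else state = 1;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns,
                      _["identity"] = columns > 0 ? (double)matches / columns : 0.0);
}

// Local Smith-Waterman-Gotoh with traceback over a (sub)sequence pair.
static List local_align_core(const std::string& a, const std::string& b,
                             const SubLookup& S, double gap_open,
                             double gap_ext) {
  int m = a.size(), n = b.size();
  double go = gap_open + gap_ext;
  std::vector<double> M((m + 1) * (n + 1), 0.0);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double prev = std::max(std::max(M[at(i - 1, j - 1)],
                                      X[at(i - 1, j - 1)]),
                             Y[at(i - 1, j - 1)]);
      double mm = prev + S.score(a[i - 1], b[j - 1]);
      M[at(i, j)] = std::max(0.0, mm);
      X[at(i, j)] = std::max(std::max(M[at(i, j - 1)] - go,
                                      Y[at(i, j - 1)] - go),
                             X[at(i, j - 1)] - gap_ext);
      Y[at(i, j)] = std::max(std::max(M[at(i - 1, j)] - go,
                                      X[at(i - 1, j)] - go),
                             Y[at(i - 1, j)] - gap_ext);
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0);
  // traceback from (bi, bj) until score 0 in M
  int i = bi, j = bj, state = 0, matches = 0, columns = 0;
  int ei = bi, ej = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (M[at(i, j)] <= 0.0) break;
      ++columns;
      if (a[i - 1] == b[j - 1]) ++matches;
      double prev = M[at(i, j)] - S.score(a[i - 1], b[j - 1]);
      --i; --j;
      if (std::abs(prev) < 1e-9 && M[at(i, j)] <= 1e-9) break;
      if (std::abs(prev - M[at(i, j)]) < 1e-9) state = 0;
      else if (std::abs(prev - X[at(i, j)]) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columns;
      double cur = X[at(i, j)];
      --j;
      if (std::abs(cur - (X[at(i, j)] - gap_ext)) < 1e-9) state = 1;
      else if (std::abs(cur - (M[at(i, j)] - go)) < 1e-9) state = 0;
      else state = 2;
    } else {
      ++columns;
      double cur = Y[at(i, j)];
      --i;
      if (std::abs(cur - (Y[at(i, j)] - gap_ext)) < 1e-9) state = 2;
      else if (std::abs(cur - (M[at(i, j)] - go)) < 1e-9) state = 0;
      else state = 1;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = i + 1,
                      _["a_end"] = ei, _["b_start"] = j + 1, _["b_end"] = ej,
                      _["matches"] = matches, _["columns"] = columns);
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, NumericMatrix sub,
                     double gap_open, double gap_ext) {
  SubLookup S(sub);
  return local_align_core(a, b, S, gap_open, gap_ext);
}

// Seed-and-extend search of one query protein against one translated frame.
// Exact k-mer seeds; a diagonal band region is triggered by two seeds on
// nearby diagonals (two-hit rule); each triggered region is resolved by a
// full Smith-Waterman on the query vs a subject window. Returns a matrix of
// HSPs: q_start q_end s_start s_end score matches columns.
// [[Rcpp::export]]
NumericMatrix cpp_seeded_search(std::string query, std::string subject,
                                NumericMatrix sub, int k, int two_hit_window,
                                double gap_open, double gap_ext,
                                double min_score) {
  SubLookup S(sub);
  int m = query.size(), n = subject.size();
  NumericMatrix empty(0, 7);
  if (m < k || n < k) return empty;
  // index query k-mers (encode over raw bytes)
  std::unordered_map<uint64_t, std::vector<int>> kmers;
  auto encode = [&](const std::string& s, int pos) {
    uint64_t h = 0;
    for (int t = 0; t < k; ++t) h = h * 131 + (unsigned char)s[pos + t];
    return h;
  };
  for (int q = 0; q + k <= m; ++q) kmers[encode(query, q)].push_back(q);
  // collect seed hits as (diagonal, subject_pos)
  std::vector<std::pair<int, int>> hits;
  for (int sp = 0; sp + k <= n; ++sp) {
    auto it = kmers.find(encode(subject, sp));
    if (it == kmers.end()) continue;
    for (int qp : it->second) hits.push_back({sp - qp, sp});
  }
  if (hits.empty()) return empty;
  std::sort(hits.begin(), hits.end());
  // two-hit trigger (BLAST-style): two non-overlapping seeds on the same
  // diagonal within the trigger window
  std::vector<std::pair<int, int>> trig; // (diag, spos) of triggered pairs
  for (size_t t = 1; t < hits.size(); ++t) {
    for (size_t s = t; s-- > 0;) {
      if (hits[s].first != hits[t].first) break;
      int gap = hits[t].second - hits[s].second;
      if (gap > two_hit_window) break;
      if (gap >= k) {
        trig.push_back(hits[s]);
        trig.push_back(hits[t]);
        break;
      }
    }
  }
  if (trig.empty()) return empty;
  // group triggered seeds into extension regions: nearby diagonals and
  // subject positions within ~query length of each other
  struct Region { int dmin, dmax, smin, smax, count; };
  std::vector<Region> regions;
  const int diag_slack = 16;
  const int prox = std::max(m, two_hit_window);
  for (auto& h : trig) {
    bool placed = false;
    for (auto& r : regions) {
      if (h.first >= r.dmin - diag_slack && h.first <= r.dmax + diag_slack &&
          h.second >= r.smin - prox && h.second <= r.smax + prox) {
        r.dmin = std::min(r.dmin, h.first);
        r.dmax = std::max(r.dmax, h.first);
        r.smin = std::min(r.smin, h.second);
        r.smax = std::max(r.smax, h.second);
        ++r.count;
        placed = true;
        break;
      }
    }
    if (!placed) regions.push_back({h.first, h.first, h.second, h.second, 1});
  }
  std::vector<std::array<double, 7>> out;
  for (auto& r : regions) {
    int w0 = std::max(0, r.smin - (r.dmax - r.dmin) - m - 16);
    int w1 = std::min(n, r.smax + m + k + 16);
    std::string win = subject.substr(w0, w1 - w0);
    List al = local_align_core(query, win, S, gap_open, gap_ext);
    double sc = al["score"];
    if (sc < min_score) continue;
    out.push_back({(double)(int)al["a_start"], (double)(int)al["a_end"],
                   (double)((int)al["b_start"] + w0),
                   (double)((int)al["b_end"] + w0), sc,
                   (double)(int)al["matches"], (double)(int)al["columns"]});
  }
  // deduplicate identical subject intervals (regions can converge)
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  NumericMatrix res(out.size(), 7);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < 7; ++j) res(i, j) = out[i][j];
  colnames(res) = CharacterVector::create("q_start", "q_end", "s_start",
                                          "s_end", "score", "matches",
                                          "columns");
  return res;
}

// Frameshift-aware local alignment of a protein against DNA (codon space).
// aa_by_end[j-1] must hold the translation of the codon ENDING at 1-based
// dna position j (or a sentinel for j < 3). Codons normally consume 3 bp;
// 2-bp or 4-bp steps model frameshifts at fs_cost. Stop codons align to any
// residue at stop_score so the path can run through a pseudogene lesion.
// Returns the best path with its frameshift events (codon start, step size).
// [[Rcpp::export]]
List cpp_fs_align(std::string prot, std::string aa_by_end, double fs_cost,
                  double stop_score, NumericMatrix sub, double gap_open,
                  double gap_ext) {
  SubLookup S(sub);
  int m = prot.size(), n = aa_by_end.size();
  double go = gap_open + gap_ext;
  auto sc = [&](int i, int j) { // prot residue i (1-based), codon ending j
    char aa = aa_by_end[j - 1];
    if (aa == '*') return stop_score;
    if (aa == '?') return NEG_INF; // incomplete codon
    return S.score(prot[i - 1], aa);
  };
  std::vector<double> M((size_t)(m + 1) * (n + 1), 0.0);
  std::vector<double> Y((size_t)(m + 1) * (n + 1), NEG_INF); // gap in dna
  std::vector<double> X((size_t)(m + 1) * (n + 1), NEG_INF); // gap in prot
  std::vector<int8_t> tbM((size_t)(m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sc(i, j);
      double v = 0.0; int8_t tb = 0; // 0 = fresh start
      if (s > NEG_INF / 2) {
        if (j >= 3) {
          double p = std::max(std::max(M[at(i - 1, j - 3)], X[at(i - 1, j - 3)]),
                              Y[at(i - 1, j - 3)]) + s;
          if (p > v) { v = p; tb = 3; }
          if (s > v) { v = s; tb = 0; } // allow starting a path here
        }
        if (j >= 2) {
          double p = std::max(std::max(M[at(i - 1, j - 2)], X[at(i - 1, j - 2)]),
                              Y[at(i - 1, j - 2)]) + s - fs_cost;
          if (p > v) { v = p; tb = 2; }
        }
        if (j >= 4) {
          double p = std::max(std::max(M[at(i - 1, j - 4)], X[at(i - 1, j - 4)]),
                              Y[at(i - 1, j - 4)]) + s - fs_cost;
          if (p > v) { v = p; tb = 4; }
        }
      }
      M[at(i, j)] = v; tbM[at(i, j)] = tb;
      if (j >= 3)
        X[at(i, j)] = std::max(std::max(M[at(i, j - 3)] - go,
                                        Y[at(i, j - 3)] - go),
                               X[at(i, j - 3)] - gap_ext);
      Y[at(i, j)] = std::max(std::max(M[at(i - 1, j)] - go,
                                      X[at(i - 1, j)] - go),
                             Y[at(i - 1, j)] - gap_ext);
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return List::create(_["score"] = 0.0);
  // traceback through M/X/Y; record frameshift steps
  int i = bi, j = bj, state = 0;
  std::vector<int> fs_start, fs_step;
  int d_start = bj, p_start = bi;
  while (i > 0 && j > 0) {
    if (state == 0) {
      int8_t tb = tbM[at(i, j)];
      d_start = j - (tb == 0 ? 3 : (int)tb) + 1;
      if (d_start < 1) d_start = 1;
      p_start = i;
      if (tb == 2 || tb == 4) { fs_start.push_back(j - tb + 1); fs_step.push_back(tb); }
      if (tb == 0) break;
      int pi = i - 1, pj = j - tb;
      double prev = M[at(i, j)] - sc(i, j) + (tb != 3 ? fs_cost : 0.0);
      i = pi; j = pj;
      if (std::abs(prev - M[at(i, j)]) < 1e-9) state = 0;
      else if (std::abs(prev - X[at(i, j)]) < 1e-9) state = 1;
      else if (std::abs(prev - Y[at(i, j)]) < 1e-9) state = 2;
      else state = 0;
      if (state == 0 && M[at(i, j)] <= 1e-9 && std::abs(prev) < 1e-9) break;
    } else if (state == 1) {
      double cur = X[at(i, j)];
      j -= 3;
      if (std::abs(cur - (X[at(i, j)] - gap_ext)) < 1e-9) state = 1;
      else if (std::abs(cur - (M[at(i, j)] - go)) < 1e-9) state = 0;
      else state = 2;
    } else {
      double cur = Y[at(i, j)];
      i -= 1;
      if (std::abs(cur - (Y[at(i, j)] - gap_ext)) < 1e-9) state = 2;
      else if (std::abs(cur - (M[at(i, j)] - go)) < 1e-9) state = 0;
      else state = 1;
    }
  }
  std::reverse(fs_start.begin(), fs_start.end());
  std::reverse(fs_step.begin(), fs_step.end());
  return List::create(_["score"] = best, _["p_start"] = p_start,
                      _["p_end"] = bi, _["d_start"] = d_start,
                      _["d_end"] = bj,
                      _["fs_start"] = IntegerVector(fs_start.begin(), fs_start.end()),
                      _["fs_step"] = IntegerVector(fs_step.begin(), fs_step.end()));
}
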