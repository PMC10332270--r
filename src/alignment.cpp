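// Affine-gap pairwise alignment with traceback: Smith-Waterman local mode
// (blastn-style scoring) and ends-free global ("overlap") mode used for
// clustering identity and chimera match profiles. A gap of length k costs
// open + k * extend, matching BLAST's convention. In overlap mode terminal
// gap runs are free and excluded from the alignment statistics.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

namespace {

const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int qstart, qend, sstart, send;  // 1-based, 0 when empty
  int matches, mismatches, gapopens, alen;
  std::vector<int> profile;  // per-query-position: 1 match, 0 otherwise
};

enum { ST_M = 0, ST_IX = 1, ST_IY = 2, ST_START = 3 };

// one traceback column: state plus the (i, j) cell it was computed in
struct Col { unsigned char state; int i, j; };

AlnResult align_core(const std::string& q, const std::string& s,
                     double reward, double penalty,
                     double gap_open, double gap_ext, bool local) {
  const int m = q.size(), n = s.size();
  const double open_cost = gap_open + gap_ext;
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> IX((m + 1) * (n + 1), NEG_INF);
  std::vector<double> IY((m + 1) * (n + 1), NEG_INF);
  std::vector<unsigned char> tbM((m + 1) * (n + 1), ST_START);
  std::vector<unsigned char> tbX((m + 1) * (n + 1), ST_M);
  std::vector<unsigned char> tbY((m + 1) * (n + 1), ST_M);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  // free start boundary in both modes
  for (int i = 0; i <= m; ++i) M[at(i, 0)] = 0.0;
  for (int j = 0; j <= n; ++j) M[at(0, j)] = 0.0;

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0, bstate = ST_M;
  bool found = false;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double xo = M[at(i - 1, j)] - open_cost;
      double xe = IX[at(i - 1, j)] - gap_ext;
      if (xo >= xe) { IX[at(i, j)] = xo; tbX[at(i, j)] = ST_M; }
      else          { IX[at(i, j)] = xe; tbX[at(i, j)] = ST_IX; }
      double yo = M[at(i, j - 1)] - open_cost;
      double ye = IY[at(i, j - 1)] - gap_ext;
      if (yo >= ye) { IY[at(i, j)] = yo; tbY[at(i, j)] = ST_M; }
      else          { IY[at(i, j)] = ye; tbY[at(i, j)] = ST_IY; }
      double sub = (q[i - 1] == s[j - 1]) ? reward : penalty;
      double pm = M[at(i - 1, j - 1)];
      double px = IX[at(i - 1, j - 1)];
      double py = IY[at(i - 1, j - 1)];
      double bestp = pm; unsigned char st = ST_M;
      if (px > bestp) { bestp = px; st = ST_IX; }
      if (py > bestp) { bestp = py; st = ST_IY; }
      if (local && 0.0 > bestp) { bestp = 0.0; st = ST_START; }
      M[at(i, j)] = bestp + sub;
      tbM[at(i, j)] = st;
      if (local && M[at(i, j)] > best) {
        best = M[at(i, j)]; bi = i; bj = j; bstate = ST_M; found = true;
      }
    }
  }
  if (!local) {
    // ends-free: best over last row and last column, any state
    for (int i = 1; i <= m; ++i) {
      double v[3] = { M[at(i, n)], IX[at(i, n)], IY[at(i, n)] };
      for (int st = 0; st < 3; ++st) {
        if (v[st] > best) { best = v[st]; bi = i; bj = n; bstate = st; }
      }
    }
    for (int j = 1; j <= n; ++j) {
      double v[3] = { M[at(m, j)], IX[at(m, j)], IY[at(m, j)] };
      for (int st = 0; st < 3; ++st) {
        if (v[st] > best) { best = v[st]; bi = m; bj = j; bstate = st; }
      }
    }
    found = (m > 0 && n > 0 && best > NEG_INF / 2);
  }

  AlnResult res;
  res.profile.assign(m, 0);
  res.score = found ? best : 0.0;
  res.qstart = res.qend = res.sstart = res.send = 0;
  res.matches = res.mismatches = res.gapopens = res.alen = 0;
  if (!found || (local && best <= 0.0)) return res;

  // traceback, collecting columns in reverse order
  std::vector<Col> cols;
  int i = bi, j = bj, state = bstate;
  while (i > 0 && j > 0) {
    Col c; c.state = state; c.i = i; c.j = j;
    cols.push_back(c);
    if (state == ST_M) {
      unsigned char st = tbM[at(i, j)];
      i--; j--;
      if (st == ST_START) break;
      state = st;
    } else if (state == ST_IX) {
      unsigned char st = tbX[at(i, j)];
      i--;
      state = st;
    } else {
      unsigned char st = tbY[at(i, j)];
      j--;
      state = st;
    }
  }
  // trim terminal gap runs (free under ends-free semantics); cols is in
  // reverse order: front = alignment end, back = alignment start
  int lo = 0, hi = (int)cols.size() - 1;
  while (lo <= hi && cols[lo].state != ST_M) ++lo;
  while (hi >= lo && cols[hi].state != ST_M) --hi;
  if (lo > hi) return res;  // gap-only path
  res.qend = cols[lo].i; res.send = cols[lo].j;
  res.qstart = cols[hi].i; res.sstart = cols[hi].j;
  int prev = -1;
  for (int k = hi; k >= lo; --k) {  // walk alignment left to right
    const Col& c = cols[k];
    res.alen++;
    if (c.state == ST_M) {
      if (q[c.i - 1] == s[c.j - 1]) {
        res.matches++;
        res.profile[c.i - 1] = 1;
      } else {
        res.mismatches++;
      }
    } else if (c.state != prev) {
      res.gapopens++;
    }
    prev = c.state;
  }
  return res;
}

List result_to_list(const AlnResult& r, bool with_profile) {
  List out = List::create(
    _["score"] = r.score, _["qstart"] = r.qstart, _["qend"] = r.qend,
    _["sstart"] = r.sstart, _["send"] = r.send, _["matches"] = r.matches,
    _["mismatches"] = r.mismatches, _["gapopens"] = r.gapopens,
    _["alen"] = r.alen);
  if (with_profile) {
    LogicalVector prof(r.profile.size());
    for (size_t k = 0; k < r.profile.size(); ++k) prof[k] = r.profile[k] == 1;
    out["profile"] = prof;
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(std::string query, std::string subject, double reward,
                    double penalty, double gap_open, double gap_ext,
                    bool local, bool with_profile = false) {
  AlnResult r = align_core(query, subject, reward, penalty, gap_open,
                           gap_ext, local);
  return result_to_list(r, with_profile);
}

// Raw local/overlap scores of one query against each sequence in `set`.
// [[Rcpp::export(name = ".cpp_score_to_set")]]
NumericVector cpp_score_to_set(std::string query,
                               std::vector<std::string> set,
                               double reward, double penalty,
                               double gap_open, double gap_ext, bool local) {
  NumericVector out(set.size());
  for (size_t k = 0; k < set.size(); ++k) {
    AlnResult r = align_core(query, set[k], reward, penalty, gap_open,
                             gap_ext, local);
    out[k] = r.score;
  }
  return out;
}

// Clustering identity of one query against each sequence in `set`:
// ends-free global alignment (terminal gaps free in score), identity =
// matching columns / full alignment span, where unaligned terminal tails of
// either sequence count as gap columns. This keeps accidental short
// dovetail overlaps between unrelated sequences from scoring as identity 1.
// [[Rcpp::export(name = ".cpp_identity_to_set")]]
NumericVector cpp_identity_to_set(std::string query,
                                  std::vector<std::string> set,
                                  double reward, double penalty,
                                  double gap_open, double gap_ext) {
  const int m = query.size();
  NumericVector out(set.size());
  for (size_t k = 0; k < set.size(); ++k) {
    const int n = set[k].size();
    AlnResult r = align_core(query, set[k], reward, penalty, gap_open,
                             gap_ext, false);
    if (r.alen == 0) { out[k] = 0.0; continue; }
    int span = r.alen + (r.qstart - 1) + (r.sstart - 1) +
      (m - r.qend) + (n - r.send);
    out[k] = span > 0 ? double(r.matches) / double(span) : 0.0;
  }
  return out;
}

// Per-candidate-position match profiles of `candidate` against each parent
// (ends-free global alignment). Returns a logical matrix, parents in rows.
// [[Rcpp::export(name = ".cpp_match_profiles")]]
LogicalMatrix cpp_match_profiles(std::string candidate,
                                 std::vector<std::string> parents,
                                 double reward, double penalty,
                                 double gap_open, double gap_ext) {
  const int L = candidate.size();
  LogicalMatrix out(parents.size(), L);
  for (size_t k = 0; k < parents.size(); ++k) {
    AlnResult r = align_core(candidate, parents[k], reward, penalty,
                             gap_open, gap_ext, false);
    for (int i = 0; i < L; ++i) out(k, i) = r.profile[i] == 1;
  }
  return out;
}
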