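#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) over integer-encoded protein
// sequences. Gap of length L costs gap_open + L * gap_extend (both negative),
// matching the BLAST -11/-1 convention. Masked subject positions are
// unalignable; masking supports iterative extraction of multiple HSPs.

struct AlnHit {
  double score;
  int qstart, qend, sstart, send; // 0-based half-open
  int nident, length;
};

static bool sw_best(const std::vector<int> &q, const std::vector<int> &s,
                    const std::vector<double> &sub, int nsub, double go,
                    double ge, const std::vector<char> &masked, AlnHit &hit) {
  const int m = (int)q.size(), n = (int)s.size();
  const double NEG = -1e30;
  std::vector<double> Hp(n + 1, 0.0), Hc(n + 1, 0.0); // rolling H rows
  std::vector<double> Ec(n + 1, NEG);                 // E within current row
  std::vector<double> Fc(n + 1, NEG);                 // F carried down columns
  // traceback: tbH 0 stop,1 diag,2 from E,3 from F; tbE/tbF 0 open,1 extend
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * (n + 1);
    const double *qrow = &sub[(size_t)q[i - 1] * nsub];
    double eprev = NEG;
    Hc[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double sc = masked[j - 1] ? NEG : qrow[s[j - 1]];
      double eopen = Hc[j - 1] + go + ge, eext = eprev + ge;
      double e = std::max(eopen, eext);
      tbE[row + j] = (eext > eopen) ? 1 : 0;
      double fopen = Hp[j] + go + ge, fext = Fc[j] + ge;
      double f = std::max(fopen, fext);
      tbF[row + j] = (fext > fopen) ? 1 : 0;
      double diag = Hp[j - 1] + sc;
      double h = 0.0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      Hc[j] = h; eprev = e; Fc[j] = f; tbH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
  }
  if (bi < 0 || best <= 0.0) return false;
  int i = bi, j = bj, nid = 0, len = 0, state = 0; // 0=H,1=E,2=F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      uint8_t t = tbH[idx];
      if (t == 0) break;
      if (t == 1) { if (q[i - 1] == s[j - 1]) ++nid; ++len; --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t t = tbE[idx]; ++len; --j; if (t == 0) state = 0;
    } else {
      uint8_t t = tbF[idx]; ++len; --i; if (t == 0) state = 0;
    }
  }
  hit.score = best; hit.qstart = i; hit.qend = bi;
  hit.sstart = j; hit.send = bj; hit.nident = nid; hit.length = len;
  return true;
}

static void collect_hsps(const std::vector<int> &q, const std::vector<int> &s,
                         int s_offset, const std::vector<double> &sub,
                         int nsub, double go, double ge, double min_score,
                         int max_hsps, std::vector<AlnHit> &out) {
  std::vector<char> masked(s.size(), 0);
  for (int iter = 0; iter < max_hsps; ++iter) {
    AlnHit hit;
    if (!sw_best(q, s, sub, nsub, go, ge, masked, hit)) break;
    if (hit.score < min_score) break;
    if (hit.send - hit.sstart <= 0) break;
    for (int j = hit.sstart; j < hit.send; ++j) masked[j] = 1;
    hit.sstart += s_offset; hit.send += s_offset;
    out.push_back(hit);
  }
}

// [[Rcpp::export(name = ".cpp_sw_hsps")]]
DataFrame cpp_sw_hsps(IntegerVector q, IntegerVector s, NumericMatrix sub,
                      double gap_open, double gap_extend, double min_score,
                      int max_hsps, double exhaustive_limit, int seed_k,
                      int window_gap, int window_margin) {
  std::vector<int> qv(q.begin(), q.end()), sv(s.begin(), s.end());
  const int nsub = sub.nrow();
  std::vector<double> subf((size_t)nsub * nsub);
  for (int a = 0; a < nsub; ++a)
    for (int b = 0; b < nsub; ++b) subf[(size_t)a * nsub + b] = sub(a, b);
  std::vector<AlnHit> hits;
  const int m = (int)qv.size(), n = (int)sv.size();
  if (m > 0 && n > 0) {
    if ((double)m * (double)n <= exhaustive_limit || m < seed_k) {
      collect_hsps(qv, sv, 0, subf, nsub, gap_open, gap_extend, min_score, max_hsps, hits);
    } else {
      // exact k-mer seeding over a 24-letter alphabet, confirmed by a
      // second hit on the same diagonal within 40 aa (BLAST-style two-hit)
      const long long B = 24;
      std::unordered_map<long long, std::vector<int>> qk;
      long long code = 0, hi = 1;
      for (int t = 0; t < seed_k - 1; ++t) hi *= B;
      for (int i = 0; i < m; ++i) {
        if (i >= seed_k) code -= (long long)qv[i - seed_k] * hi;
        code = code * B + qv[i];
        if (i >= seed_k - 1) qk[code].push_back(i - seed_k + 1);
      }
      std::unordered_map<int, std::vector<int>> by_diag; // diag -> subject pos
      code = 0;
      for (int j = 0; j < n; ++j) {
        if (j >= seed_k) code -= (long long)sv[j - seed_k] * hi;
        code = code * B + sv[j];
        if (j >= seed_k - 1) {
          auto it = qk.find(code);
          if (it != qk.end()) {
            int sj = j - seed_k + 1;
            for (int qp : it->second) by_diag[sj - qp].push_back(sj);
          }
        }
      }
      std::vector<int> seeds;
      for (auto &kv : by_diag) {
        std::vector<int> &v = kv.second; // ascending by construction
        for (size_t t = 0; t + 1 < v.size(); ++t) {
          if (v[t + 1] - v[t] <= 40) {
            seeds.push_back(v[t]);
            seeds.push_back(v[t + 1]);
          }
        }
      }
      std::sort(seeds.begin(), seeds.end());
      seeds.erase(std::unique(seeds.begin(), seeds.end()), seeds.end());
      if (!seeds.empty()) {
        std::vector<std::pair<int,int>> wins;
        int lo = seeds[0], hiw = seeds[0];
        for (size_t t = 1; t < seeds.size(); ++t) {
          if (seeds[t] - hiw > window_gap) { wins.push_back({lo, hiw}); lo = seeds[t]; }
          hiw = seeds[t];
        }
        wins.push_back({lo, hiw});
        std::vector<std::pair<int,int>> merged;
        for (auto &w : wins) {
          int a = std::max(0, w.first - window_margin);
          int b = std::min(n, w.second + seed_k + window_margin);
          if (!merged.empty() && a <= merged.back().second) {
            merged.back().second = std::max(merged.back().second, b);
          } else merged.push_back({a, b});
        }
        for (auto &w : merged) {
          std::vector<int> slice(sv.begin() + w.first, sv.begin() + w.second);
          collect_hsps(qv, slice, w.first, subf, nsub, gap_open, gap_extend,
                       min_score, max_hsps, hits);
        }
      }
    }
  }
  int k = (int)hits.size();
  NumericVector score(k); IntegerVector qs(k), qe(k), ss(k), se(k), nid(k), len(k);
  for (int i = 0; i < k; ++i) {
    score[i] = hits[i].score; qs[i] = hits[i].qstart; qe[i] = hits[i].qend;
    ss[i] = hits[i].sstart; se[i] = hits[i].send;
    nid[i] = hits[i].nident; len[i] = hits[i].length;
  }
  return DataFrame::create(_["raw_score"] = score, _["qstart0"] = qs,
                           _["qend0"] = qe, _["sstart0"] = ss, _["send0"] = se,
                           _["nident"] = nid, _["length"] = len);
}

// Single best local alignment (protein vs protein), 1-based inclusive coords.
// [[Rcpp::export(name = ".cpp_sw_pair")]]
List cpp_sw_pair(IntegerVector q, IntegerVector s, NumericMatrix sub,
                 double gap_open, double gap_extend) {
  std::vector<int> qv(q.begin(), q.end()), sv(s.begin(), s.end());
  const int nsub = sub.nrow();
  std::vector<double> subf((size_t)nsub * nsub);
  for (int a = 0; a < nsub; ++a)
    for (int b = 0; b < nsub; ++b) subf[(size_t)a * nsub + b] = sub(a, b);
  std::vector<char> masked(sv.size(), 0);
  AlnHit hit;
  if (qv.empty() || sv.empty() ||
      !sw_best(qv, sv, subf, nsub, gap_open, gap_extend, masked, hit))
    return List::create(_["score"] = 0.0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["nident"] = 0, _["length"] = 0);
  return List::create(_["score"] = hit.score, _["qstart"] = hit.qstart + 1,
                      _["qend"] = hit.qend, _["sstart"] = hit.sstart + 1,
                      _["send"] = hit.send, _["nident"] = hit.nident,
                      _["length"] = hit.length);
}
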