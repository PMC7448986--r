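#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Spliced local alignment of a reference protein against locus DNA.
// DP over (dna bases consumed i, reference residues consumed j) with states:
//   H  - main state, reached by codon match (3 bp -> 1 aa, BLOSUM on the
//        translated codon; stop codons score stop_score and translate to X),
//        by a 2-bp or 4-bp frameshift step (fs_penalty, emits X), by closing
//        a codon gap (D: unmatched genomic codons, translated into the model
//        protein) or reference gap (I: reference residues absent from the
//        model), or by an intron jump: a zero-emission skip from a GT donor
//        to an AG acceptor of length >= min_intron at a flat intron_penalty,
//        allowed only between codons.
// Local semantics: H may restart at 0; the best cell anywhere ends the model.

static inline int codon_code(int a, int b, int c) { return a * 25 + b * 5 + c; }

// [[Rcpp::export(name = ".cpp_spliced_align")]]
List cpp_spliced_align(IntegerVector prot, IntegerVector dna,
                       NumericMatrix sub, IntegerVector codon2aa,
                       double gap_open, double gap_extend, double fs_penalty,
                       double intron_penalty, double stop_score,
                       int min_intron, int aa_stop, int aa_x) {
  const int m = (int)prot.size(), n = (int)dna.size();
  if ((double)(n + 1) * (m + 1) > 6e7)
    stop("locus too large for spliced alignment (%d bp x %d aa)", n, m);
  const double NEG = -1e30;
  const size_t W = (size_t)m + 1;
  std::vector<float> H((size_t)(n + 1) * W, 0.0f);
  std::vector<uint8_t> tbH((size_t)(n + 1) * W, 0); // 0 start,1 match,2 fs2,3 fs4,4 D,5 I,6 intron
  std::vector<uint8_t> tbD((size_t)(n + 1) * W, 0); // 0 open, 1 extend
  std::vector<uint8_t> tbI((size_t)(n + 1) * W, 0);
  // D rolls over 4 rows (depends on i-3); I is within-row (j-1)
  std::vector<std::vector<double>> Dring(4, std::vector<double>(W, NEG));
  std::vector<double> Icur(W, NEG);
  std::vector<float> runmax(W, (float)NEG); // best donor H per j, lagged
  std::vector<double> aaScore(m + 1); // scratch per codon
  // translated codon per dna end-position (codon = dna[i-3..i-1])
  std::vector<int> codAA(n + 1, -1);
  for (int i = 3; i <= n; ++i)
    codAA[i] = codon2aa[codon_code(dna[i - 3], dna[i - 2], dna[i - 1])];
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 0; i <= n; ++i) {
    const size_t row = (size_t)i * W;
    std::vector<double> &Dcur = Dring[i % 4];
    const std::vector<double> &D3 = Dring[(i + 1) % 4]; // row i-3
    // fold donor row i - min_intron into the running per-j maxima
    int d = i - min_intron;
    if (d >= 0 && d + 1 < n && dna[d] == 2 /*G*/ && dna[d + 1] == 3 /*T*/) {
      const size_t drow = (size_t)d * W;
      for (int j = 0; j <= m; ++j)
        if (H[drow + j] > runmax[j]) runmax[j] = H[drow + j];
    }
    const bool acceptor = (i >= 2 && dna[i - 2] == 0 /*A*/ && dna[i - 1] == 2 /*G*/);
    for (int j = 0; j <= m; ++j) {
      // D: consume a genomic codon with no reference residue
      double dval = NEG; uint8_t dtb = 0;
      if (i >= 3) {
        double extra = (codAA[i] == aa_stop) ? stop_score : 0.0;
        double dopen = (double)H[(size_t)(i - 3) * W + j] + gap_open + gap_extend + extra;
        double dext = D3[j] + gap_extend + extra;
        if (dext > dopen) { dval = dext; dtb = 1; } else { dval = dopen; dtb = 0; }
      }
      Dcur[j] = dval; tbD[row + j] = dtb;
      // I: consume a reference residue with no genomic bases
      double ival = NEG; uint8_t itb = 0;
      if (j >= 1) {
        double iopen = (double)H[row + j - 1] + gap_open + gap_extend;
        double iext = Icur[j - 1] + gap_extend;
        if (iext > iopen) { ival = iext; itb = 1; } else { ival = iopen; itb = 0; }
      }
      Icur[j] = ival; tbI[row + j] = itb;
      double h = 0.0; uint8_t t = 0;
      if (i >= 3 && j >= 1) {
        int ca = codAA[i];
        double sc = (ca == aa_stop) ? stop_score : sub(ca, prot[j - 1]);
        double v = (double)H[(size_t)(i - 3) * W + j - 1] + sc;
        if (v > h) { h = v; t = 1; }
      }
      if (i >= 2 && j >= 1) {
        double v = (double)H[(size_t)(i - 2) * W + j - 1] + fs_penalty;
        if (v > h) { h = v; t = 2; }
      }
      if (i >= 4 && j >= 1) {
        double v = (double)H[(size_t)(i - 4) * W + j - 1] + fs_penalty;
        if (v > h) { h = v; t = 3; }
      }
      if (dval > h) { h = dval; t = 4; }
      if (ival > h) { h = ival; t = 5; }
      if (acceptor && runmax[j] > (float)NEG) {
        double v = (double)runmax[j] + intron_penalty;
        if (v > h) { h = v; t = 6; }
      }
      H[row + j] = (float)h; tbH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["exons"] = IntegerMatrix(0, 2),
                        _["protein"] = IntegerVector(0),
                        _["frameshift_events"] = 0, _["internal_stops"] = 0,
                        _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["aligned"] = false);
  }
  // traceback
  int i = bi, j = bj, state = 0, nfs = 0, nstop = 0;
  std::vector<int> aa_rev;                 // model protein, reversed
  std::vector<std::pair<int,int>> exons;   // built back-to-front
  int exon_end = bi;
  while (true) {
    const size_t idx = (size_t)i * W + j;
    if (state == 0) {
      uint8_t t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        int ca = codAA[i];
        if (ca == aa_stop) { ++nstop; aa_rev.push_back(aa_x); }
        else aa_rev.push_back(ca);
        i -= 3; --j;
      } else if (t == 2) { ++nfs; aa_rev.push_back(aa_x); i -= 2; --j; }
      else if (t == 3) { ++nfs; aa_rev.push_back(aa_x); i -= 4; --j; }
      else if (t == 4) state = 1;
      else if (t == 5) state = 2;
      else { // intron: find the donor the forward pass folded in
        int dmax = i - min_intron;
        float bestd = (float)NEG; int darg = -1;
        for (int d2 = 0; d2 <= dmax; ++d2) {
          if (d2 + 1 < n && dna[d2] == 2 && dna[d2 + 1] == 3) {
            float v = H[(size_t)d2 * W + j];
            if (v > bestd) { bestd = v; darg = d2; }
          }
        }
        exons.push_back({i, exon_end});
        i = darg; exon_end = darg;
      }
    } else if (state == 1) { // D: genomic codon in the model, no reference aa
      uint8_t t = tbD[idx];
      int ca = codAA[i];
      if (ca == aa_stop) { ++nstop; aa_rev.push_back(aa_x); }
      else aa_rev.push_back(ca);
      i -= 3;
      if (t == 0) state = 0;
    } else { // I: reference residue skipped
      uint8_t t = tbI[idx];
      --j;
      if (t == 0) state = 0;
    }
  }
  exons.push_back({i, exon_end});
  int k = (int)exons.size();
  IntegerMatrix ex(k, 2);
  for (int e = 0; e < k; ++e) { // reverse into 5'->3' order
    ex(e, 0) = exons[k - 1 - e].first;
    ex(e, 1) = exons[k - 1 - e].second;
  }
  IntegerVector paa(aa_rev.size());
  for (size_t t = 0; t < aa_rev.size(); ++t) paa[t] = aa_rev[aa_rev.size() - 1 - t];
  return List::create(_["score"] = best, _["exons"] = ex, _["protein"] = paa,
                      _["frameshift_events"] = nfs, _["internal_stops"] = nstop,
                      _["qstart"] = j + 1, _["qend"] = bj, _["aligned"] = true);
}
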