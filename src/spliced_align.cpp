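#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Spliced alignment of an evidence CDS against a genomic sequence:
// global in the CDS (every evidence base must be matched, mismatched or
// explicitly deleted), free end gaps in the genomic. Exonic portions align
// under match/mismatch + affine gaps (a gap of length L costs
// gap_open + L*gap_ext); the genomic side may additionally be skipped by an
// intron, which must begin "GT", end "AG" and be at least `min_intron` nt,
// at a flat `intron_penalty`. The O(m*n) formulation keeps a per-row running
// maximum over admissible donor sites so the intron jump is a constant-time
// transition.
//
// Coordinates in the result are 1-based and inclusive.
// [[Rcpp::export(name = ".spliced_align")]]
List spliced_align(std::string cds, std::string genomic,
                   double match, double mismatch,
                   double gap_open, double gap_ext,
                   double intron_penalty, int min_intron) {
  const int m = (int)cds.size(), n = (int)genomic.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  if (min_intron < 4) min_intron = 4;

  // pointer matrices, column-major (m+1) x (n+1)
  const size_t sz = (size_t)(m + 1) * (size_t)(n + 1);
  // echoice: -1 start, 0 M, 1 X (genomic gap run), 2 Y (cds deletion), 3 intron
  std::vector<signed char> echoice(sz, -1), px(sz, 0), py(sz, 0);
  std::vector<int> donor_at(sz, 0);
  auto IX = [&](int i, int j) { return (size_t)j * (m + 1) + i; };

  std::vector<double> Xp(m + 1, NEG);            // X, previous column
  std::vector<double> Mc(m + 1, NEG), Xc(m + 1, NEG), Yc(m + 1, NEG);
  const int ring = min_intron + 2;
  std::vector<std::vector<double>> Ering(ring, std::vector<double>(m + 1, NEG));
  std::vector<double> D(m + 1, NEG);
  std::vector<int> Darg(m + 1, 0);

  // column 0: E[0][0] = 0 (start); leading cds deletions via Y
  {
    std::vector<double> &E0 = Ering[0];
    E0[0] = 0.0;
    double y = NEG;
    for (int i = 1; i <= m; ++i) {
      double yo = E0[i - 1] - gap_open - gap_ext, ye = y - gap_ext;
      if (yo >= ye) { y = yo; py[IX(i, 0)] = 0; }
      else          { y = ye; py[IX(i, 0)] = 1; }
      E0[i] = y; echoice[IX(i, 0)] = 2;
    }
  }

  double best = NEG; int bj = -1;
  std::vector<double> Ecur(m + 1, NEG);
  for (int j = 1; j <= n; ++j) {
    // admit donor d = j - min_intron + 1 (intron d..j has length min_intron)
    int d = j - min_intron + 1;
    if (d >= 1 && d + 1 <= n && genomic[d - 1] == 'G' && genomic[d] == 'T') {
      const std::vector<double> &Ed = Ering[(d - 1) % ring];
      for (int i = 0; i <= m; ++i)
        if (Ed[i] > D[i]) { D[i] = Ed[i]; Darg[i] = d; }
    }
    bool acceptor = (j >= 2 && genomic[j - 2] == 'A' && genomic[j - 1] == 'G');
    const std::vector<double> &Eprev = Ering[(j - 1) % ring];

    // i = 0: free leading genomic
    Ecur[0] = 0.0; echoice[IX(0, j)] = -1;
    Mc[0] = Xc[0] = Yc[0] = NEG;
    for (int i = 1; i <= m; ++i) {
      char a = cds[i - 1], b = genomic[j - 1];
      Mc[i] = Eprev[i - 1] + ((a == b) ? match : mismatch);
      // X: consume genomic within an exon (insertion relative to evidence)
      double xo = Eprev[i] - gap_open - gap_ext, xe = Xp[i] - gap_ext;
      if (xo >= xe) { Xc[i] = xo; px[IX(i, j)] = 0; }
      else          { Xc[i] = xe; px[IX(i, j)] = 1; }
      // Y: delete evidence bases
      double yo = Ecur[i - 1] - gap_open - gap_ext, ye = Yc[i - 1] - gap_ext;
      if (yo >= ye) { Yc[i] = yo; py[IX(i, j)] = 0; }
      else          { Yc[i] = ye; py[IX(i, j)] = 1; }
      // E
      double e = Mc[i]; signed char ch = 0;
      if (Xc[i] > e) { e = Xc[i]; ch = 1; }
      if (Yc[i] > e) { e = Yc[i]; ch = 2; }
      if (acceptor) {
        double ar = D[i] - intron_penalty;
        if (ar > e) { e = ar; ch = 3; donor_at[IX(i, j)] = Darg[i]; }
      }
      Ecur[i] = e; echoice[IX(i, j)] = ch;
    }
    if (Ecur[m] > best) { best = Ecur[m]; bj = j; }   // free trailing genomic
    Ering[j % ring] = Ecur;
    std::swap(Xp, Xc);
  }
  // all-deletion corner (no genomic consumed at all)
  if (Ering[0][m] > best) { best = Ering[0][m]; bj = 0; }

  if (bj <= 0 || best == NEG)
    return List::create(_["score"] = best, _["cds_span"] = IntegerVector::create(0, 0),
                        _["exons"] = IntegerMatrix(0, 2), _["n_mismatch"] = 0,
                        _["n_cds_deleted"] = m);

  std::vector<std::pair<int, int>> introns;
  int i = m, j = bj;
  int state = echoice[IX(i, j)];
  int gmin = 0, gmax = 0, mism = 0, del = 0;
  auto follow_introns = [&]() {
    while (state == 3) {
      int d = donor_at[IX(i, j)];
      introns.push_back({d, j});
      j = d - 1;
      state = echoice[IX(i, j)];
    }
  };
  follow_introns();
  while (i > 0 && state != -1) {
    if (state == 0) {
      if (gmax == 0) gmax = j;
      gmin = j;
      if (cds[i - 1] != genomic[j - 1]) ++mism;
      --i; --j;
      state = echoice[IX(i, j)];
      follow_introns();
    } else if (state == 1) {
      if (gmax == 0) gmax = j;
      gmin = j;
      signed char p = px[IX(i, j)];
      --j;
      if (p == 0) { state = echoice[IX(i, j)]; follow_introns(); }
    } else { // state == 2
      ++del;
      signed char p = py[IX(i, j)];
      --i;
      if (p == 0) { state = echoice[IX(i, j)]; follow_introns(); }
    }
  }

  IntegerMatrix ex(0, 2);
  if (gmax > 0) {
    std::vector<std::pair<int, int>> exons;
    int end = gmax;
    for (auto &in : introns) {
      if (in.second + 1 <= end) exons.push_back({in.second + 1, end});
      end = in.first - 1;
    }
    if (gmin <= end) exons.push_back({gmin, end});
    std::reverse(exons.begin(), exons.end());
    ex = IntegerMatrix((int)exons.size(), 2);
    for (int k = 0; k < (int)exons.size(); ++k) {
      ex(k, 0) = exons[k].first; ex(k, 1) = exons[k].second;
    }
  }

  return List::create(_["score"] = best,
                      _["cds_span"] = IntegerVector::create(1, m),
                      _["exons"] = ex,
                      _["n_mismatch"] = mism,
                      _["n_cds_deleted"] = del);
}
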