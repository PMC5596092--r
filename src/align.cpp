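#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact Smith-Waterman-Gotoh local alignment with affine gaps. A gap of
// length L scores gap_open + L * gap_extend (both negative). Among equally
// scoring optima the alignment with the smallest query start, then smallest
// subject start, is returned.

struct Aln {
  double score;
  int qs, qe, ss, se;  // 1-based inclusive
  std::string qaln, saln;
};

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b, double match, double mismatch,
              double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const double NEG = -1e30;
  size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> H(sz, 0.0), E(sz, NEG), F(sz, NEG);
  // traceback codes for H: 0 stop, 1 diag, 2 from E (gap in query row a), 3 from F
  std::vector<unsigned char> tH(sz, 0), tE(sz, 0), tF(sz, 0);
  double best = 0.0;
  size_t idx;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      idx = (size_t)i * (m + 1) + j;
      size_t up = idx - (m + 1), left = idx - 1, diag = up - 1;
      // E: gap in a (consume b[j]) -> horizontal
      double eo = H[left] + gap_open + gap_extend;
      double ee = E[left] + gap_extend;
      if (ee > eo) { E[idx] = ee; tE[idx] = 1; } else { E[idx] = eo; tE[idx] = 0; }
      // F: gap in b (consume a[i]) -> vertical
      double fo = H[up] + gap_open + gap_extend;
      double fe = F[up] + gap_extend;
      if (fe > fo) { F[idx] = fe; tF[idx] = 1; } else { F[idx] = fo; tF[idx] = 0; }
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double h = H[diag] + s;
      unsigned char t = 1;
      if (F[idx] > h) { h = F[idx]; t = 3; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (h <= 0.0) { h = 0.0; t = 0; }
      H[idx] = h;
      tH[idx] = t;
      if (h > best) best = h;
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0);
  }
  // collect optima, traceback each, keep smallest (qs, ss)
  Aln chosen;
  chosen.score = -1.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      idx = (size_t)i * (m + 1) + j;
      if (H[idx] < best - 1e-9) continue;
      // traceback
      std::string qa, sa;
      int ci = i, cj = j;
      int state = 0;  // 0 = in H
      while (true) {
        size_t c = (size_t)ci * (m + 1) + cj;
        if (state == 0) {
          unsigned char t = tH[c];
          if (t == 0) break;
          if (t == 1) {
            qa.push_back(a[ci - 1]);
            sa.push_back(b[cj - 1]);
            --ci; --cj;
            if (H[(size_t)ci * (m + 1) + cj] <= 0.0 &&
                tH[(size_t)ci * (m + 1) + cj] == 0) break;
          } else if (t == 2) {
            state = 2;
          } else {
            state = 3;
          }
        } else if (state == 2) {
          qa.push_back('-');
          sa.push_back(b[cj - 1]);
          unsigned char t = tE[c];
          --cj;
          state = (t == 1) ? 2 : 0;
        } else {
          qa.push_back(a[ci - 1]);
          sa.push_back('-');
          unsigned char t = tF[c];
          --ci;
          state = (t == 1) ? 3 : 0;
        }
      }
      std::reverse(qa.begin(), qa.end());
      std::reverse(sa.begin(), sa.end());
      int qs = ci + 1, ss = cj + 1;
      if (chosen.score < 0 || qs < chosen.qs ||
          (qs == chosen.qs && ss < chosen.ss)) {
        chosen.score = best;
        chosen.qs = qs; chosen.qe = i;
        chosen.ss = ss; chosen.se = j;
        chosen.qaln = qa; chosen.saln = sa;
      }
    }
  }
  int ident = 0, cols = 0, ug = 0;
  for (size_t k = 0; k < chosen.qaln.size(); ++k) {
    if (chosen.qaln[k] != '-' && chosen.saln[k] != '-') {
      ++ug;
      if (chosen.qaln[k] == chosen.saln[k]) ++ident;
    }
    ++cols;
  }
  return List::create(
      _["score"] = chosen.score, _["q_start"] = chosen.qs,
      _["q_end"] = chosen.qe, _["s_start"] = chosen.ss, _["s_end"] = chosen.se,
      _["q_aln"] = chosen.qaln, _["s_aln"] = chosen.saln,
      _["identity"] = ug > 0 ? (double)ident / ug : 0.0,
      _["n_columns"] = cols, _["n_ungapped"] = ug);
}

// Maximum ungapped segment score over all diagonals (Kadane per diagonal);
// used for Karlin-Altschul K calibration by simulation.
// [[Rcpp::export(name = ".ungapped_max_score")]]
double ungapped_max_score(std::string a, std::string b, double match,
                          double mismatch) {
  int n = a.size(), m = b.size();
  double best = 0.0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    double run = 0.0;
    int i0 = std::max(0, -d);
    int i1 = std::min(n - 1, m - 1 - d);
    for (int i = i0; i <= i1; ++i) {
      double s = (a[i] == b[i + d]) ? match : mismatch;
      run += s;
      if (run < 0) run = 0;
      if (run > best) best = run;
    }
  }
  return best;
}
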