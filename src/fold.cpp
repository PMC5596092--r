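#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-free-energy folding engine shared by the single-sequence screen and
// the consensus (two-row alignment) fold used for the structure conservation
// index. Model: nearest-neighbor stacking for adjacent pairs, linear length
// penalties for hairpin/bulge/internal loops, linear multiloop model, no
// dangles. A column of an alignment may pair only if every row forms a legal
// pair (AU/UA/GC/CG/GU/UG) at those columns; stack terms are averaged over
// rows and a fixed bonus rewards compensatory (double-substituted) pairs.

static const double INF_E = 1e30;
static const int MINLOOP = 3;   // minimum hairpin loop, columns
static const int MAXLOOP = 30;  // max bulge/internal loop total length

static inline int pairtype(int a, int b) {
  // base codes: 1=A 2=C 3=G 4=U, 0=gap/other
  if (a == 2 && b == 3) return 1;  // CG
  if (a == 3 && b == 2) return 2;  // GC
  if (a == 3 && b == 4) return 3;  // GU
  if (a == 4 && b == 3) return 4;  // UG
  if (a == 1 && b == 4) return 5;  // AU
  if (a == 4 && b == 1) return 6;  // UA
  return 0;
}

struct FoldModel {
  double stack[7][7];
  double hp_a, hp_c, bu_a, bu_c, in_a, in_c, ml_a, ml_b, ml_c, comp_bonus;
};

class Folder {
public:
  int n, nrow;
  std::vector<std::vector<int> > rows;  // [nrow][n]
  FoldModel mod;
  std::vector<double> V, WM;
  std::vector<double> F;

  double &v(int i, int j) { return V[(size_t)i * n + j]; }
  double &wm(int i, int j) { return WM[(size_t)i * n + j]; }

  bool pair_ok(int i, int j) {
    if (j - i - 1 < MINLOOP) return false;
    for (int r = 0; r < nrow; ++r)
      if (pairtype(rows[r][i], rows[r][j]) == 0) return false;
    return true;
  }

  double pbonus(int i, int j) {
    if (nrow != 2) return 0.0;
    if (rows[0][i] != rows[1][i] && rows[0][j] != rows[1][j])
      return mod.comp_bonus;
    return 0.0;
  }

  double stackE(int i, int j, int k, int l) {
    double s = 0.0;
    for (int r = 0; r < nrow; ++r) {
      int p1 = pairtype(rows[r][i], rows[r][j]);
      int p2 = pairtype(rows[r][k], rows[r][l]);
      s += mod.stack[p1][p2];
    }
    return s / nrow;
  }

  double hairpinE(int i, int j) {
    int L = j - i - 1;
    return mod.hp_a + mod.hp_c * (L - MINLOOP);
  }

  double interiorE(int i, int j, int k, int l) {
    int L1 = k - i - 1, L2 = j - l - 1;
    if (L1 == 0 && L2 == 0) return stackE(i, j, k, l);
    if (L1 == 0 || L2 == 0) return mod.bu_a + mod.bu_c * (L1 + L2);
    return mod.in_a + mod.in_c * (L1 + L2);
  }

  void fill() {
    V.assign((size_t)n * n, INF_E);
    WM.assign((size_t)n * n, INF_E);
    for (int len = MINLOOP + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        // V(i,j)
        if (pair_ok(i, j)) {
          double best = hairpinE(i, j);
          int kmax = std::min(j - MINLOOP - 2, i + 1 + MAXLOOP);
          for (int k = i + 1; k <= kmax; ++k) {
            int lmin = std::max(k + MINLOOP + 1, j - 1 - (MAXLOOP - (k - i - 1)));
            for (int l = j - 1; l >= lmin; --l) {
              double vkl = v(k, l);
              if (vkl >= INF_E / 2) continue;
              double e = vkl + interiorE(i, j, k, l);
              if (e < best) best = e;
            }
          }
          // multiloop closure: >= 2 branches inside
          for (int m = i + 1; m < j - 1; ++m) {
            double a = wm(i + 1, m), b = wm(m + 1, j - 1);
            if (a >= INF_E / 2 || b >= INF_E / 2) continue;
            double e = mod.ml_a + mod.ml_b + a + b;
            if (e < best) best = e;
          }
          v(i, j) = best + pbonus(i, j);
        }
        // WM(i,j): >=1 branch, multiloop interior energies
        double w = INF_E;
        if (v(i, j) < INF_E / 2) w = v(i, j) + mod.ml_b;
        if (i + 1 <= j && wm(i + 1, j) < INF_E / 2)
          w = std::min(w, wm(i + 1, j) + mod.ml_c);
        if (i <= j - 1 && wm(i, j - 1) < INF_E / 2)
          w = std::min(w, wm(i, j - 1) + mod.ml_c);
        for (int m = i + 1; m < j; ++m) {
          double a = wm(i, m), b = wm(m + 1, j);
          if (a >= INF_E / 2 || b >= INF_E / 2) continue;
          w = std::min(w, a + b);
        }
        wm(i, j) = w;
      }
    }
    // external
    F.assign(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
      double best = F[j - 1];
      for (int k = 1; k <= j; ++k) {
        double vkj = v(k - 1, j - 1);
        if (vkj >= INF_E / 2) continue;
        double e = F[k - 1] + vkj;
        if (e < best - 1e-12) best = e;
      }
      F[j] = best;
    }
  }

  // traceback -------------------------------------------------------------
  std::vector<std::pair<int, int> > pairs;

  void trace_ext(int j) {  // F[j], 1-based
    const double eps = 1e-9;
    while (j > 0) {
      if (std::fabs(F[j] - F[j - 1]) <= eps) { --j; continue; }
      bool found = false;
      for (int k = 1; k <= j; ++k) {
        double vkj = v(k - 1, j - 1);
        if (vkj >= INF_E / 2) continue;
        if (std::fabs(F[j] - (F[k - 1] + vkj)) <= eps) {
          trace_v(k - 1, j - 1);
          j = k - 1;
          found = true;
          break;
        }
      }
      if (!found) --j;  // numerical safety
    }
  }

  void trace_v(int i, int j) {
    const double eps = 1e-9;
    pairs.push_back(std::make_pair(i, j));
    double target = v(i, j) - pbonus(i, j);
    if (std::fabs(target - hairpinE(i, j)) <= eps) return;
    int kmax = std::min(j - MINLOOP - 2, i + 1 + MAXLOOP);
    for (int k = i + 1; k <= kmax; ++k) {
      int lmin = std::max(k + MINLOOP + 1, j - 1 - (MAXLOOP - (k - i - 1)));
      for (int l = j - 1; l >= lmin; --l) {
        double vkl = v(k, l);
        if (vkl >= INF_E / 2) continue;
        if (std::fabs(target - (vkl + interiorE(i, j, k, l))) <= eps) {
          trace_v(k, l);
          return;
        }
      }
    }
    for (int m = i + 1; m < j - 1; ++m) {
      double a = wm(i + 1, m), b = wm(m + 1, j - 1);
      if (a >= INF_E / 2 || b >= INF_E / 2) continue;
      if (std::fabs(target - (mod.ml_a + mod.ml_b + a + b)) <= eps) {
        trace_wm(i + 1, m);
        trace_wm(m + 1, j - 1);
        return;
      }
    }
  }

  void trace_wm(int i, int j) {
    const double eps = 1e-9;
    double w = wm(i, j);
    if (w >= INF_E / 2) return;
    if (i + 1 <= j && wm(i + 1, j) < INF_E / 2 &&
        std::fabs(w - (wm(i + 1, j) + mod.ml_c)) <= eps) {
      trace_wm(i + 1, j);
      return;
    }
    if (i <= j - 1 && wm(i, j - 1) < INF_E / 2 &&
        std::fabs(w - (wm(i, j - 1) + mod.ml_c)) <= eps) {
      trace_wm(i, j - 1);
      return;
    }
    if (v(i, j) < INF_E / 2 && std::fabs(w - (v(i, j) + mod.ml_b)) <= eps) {
      trace_v(i, j);
      return;
    }
    for (int m = i + 1; m < j; ++m) {
      double a = wm(i, m), b = wm(m + 1, j);
      if (a >= INF_E / 2 || b >= INF_E / 2) continue;
      if (std::fabs(w - (a + b)) <= eps) {
        trace_wm(i, m);
        trace_wm(m + 1, j);
        return;
      }
    }
  }
};

// [[Rcpp::export(name = ".fold_engine")]]
List fold_engine(List rows, NumericMatrix stack, NumericVector loop_params) {
  Folder f;
  f.nrow = rows.size();
  if (f.nrow < 1) stop("at least one row required");
  for (int r = 0; r < f.nrow; ++r) {
    IntegerVector rv = rows[r];
    f.rows.push_back(std::vector<int>(rv.begin(), rv.end()));
  }
  f.n = f.rows[0].size();
  for (int r = 1; r < f.nrow; ++r)
    if ((int)f.rows[r].size() != f.n) stop("rows of unequal length");
  if (f.n > 4000) stop("sequence too long for the folding engine");
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j) f.mod.stack[i][j] = 0.0;
  for (int i = 1; i <= 6; ++i)
    for (int j = 1; j <= 6; ++j) f.mod.stack[i][j] = stack(i - 1, j - 1);
  f.mod.hp_a = loop_params["hairpin_a"];
  f.mod.hp_c = loop_params["hairpin_c"];
  f.mod.bu_a = loop_params["bulge_a"];
  f.mod.bu_c = loop_params["bulge_c"];
  f.mod.in_a = loop_params["internal_a"];
  f.mod.in_c = loop_params["internal_c"];
  f.mod.ml_a = loop_params["multi_a"];
  f.mod.ml_b = loop_params["multi_b"];
  f.mod.ml_c = loop_params["multi_c"];
  f.mod.comp_bonus = loop_params["comp_bonus"];

  double energy = 0.0;
  std::string db(f.n, '.');
  if (f.n >= MINLOOP + 2) {
    f.fill();
    energy = f.F[f.n];
    if (energy < -1e-12) {
      f.trace_ext(f.n);
      for (size_t k = 0; k < f.pairs.size(); ++k) {
        db[f.pairs[k].first] = '(';
        db[f.pairs[k].second] = ')';
      }
    } else {
      energy = 0.0;
    }
  }
  int np = 0;
  for (int i = 0; i < f.n; ++i) if (db[i] == '(') ++np;
  IntegerMatrix pm(np, 2);
  {
    int k = 0;
    // report pairs sorted by opening position
    std::vector<std::pair<int, int> > ps(f.pairs.begin(), f.pairs.end());
    std::sort(ps.begin(), ps.end());
    for (size_t t = 0; t < ps.size(); ++t) {
      pm(k, 0) = ps[t].first + 1;
      pm(k, 1) = ps[t].second + 1;
      ++k;
    }
  }
  return List::create(_["energy"] = energy, _["structure"] = db,
                      _["n_pairs"] = np, _["pairs"] = pm);
}
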