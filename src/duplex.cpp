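#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Intermolecular duplex minimum-free-energy dynamic program.
//
// Bases are encoded A=0, C=1, G=2, U=3. The miRNA is read 5'->3'; the target
// window is reversed internally so that both strands advance in the same
// direction (antiparallel hybridization). A structure is a set of base pairs
// (i1<...<ip on the miRNA, k1<...<kp on the reversed window), i.e. a
// non-crossing, purely intermolecular pairing with one contiguous duplex.
// Energy = sum over consecutive pair steps of
//   stack(pair_t, pair_{t+1})                        if no unpaired bases
//   bulge_open + bulge_ext * L                       if L unpaired on one side
//   loop_open + loop_ext * (L1+L2)                   if unpaired on both sides
// plus end_pen per helix end (two ends). Caps: a bulge may not exceed
// max_bulge nt, an internal loop may not exceed max_loop nt per side
// (negative cap = uncapped).
//
// Because gap penalties are linear in length, uncapped transitions reduce to
// prefix minima of E minus a linear drift, giving O(M*W) amortized work per
// window; capped transitions use bounded scans (caps are small). The
// traceback re-identifies each step by energy search, so no predecessor
// matrix is stored.

static const double INF = std::numeric_limits<double>::infinity();

// pair codes: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5, -1 = not pairable
static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct DuplexResult {
  double mfe;
  std::vector<int> mi;  // miRNA positions, 1-based, 5'->3'
  std::vector<int> wj;  // window positions, 1-based on the original window
};

struct Params {
  const NumericMatrix* stack;
  double bo, be, lo, le, ep;
  int maxb, maxl;
};

// cost of the step from pair (i2,k2) to pair (i,k); INF if inadmissible
static inline double step_cost(const Params& P, const std::vector<int>& pc,
                               int W, int i2, int k2, int i, int k) {
  int gi = i - i2 - 1, gk = k - k2 - 1;
  if (gi == 0 && gk == 0)
    return (*P.stack)(pc[(size_t)i2 * W + k2], pc[(size_t)i * W + k]);
  if (gi == 0 || gk == 0) {
    int L = gi + gk;
    if (P.maxb >= 0 && L > P.maxb) return INF;
    return P.bo + P.be * L;
  }
  int side = gi > gk ? gi : gk;
  if (P.maxl >= 0 && side > P.maxl) return INF;
  return P.lo + P.le * (gi + gk);
}

static DuplexResult duplex_dp(const std::vector<int>& m,
                              const std::vector<int>& w,
                              const Params& P,
                              bool traceback) {
  const int M = m.size(), W = w.size();
  DuplexResult res;
  res.mfe = INF;
  if (M == 0 || W == 0) return res;

  std::vector<int> r(W);
  for (int k = 0; k < W; ++k) r[k] = w[W - 1 - k];

  std::vector<double> E((size_t)M * W, INF);
  std::vector<int> pc((size_t)M * W, -1);
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < W; ++k)
      pc[(size_t)i * W + k] = pair_code(m[i], r[k]);

  const bool fast_bulge = P.maxb < 0;
  const bool fast_loop = P.maxl < 0;

  // colMin[k]: min over i2 <= i-2 of E[i2][k] - be*i2   (miRNA-side bulge)
  // loopPref[k]: min over i2 <= i-2, k2 <= k of E[i2][k2] - le*(i2+k2)
  std::vector<double> colMin(W, INF), loopPref(W, INF);
  std::vector<double> rowPrefPrev(W, INF);  // row i-1: prefix min of E - be*k2

  for (int i = 0; i < M; ++i) {
    // rowPrefPrev over row i-1
    if (i >= 1) {
      double run = INF;
      for (int k = 0; k < W; ++k) {
        double v = E[(size_t)(i - 1) * W + k];
        if (v - P.be * k < run) run = v - P.be * k;
        rowPrefPrev[k] = run;
      }
    }
    for (int k = 0; k < W; ++k) {
      int c = pc[(size_t)i * W + k];
      if (c < 0) continue;
      double best = P.ep;  // open a new helix here
      // stack
      if (i >= 1 && k >= 1) {
        double prev = E[(size_t)(i - 1) * W + (k - 1)];
        if (std::isfinite(prev)) {
          double cand = prev + (*P.stack)(pc[(size_t)(i - 1) * W + (k - 1)], c);
          if (cand < best) best = cand;
        }
      }
      // target-side bulge: i2 = i-1, k2 <= k-2
      if (i >= 1 && k >= 2) {
        if (fast_bulge) {
          double v = rowPrefPrev[k - 2];
          if (std::isfinite(v)) {
            double cand = v + P.bo + P.be * (k - 1);
            if (cand < best) best = cand;
          }
        } else {
          int lim = k - 1 - P.maxb; if (lim < 0) lim = 0;
          for (int k2 = k - 2; k2 >= lim; --k2) {
            double prev = E[(size_t)(i - 1) * W + k2];
            if (!std::isfinite(prev)) continue;
            double cand = prev + P.bo + P.be * (k - k2 - 1);
            if (cand < best) best = cand;
          }
        }
      }
      // miRNA-side bulge: k2 = k-1, i2 <= i-2
      if (i >= 2 && k >= 1) {
        if (fast_bulge) {
          double v = colMin[k - 1];
          if (std::isfinite(v)) {
            double cand = v + P.bo + P.be * (i - 1);
            if (cand < best) best = cand;
          }
        } else {
          int lim = i - 1 - P.maxb; if (lim < 0) lim = 0;
          for (int i2 = i - 2; i2 >= lim; --i2) {
            double prev = E[(size_t)i2 * W + (k - 1)];
            if (!std::isfinite(prev)) continue;
            double cand = prev + P.bo + P.be * (i - i2 - 1);
            if (cand < best) best = cand;
          }
        }
      }
      // internal loop: i2 <= i-2, k2 <= k-2
      if (i >= 2 && k >= 2) {
        if (fast_loop) {
          double v = loopPref[k - 2];
          if (std::isfinite(v)) {
            double cand = v + P.lo + P.le * (i + k - 2);
            if (cand < best) best = cand;
          }
        } else {
          int ilim = i - 1 - P.maxl; if (ilim < 0) ilim = 0;
          int klim = k - 1 - P.maxl; if (klim < 0) klim = 0;
          for (int i2 = i - 2; i2 >= ilim; --i2)
            for (int k2 = k - 2; k2 >= klim; --k2) {
              double prev = E[(size_t)i2 * W + k2];
              if (!std::isfinite(prev)) continue;
              double cand = prev + P.lo + P.le * ((i - i2 - 1) + (k - k2 - 1));
              if (cand < best) best = cand;
            }
        }
      }
      E[(size_t)i * W + k] = best;
      if (best + P.ep < res.mfe) res.mfe = best + P.ep;
    }
    // fold row i-1 into the lagged prefix structures (so that at row i+1
    // they cover i2 <= i-1)
    if (i >= 1) {
      double run = INF;
      for (int k = 0; k < W; ++k) {
        double v = E[(size_t)(i - 1) * W + k];
        double d = v - P.be * (i - 1);
        if (d < colMin[k]) colMin[k] = d;
        double l = v - P.le * (i - 1 + k);
        if (l < run) run = l;
        if (run < loopPref[k]) loopPref[k] = run;
      }
    }
  }

  if (!std::isfinite(res.mfe)) return res;
  if (!traceback) return res;

  // locate the terminal pair, then walk back by energy search
  int ci = -1, ck = -1;
  for (int i = 0; i < M && ci < 0; ++i)
    for (int k = 0; k < W; ++k)
      if (std::isfinite(E[(size_t)i * W + k]) &&
          std::abs(E[(size_t)i * W + k] + P.ep - res.mfe) < 1e-9) {
        ci = i; ck = k; break;
      }
  const double tol = 1e-9;
  while (ci >= 0) {
    res.mi.push_back(ci + 1);
    res.wj.push_back(W - ck);
    double v = E[(size_t)ci * W + ck];
    if (std::abs(v - P.ep) < tol) break;  // helix start
    bool found = false;
    for (int i2 = ci - 1; i2 >= 0 && !found; --i2)
      for (int k2 = ck - 1; k2 >= 0; --k2) {
        double prev = E[(size_t)i2 * W + k2];
        if (!std::isfinite(prev)) continue;
        double sc = step_cost(P, pc, W, i2, k2, ci, ck);
        if (std::isfinite(sc) && std::abs(prev + sc - v) < tol) {
          ci = i2; ck = k2; found = true; break;
        }
      }
    if (!found) break;  // defensive: treat as helix start
  }
  std::reverse(res.mi.begin(), res.mi.end());
  std::reverse(res.wj.begin(), res.wj.end());
  return res;
}

static List result_to_list(const DuplexResult& r) {
  if (!std::isfinite(r.mfe))
    return List::create(_["mfe"] = R_PosInf,
                        _["mirna_pos"] = IntegerVector(0),
                        _["window_pos"] = IntegerVector(0));
  return List::create(_["mfe"] = r.mfe,
                      _["mirna_pos"] = wrap(r.mi),
                      _["window_pos"] = wrap(r.wj));
}

// [[Rcpp::export]]
List duplex_mfe_cpp(IntegerVector mirna, IntegerVector window,
                    NumericMatrix stack,
                    double bulge_open, double bulge_ext,
                    double loop_open, double loop_ext,
                    double end_pen, int max_bulge, int max_loop,
                    bool traceback = true) {
  std::vector<int> m = as<std::vector<int>>(mirna);
  std::vector<int> w = as<std::vector<int>>(window);
  Params P{&stack, bulge_open, bulge_ext, loop_open, loop_ext, end_pen,
           max_bulge, max_loop};
  DuplexResult r = duplex_dp(m, w, P, traceback);
  return result_to_list(r);
}

// Exhaustive enumeration oracle: depth-first over every admissible pairing
// (every increasing chain of pairable (i,k) positions), accumulating energy
// directly. No DP tables; intended for tiny sequences in tests.
struct EnumState {
  const std::vector<int>* m;
  const std::vector<int>* r;
  const NumericMatrix* stack;
  double bo, be, lo, le, ep;
  int maxb, maxl;
  double best;
};

static void enum_rec(EnumState& st, int li, int lk, int lc, double acc) {
  const int M = st.m->size(), W = st.r->size();
  // the current chain is itself a complete structure
  if (lc >= 0) {
    double total = acc + st.ep;  // closing end penalty
    if (total < st.best) st.best = total;
  }
  for (int i = li + 1; i < M; ++i) {
    for (int k = lk + 1; k < W; ++k) {
      int c = pair_code((*st.m)[i], (*st.r)[k]);
      if (c < 0) continue;
      double step;
      if (lc < 0) {
        step = st.ep;  // opening end penalty
      } else {
        int gi = i - li - 1, gk = k - lk - 1;
        if (gi == 0 && gk == 0) step = (*st.stack)(lc, c);
        else if (gi == 0 || gk == 0) {
          int L = gi + gk;
          if (st.maxb >= 0 && L > st.maxb) continue;
          step = st.bo + st.be * L;
        } else {
          int side = gi > gk ? gi : gk;
          if (st.maxl >= 0 && side > st.maxl) continue;
          step = st.lo + st.le * (gi + gk);
        }
      }
      enum_rec(st, i, k, c, acc + step);
    }
  }
}

// [[Rcpp::export]]
double duplex_mfe_enum_cpp(IntegerVector mirna, IntegerVector window,
                           NumericMatrix stack,
                           double bulge_open, double bulge_ext,
                           double loop_open, double loop_ext,
                           double end_pen, int max_bulge, int max_loop) {
  std::vector<int> m = as<std::vector<int>>(mirna);
  std::vector<int> w = as<std::vector<int>>(window);
  const int W = w.size();
  std::vector<int> r(W);
  for (int k = 0; k < W; ++k) r[k] = w[W - 1 - k];
  EnumState st{&m, &r, &stack, bulge_open, bulge_ext, loop_open, loop_ext,
               end_pen, max_bulge, max_loop, INF};
  enum_rec(st, -1, -1, -1, 0.0);
  return st.best;
}

// Windowed scan over a full region: one DP per window offset, returning all
// windows whose best duplex is stabilizing (mfe < 0). Overlap resolution is
// done on the R side.
// [[Rcpp::export]]
List scan_region_cpp(IntegerVector mirna, IntegerVector region,
                     NumericMatrix stack,
                     double bulge_open, double bulge_ext,
                     double loop_open, double loop_ext,
                     double end_pen, int max_bulge, int max_loop,
                     int width, int stride) {
  std::vector<int> m = as<std::vector<int>>(mirna);
  std::vector<int> reg = as<std::vector<int>>(region);
  const int L = reg.size();
  List out;
  if ((int)m.size() > L) return out;
  int w_eff = width < L ? width : L;
  Params P{&stack, bulge_open, bulge_ext, loop_open, loop_ext, end_pen,
           max_bulge, max_loop};
  for (int o = 0; o + w_eff <= L; o += stride) {
    std::vector<int> win(reg.begin() + o, reg.begin() + o + w_eff);
    DuplexResult r = duplex_dp(m, win, P, true);
    if (std::isfinite(r.mfe) && r.mfe < 0) {
      List h = result_to_list(r);
      h["offset"] = o;  // 0-based window offset on the region
      out.push_back(h);
    }
  }
  return out;
}
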