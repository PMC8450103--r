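// Core dynamic programming for compact profile-SCFG (covariance-model style)
// scoring, the structure-free first-pass profile scan, and fifth-order Markov
// sequence generation.
//
// Guide-tree node types (must match the R side):
//   0 ROOT, 1 SINGLE_L, 2 SINGLE_R, 3 PAIR, 4 BIF, 5 END
//
// Generative order (defines where insert slots sit):
//   ROOT:     [L-slot] child [R-slot]
//   SINGLE_L: x_l [L-slot] child
//   SINGLE_R: child [R-slot] x_r
//   PAIR:     x_l [L-slot] child [R-slot] x_r
//   BIF:      left [L-slot] right
//   END:      [L-slot]
//
// A slot with k inserted residues costs log2(1-po) if k==0, otherwise
// log2(po) + (k-1)*log2(pe) + log2(1-pe); inserted residues emit at background
// (0 bits).  Sequence is encoded 0..3 = A,C,G,T, 4 = N/ambiguity.  N emits at
// 0 bits; a pair with one N side scores the marginal of the concrete side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEG = -1e30;
static const double TB_EPS = 1e-6;

struct CModel {
  int n, clen, root;
  std::vector<int> ntype, lcol, rcol, child, bl, br;
  NumericMatrix tr;       // n x 4: match, delete, left_only, right_only (log2 probs)
  NumericMatrix insl;     // n x 2: po, pe  (po < 0 => slot absent)
  NumericMatrix insr;     // n x 2
  NumericMatrix esingle;  // clen x 4 (marginals for pair columns)
  NumericMatrix epair;    // n x 16 (PAIR rows only)
};

struct Tables {
  int L;                  // sequence length
  int W;                  // row width = L+1
  std::vector<std::vector<double> > S, T5, T3;
  inline int idx(int a, int b) const { return a * W + b; }
};

static CModel unpack_model(const List &m) {
  CModel cm;
  cm.n = as<int>(m["n"]);
  cm.clen = as<int>(m["clen"]);
  cm.root = as<int>(m["root"]) - 1;
  cm.ntype = as<std::vector<int> >(m["ntype"]);
  cm.lcol = as<std::vector<int> >(m["lcol"]);
  cm.rcol = as<std::vector<int> >(m["rcol"]);
  cm.child = as<std::vector<int> >(m["child"]);
  cm.bl = as<std::vector<int> >(m["bl"]);
  cm.br = as<std::vector<int> >(m["br"]);
  // R side is 1-based; convert node references (0 = none -> -1)
  for (int i = 0; i < cm.n; ++i) {
    cm.child[i] -= 1; cm.bl[i] -= 1; cm.br[i] -= 1;
  }
  cm.tr = as<NumericMatrix>(m["tr"]);
  cm.insl = as<NumericMatrix>(m["insl"]);
  cm.insr = as<NumericMatrix>(m["insr"]);
  cm.esingle = as<NumericMatrix>(m["esingle"]);
  cm.epair = as<NumericMatrix>(m["epair"]);
  return cm;
}

static inline double em1(const CModel &cm, int col, int x) {
  if (x >= 4) return 0.0;
  return cm.esingle(col - 1, x);
}

static inline double em2(const CModel &cm, int node, int x, int y) {
  if (x >= 4 && y >= 4) return 0.0;
  if (x >= 4) return cm.esingle(cm.rcol[node] - 1, y);
  if (y >= 4) return cm.esingle(cm.lcol[node] - 1, x);
  // pair tables are stored column-major: left residue varies fastest
  return cm.epair(node, x + 4 * y);
}

// ---- insert-slot transforms -------------------------------------------------

// out(a,b) = max over k>=0 inserts consumed on the LEFT of the child segment
static void wl_transform(const std::vector<double> &C, std::vector<double> &out,
                         double po, double pe, int L) {
  int W = L + 1;
  if (po < 0) { out = C; return; }
  double lpo = std::log2(po), l0 = std::log2(1.0 - po);
  double lpe = std::log2(pe), l1e = std::log2(1.0 - pe);
  out.assign(C.size(), NEG);
  for (int b = 0; b <= L; ++b) {
    double J = NEG;  // J(a,b) = max_{k>=1} (k-1)*lpe + C(a+k,b)
    for (int a = b; a >= 0; --a) {
      double v = l0 + C[a * W + b];
      if (J > NEG / 2) {
        double w = lpo + l1e + J;
        if (w > v) v = w;
      }
      out[a * W + b] = v;
      double nj = C[a * W + b];
      if (J > NEG / 2 && lpe + J > nj) nj = lpe + J;
      J = nj;
    }
  }
}

// out(a,b) = max over k>=0 inserts consumed on the RIGHT of the child segment
static void wr_transform(const std::vector<double> &C, std::vector<double> &out,
                         double po, double pe, int L) {
  int W = L + 1;
  if (po < 0) { out = C; return; }
  double lpo = std::log2(po), l0 = std::log2(1.0 - po);
  double lpe = std::log2(pe), l1e = std::log2(1.0 - pe);
  out.assign(C.size(), NEG);
  for (int a = 0; a <= L; ++a) {
    double K = NEG;  // K(a,b) = max_{k>=1} (k-1)*lpe + C(a,b-k)
    for (int b = a; b <= L; ++b) {
      double v = l0 + C[a * W + b];
      if (K > NEG / 2) {
        double w = lpo + l1e + K;
        if (w > v) v = w;
      }
      out[a * W + b] = v;
      double nk = C[a * W + b];
      if (K > NEG / 2 && lpe + K > nk) nk = lpe + K;
      K = nk;
    }
  }
}

static inline double slot_cost(double po, double pe, int k) {
  if (po < 0) return (k == 0) ? 0.0 : NEG;
  if (k == 0) return std::log2(1.0 - po);
  return std::log2(po) + (k - 1) * std::log2(pe) + std::log2(1.0 - pe);
}

// single-cell evaluation of a left transform (used by traceback)
static double wl_cell(const std::vector<double> &C, double po, double pe,
                      int a, int b, int W, int *karg) {
  double best = NEG; int kb = 0;
  int maxk = b - a;
  if (po < 0) maxk = 0;
  for (int k = 0; k <= maxk; ++k) {
    double v = slot_cost(po, pe, k) + C[(a + k) * W + b];
    if (v > best + TB_EPS) { best = v; kb = k; }
  }
  if (karg) *karg = kb;
  return best;
}

static double wr_cell(const std::vector<double> &C, double po, double pe,
                      int a, int b, int W, int *karg) {
  double best = NEG; int kb = 0;
  int maxk = b - a;
  if (po < 0) maxk = 0;
  for (int k = 0; k <= maxk; ++k) {
    double v = slot_cost(po, pe, k) + C[a * W + (b - k)];
    if (v > best + TB_EPS) { best = v; kb = k; }
  }
  if (karg) *karg = kb;
  return best;
}

// combined L+R slots around a child (PAIR, ROOT)
static double wlr_cell(const std::vector<double> &C, double pol, double pel,
                       double por, double per, int a, int b, int W,
                       int *k1arg, int *k2arg) {
  double best = NEG; int k1b = 0, k2b = 0;
  int maxk1 = (pol < 0) ? 0 : (b - a);
  for (int k1 = 0; k1 <= maxk1; ++k1) {
    double c1 = slot_cost(pol, pel, k1);
    int maxk2 = (por < 0) ? 0 : (b - a - k1);
    for (int k2 = 0; k2 <= maxk2; ++k2) {
      double v = c1 + slot_cost(por, per, k2) + C[(a + k1) * W + (b - k2)];
      if (v > best + TB_EPS) { best = v; k1b = k1; k2b = k2; }
    }
  }
  if (k1arg) *k1arg = k1b;
  if (k2arg) *k2arg = k2b;
  return best;
}

// ---- forward DP -------------------------------------------------------------

static void compute_node(const CModel &cm, const std::vector<int> &s, Tables &tb,
                         int v) {
  int L = tb.L, W = tb.W;
  std::vector<double> &S = tb.S[v];
  S.assign((size_t)W * W, NEG);
  int ty = cm.ntype[v];
  std::vector<double> tmp, tmp2;

  if (ty == 5) {  // END
    double po = cm.insl(v, 0), pe = cm.insl(v, 1);
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b)
        S[a * W + b] = slot_cost(po, pe, b - a);
    return;
  }
  if (ty == 1) {  // SINGLE_L
    int c = cm.child[v];
    wl_transform(tb.S[c], tmp, cm.insl(v, 0), cm.insl(v, 1), L);
    double tm = cm.tr(v, 0), td = cm.tr(v, 1);
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = td + tmp[a * W + b];
        if (a < b) {
          double m = tm + em1(cm, cm.lcol[v], s[a]) + tmp[(a + 1) * W + b];
          if (m > best) best = m;
        }
        S[a * W + b] = best;
      }
    return;
  }
  if (ty == 2) {  // SINGLE_R
    int c = cm.child[v];
    wr_transform(tb.S[c], tmp, cm.insr(v, 0), cm.insr(v, 1), L);
    double tm = cm.tr(v, 0), td = cm.tr(v, 1);
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = td + tmp[a * W + b];
        if (a < b) {
          double m = tm + em1(cm, cm.rcol[v], s[b - 1]) + tmp[a * W + (b - 1)];
          if (m > best) best = m;
        }
        S[a * W + b] = best;
      }
    return;
  }
  if (ty == 3) {  // PAIR
    int c = cm.child[v];
    wr_transform(tb.S[c], tmp2, cm.insr(v, 0), cm.insr(v, 1), L);
    wl_transform(tmp2, tmp, cm.insl(v, 0), cm.insl(v, 1), L);
    double tmp_m = cm.tr(v, 0), tmp_d = cm.tr(v, 1);
    double tmp_lo = cm.tr(v, 2), tmp_ro = cm.tr(v, 3);
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = tmp_d + tmp[a * W + b];
        if (a < b) {
          double lo = tmp_lo + em1(cm, cm.lcol[v], s[a]) + tmp[(a + 1) * W + b];
          if (lo > best) best = lo;
          double ro = tmp_ro + em1(cm, cm.rcol[v], s[b - 1]) + tmp[a * W + (b - 1)];
          if (ro > best) best = ro;
          if (b - a >= 2) {
            double mp = tmp_m + em2(cm, v, s[a], s[b - 1]) +
                        tmp[(a + 1) * W + (b - 1)];
            if (mp > best) best = mp;
          }
        }
        S[a * W + b] = best;
      }
    return;
  }
  if (ty == 4) {  // BIF (mid slot on left edge of right child)
    int l = cm.bl[v], r = cm.br[v];
    wl_transform(tb.S[r], tmp, cm.insl(v, 0), cm.insl(v, 1), L);
    const std::vector<double> &SL = tb.S[l];
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = NEG;
        for (int m = a; m <= b; ++m) {
          double v2 = SL[a * W + m] + tmp[m * W + b];
          if (v2 > best) best = v2;
        }
        S[a * W + b] = best;
      }
    return;
  }
  // ROOT
  int c = cm.child[v];
  wr_transform(tb.S[c], tmp2, cm.insr(v, 0), cm.insr(v, 1), L);
  wl_transform(tmp2, tmp, cm.insl(v, 0), cm.insl(v, 1), L);
  S = tmp;
}

// truncation layers -----------------------------------------------------------

static void compute_node_t5(const CModel &cm, const std::vector<int> &s,
                            Tables &tb, int v) {
  int L = tb.L, W = tb.W;
  std::vector<double> &T = tb.T5[v];
  T.assign((size_t)W * W, NEG);
  int ty = cm.ntype[v];
  std::vector<double> tmp, U;

  if (ty == 5) return;  // END: no columns to truncate
  if (ty == 1) {        // SINGLE_L: its column is free-deleted
    int c = cm.child[v];
    const std::vector<double> &Sc = tb.S[c], &Tc = tb.T5[c];
    for (size_t i = 0; i < T.size(); ++i)
      T[i] = std::max(Tc[i], Sc[i]);
    return;
  }
  if (ty == 2) {  // SINGLE_R behaves normally over a truncated child
    int c = cm.child[v];
    wr_transform(tb.T5[c], tmp, cm.insr(v, 0), cm.insr(v, 1), L);
    double tm = cm.tr(v, 0), td = cm.tr(v, 1);
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = td + tmp[a * W + b];
        if (a < b) {
          double m = tm + em1(cm, cm.rcol[v], s[b - 1]) + tmp[a * W + (b - 1)];
          if (m > best) best = m;
        }
        T[a * W + b] = best;
      }
    return;
  }
  if (ty == 3) {  // PAIR: left side free, right column emitted as marginal
    int c = cm.child[v];
    const std::vector<double> &Sc = tb.S[c], &Tc = tb.T5[c];
    U.resize(Sc.size());
    for (size_t i = 0; i < U.size(); ++i) U[i] = std::max(Tc[i], Sc[i]);
    wr_transform(U, tmp, cm.insr(v, 0), cm.insr(v, 1), L);
    for (int a = 0; a <= L; ++a)
      for (int b = a + 1; b <= L; ++b)
        T[a * W + b] = em1(cm, cm.rcol[v], s[b - 1]) + tmp[a * W + (b - 1)];
    return;
  }
  if (ty == 4) {  // BIF
    int l = cm.bl[v], r = cm.br[v];
    wl_transform(tb.S[r], tmp, cm.insl(v, 0), cm.insl(v, 1), L);
    const std::vector<double> &T5l = tb.T5[l];
    const std::vector<double> &T5r = tb.T5[r], &Sr = tb.S[r];
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = std::max(T5r[a * W + b], Sr[a * W + b]);
        for (int m = a; m <= b; ++m) {
          double v2 = T5l[a * W + m] + tmp[m * W + b];
          if (v2 > best) best = v2;
        }
        T[a * W + b] = best;
      }
    return;
  }
  // ROOT: not used at top level in truncated mode
}

static void compute_node_t3(const CModel &cm, const std::vector<int> &s,
                            Tables &tb, int v) {
  int L = tb.L, W = tb.W;
  std::vector<double> &T = tb.T3[v];
  T.assign((size_t)W * W, NEG);
  int ty = cm.ntype[v];
  std::vector<double> tmp, U;

  if (ty == 5) return;
  if (ty == 2) {  // SINGLE_R: its column is free-deleted
    int c = cm.child[v];
    const std::vector<double> &Sc = tb.S[c], &Tc = tb.T3[c];
    for (size_t i = 0; i < T.size(); ++i)
      T[i] = std::max(Tc[i], Sc[i]);
    return;
  }
  if (ty == 1) {
    int c = cm.child[v];
    wl_transform(tb.T3[c], tmp, cm.insl(v, 0), cm.insl(v, 1), L);
    double tm = cm.tr(v, 0), td = cm.tr(v, 1);
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = td + tmp[a * W + b];
        if (a < b) {
          double m = tm + em1(cm, cm.lcol[v], s[a]) + tmp[(a + 1) * W + b];
          if (m > best) best = m;
        }
        T[a * W + b] = best;
      }
    return;
  }
  if (ty == 3) {  // PAIR: right side free, left column emitted as marginal
    int c = cm.child[v];
    const std::vector<double> &Sc = tb.S[c], &Tc = tb.T3[c];
    U.resize(Sc.size());
    for (size_t i = 0; i < U.size(); ++i) U[i] = std::max(Tc[i], Sc[i]);
    wl_transform(U, tmp, cm.insl(v, 0), cm.insl(v, 1), L);
    for (int a = 0; a <= L; ++a)
      for (int b = a + 1; b <= L; ++b)
        T[a * W + b] = em1(cm, cm.lcol[v], s[a]) + tmp[(a + 1) * W + b];
    return;
  }
  if (ty == 4) {
    int l = cm.bl[v], r = cm.br[v];
    wl_transform(tb.T3[r], tmp, cm.insl(v, 0), cm.insl(v, 1), L);
    const std::vector<double> &Sl = tb.S[l];
    const std::vector<double> &T3l = tb.T3[l];
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b) {
        double best = std::max(T3l[a * W + b], Sl[a * W + b]);
        for (int m = a; m <= b; ++m) {
          double v2 = Sl[a * W + m] + tmp[m * W + b];
          if (v2 > best) best = v2;
        }
        T[a * W + b] = best;
      }
    return;
  }
}

// post-order node list
static void postorder(const CModel &cm, int v, std::vector<int> &out) {
  int ty = cm.ntype[v];
  if (ty == 4) {
    postorder(cm, cm.bl[v], out);
    postorder(cm, cm.br[v], out);
  } else if (ty != 5) {
    postorder(cm, cm.child[v], out);
  }
  out.push_back(v);
}

// ---- traceback --------------------------------------------------------------

struct TBCtx {
  const CModel *cm;
  const std::vector<int> *s;
  Tables *tb;
  std::vector<int> colpos;  // per consensus column: 0-based pos, -1 del, -2 trunc
};

static void mark_free(TBCtx &ctx, int v) {
  const CModel &cm = *ctx.cm;
  int ty = cm.ntype[v];
  if (cm.lcol[v] > 0) ctx.colpos[cm.lcol[v] - 1] = -2;
  if (cm.rcol[v] > 0) ctx.colpos[cm.rcol[v] - 1] = -2;
  if (ty == 4) { mark_free(ctx, cm.bl[v]); mark_free(ctx, cm.br[v]); }
  else if (ty != 5) mark_free(ctx, cm.child[v]);
}

static void tb_node(TBCtx &ctx, int v, int a, int b, int layer);

// descend through L (and possibly R) slots into child table `layer`
static void tb_descend_lr(TBCtx &ctx, int child, int a, int b,
                          double pol, double pel, double por, double per,
                          int layer) {
  int W = ctx.tb->W;
  const std::vector<double> &C =
      (layer == 0) ? ctx.tb->S[child] : (layer == 5 ? ctx.tb->T5[child]
                                                     : ctx.tb->T3[child]);
  int k1 = 0, k2 = 0;
  wlr_cell(C, pol, pel, por, per, a, b, W, &k1, &k2);
  tb_node(ctx, child, a + k1, b - k2, layer);
}

// descend where the child cell value is max(T5, S) (or max(T3, S))
static void tb_descend_lr_u(TBCtx &ctx, int child, int a, int b,
                            double pol, double pel, double por, double per,
                            int tlayer) {
  int W = ctx.tb->W;
  const std::vector<double> &Sc = ctx.tb->S[child];
  const std::vector<double> &Tc =
      (tlayer == 5) ? ctx.tb->T5[child] : ctx.tb->T3[child];
  std::vector<double> U(Sc.size());
  for (size_t i = 0; i < U.size(); ++i) U[i] = std::max(Tc[i], Sc[i]);
  int k1 = 0, k2 = 0;
  wlr_cell(U, pol, pel, por, per, a, b, W, &k1, &k2);
  int aa = a + k1, bb = b - k2;
  if (Sc[aa * W + bb] + TB_EPS >= Tc[aa * W + bb])
    tb_node(ctx, child, aa, bb, 0);
  else {
    // the free spine continues into the child but the child subtree may have
    // no explicit free marks beyond what tb_node sets
    tb_node(ctx, child, aa, bb, tlayer);
  }
}

static void tb_node(TBCtx &ctx, int v, int a, int b, int layer) {
  const CModel &cm = *ctx.cm;
  const std::vector<int> &s = *ctx.s;
  Tables &tb = *ctx.tb;
  int W = tb.W;
  int ty = cm.ntype[v];
  const std::vector<double> &T =
      (layer == 0) ? tb.S[v] : (layer == 5 ? tb.T5[v] : tb.T3[v]);
  double target = T[a * W + b];

  if (ty == 5) return;  // END: residues (if any) are inserts

  if (layer == 0) {
    if (ty == 0) {  // ROOT
      tb_descend_lr(ctx, cm.child[v], a, b, cm.insl(v, 0), cm.insl(v, 1),
                    cm.insr(v, 0), cm.insr(v, 1), 0);
      return;
    }
    if (ty == 1) {
      double tm = cm.tr(v, 0), td = cm.tr(v, 1);
      const std::vector<double> &C = tb.S[cm.child[v]];
      if (a < b) {
        double m = tm + em1(cm, cm.lcol[v], s[a]) +
                   wl_cell(C, cm.insl(v, 0), cm.insl(v, 1), a + 1, b, W, NULL);
        if (std::fabs(m - target) < TB_EPS) {
          ctx.colpos[cm.lcol[v] - 1] = a;
          tb_descend_lr(ctx, cm.child[v], a + 1, b, cm.insl(v, 0),
                        cm.insl(v, 1), -1, -1, 0);
          return;
        }
      }
      (void)td;
      ctx.colpos[cm.lcol[v] - 1] = -1;
      tb_descend_lr(ctx, cm.child[v], a, b, cm.insl(v, 0), cm.insl(v, 1), -1,
                    -1, 0);
      return;
    }
    if (ty == 2) {
      double tm = cm.tr(v, 0);
      const std::vector<double> &C = tb.S[cm.child[v]];
      if (a < b) {
        double m = tm + em1(cm, cm.rcol[v], s[b - 1]) +
                   wr_cell(C, cm.insr(v, 0), cm.insr(v, 1), a, b - 1, W, NULL);
        if (std::fabs(m - target) < TB_EPS) {
          ctx.colpos[cm.rcol[v] - 1] = b - 1;
          tb_descend_lr(ctx, cm.child[v], a, b - 1, -1, -1, cm.insr(v, 0),
                        cm.insr(v, 1), 0);
          return;
        }
      }
      ctx.colpos[cm.rcol[v] - 1] = -1;
      tb_descend_lr(ctx, cm.child[v], a, b, -1, -1, cm.insr(v, 0),
                    cm.insr(v, 1), 0);
      return;
    }
    if (ty == 3) {
      const std::vector<double> &C = tb.S[cm.child[v]];
      double pol = cm.insl(v, 0), pel = cm.insl(v, 1);
      double por = cm.insr(v, 0), per = cm.insr(v, 1);
      int li = cm.lcol[v] - 1, ri = cm.rcol[v] - 1;
      if (b - a >= 2) {
        double mp = cm.tr(v, 0) + em2(cm, v, s[a], s[b - 1]) +
                    wlr_cell(C, pol, pel, por, per, a + 1, b - 1, W, NULL, NULL);
        if (std::fabs(mp - target) < TB_EPS) {
          ctx.colpos[li] = a; ctx.colpos[ri] = b - 1;
          tb_descend_lr(ctx, cm.child[v], a + 1, b - 1, pol, pel, por, per, 0);
          return;
        }
      }
      if (a < b) {
        double lo = cm.tr(v, 2) + em1(cm, cm.lcol[v], s[a]) +
                    wlr_cell(C, pol, pel, por, per, a + 1, b, W, NULL, NULL);
        if (std::fabs(lo - target) < TB_EPS) {
          ctx.colpos[li] = a; ctx.colpos[ri] = -1;
          tb_descend_lr(ctx, cm.child[v], a + 1, b, pol, pel, por, per, 0);
          return;
        }
        double ro = cm.tr(v, 3) + em1(cm, cm.rcol[v], s[b - 1]) +
                    wlr_cell(C, pol, pel, por, per, a, b - 1, W, NULL, NULL);
        if (std::fabs(ro - target) < TB_EPS) {
          ctx.colpos[li] = -1; ctx.colpos[ri] = b - 1;
          tb_descend_lr(ctx, cm.child[v], a, b - 1, pol, pel, por, per, 0);
          return;
        }
      }
      ctx.colpos[li] = -1; ctx.colpos[ri] = -1;
      tb_descend_lr(ctx, cm.child[v], a, b, pol, pel, por, per, 0);
      return;
    }
    // BIF
    {
      int l = cm.bl[v], r = cm.br[v];
      const std::vector<double> &SL = tb.S[l];
      const std::vector<double> &SR = tb.S[r];
      for (int m = a; m <= b; ++m) {
        double val = SL[a * W + m] +
                     wl_cell(SR, cm.insl(v, 0), cm.insl(v, 1), m, b, W, NULL);
        if (std::fabs(val - target) < TB_EPS) {
          tb_node(ctx, l, a, m, 0);
          tb_descend_lr(ctx, r, m, b, cm.insl(v, 0), cm.insl(v, 1), -1, -1, 0);
          return;
        }
      }
      Rcpp::stop("traceback failure at BIF");
    }
  }

  if (layer == 5) {
    if (ty == 1) {  // free column
      ctx.colpos[cm.lcol[v] - 1] = -2;
      int c = cm.child[v];
      if (tb.S[c][a * W + b] + TB_EPS >= tb.T5[c][a * W + b])
        tb_node(ctx, c, a, b, 0);
      else tb_node(ctx, c, a, b, 5);
      return;
    }
    if (ty == 2) {
      double tm = cm.tr(v, 0);
      const std::vector<double> &C = tb.T5[cm.child[v]];
      if (a < b) {
        double m = tm + em1(cm, cm.rcol[v], s[b - 1]) +
                   wr_cell(C, cm.insr(v, 0), cm.insr(v, 1), a, b - 1, W, NULL);
        if (std::fabs(m - target) < TB_EPS) {
          ctx.colpos[cm.rcol[v] - 1] = b - 1;
          tb_descend_lr(ctx, cm.child[v], a, b - 1, -1, -1, cm.insr(v, 0),
                        cm.insr(v, 1), 5);
          return;
        }
      }
      ctx.colpos[cm.rcol[v] - 1] = -1;
      tb_descend_lr(ctx, cm.child[v], a, b, -1, -1, cm.insr(v, 0),
                    cm.insr(v, 1), 5);
      return;
    }
    if (ty == 3) {
      ctx.colpos[cm.lcol[v] - 1] = -2;
      ctx.colpos[cm.rcol[v] - 1] = b - 1;
      tb_descend_lr_u(ctx, cm.child[v], a, b - 1, -1, -1, cm.insr(v, 0),
                      cm.insr(v, 1), 5);
      return;
    }
    if (ty == 4) {
      int l = cm.bl[v], r = cm.br[v];
      if (std::fabs(tb.S[r][a * W + b] - target) < TB_EPS) {
        mark_free(ctx, l);
        tb_node(ctx, r, a, b, 0);
        return;
      }
      if (std::fabs(tb.T5[r][a * W + b] - target) < TB_EPS) {
        mark_free(ctx, l);
        tb_node(ctx, r, a, b, 5);
        return;
      }
      for (int m = a; m <= b; ++m) {
        double val = tb.T5[l][a * W + m] +
                     wl_cell(tb.S[r], cm.insl(v, 0), cm.insl(v, 1), m, b, W, NULL);
        if (std::fabs(val - target) < TB_EPS) {
          tb_node(ctx, l, a, m, 5);
          tb_descend_lr(ctx, r, m, b, cm.insl(v, 0), cm.insl(v, 1), -1, -1, 0);
          return;
        }
      }
      Rcpp::stop("traceback failure at BIF/T5");
    }
    return;
  }

  // layer == 3 (T3)
  if (ty == 2) {
    ctx.colpos[cm.rcol[v] - 1] = -2;
    int c = cm.child[v];
    if (tb.S[c][a * W + b] + TB_EPS >= tb.T3[c][a * W + b])
      tb_node(ctx, c, a, b, 0);
    else tb_node(ctx, c, a, b, 3);
    return;
  }
  if (ty == 1) {
    double tm = cm.tr(v, 0);
    const std::vector<double> &C = tb.T3[cm.child[v]];
    if (a < b) {
      double m = tm + em1(cm, cm.lcol[v], s[a]) +
                 wl_cell(C, cm.insl(v, 0), cm.insl(v, 1), a + 1, b, W, NULL);
      if (std::fabs(m - target) < TB_EPS) {
        ctx.colpos[cm.lcol[v] - 1] = a;
        tb_descend_lr(ctx, cm.child[v], a + 1, b, cm.insl(v, 0), cm.insl(v, 1),
                      -1, -1, 3);
        return;
      }
    }
    ctx.colpos[cm.lcol[v] - 1] = -1;
    tb_descend_lr(ctx, cm.child[v], a, b, cm.insl(v, 0), cm.insl(v, 1), -1, -1,
                  3);
    return;
  }
  if (ty == 3) {
    ctx.colpos[cm.rcol[v] - 1] = -2;
    ctx.colpos[cm.lcol[v] - 1] = a;
    tb_descend_lr_u(ctx, cm.child[v], a + 1, b, cm.insl(v, 0), cm.insl(v, 1),
                    -1, -1, 3);
    return;
  }
  if (ty == 4) {
    int l = cm.bl[v], r = cm.br[v];
    if (std::fabs(tb.S[l][a * W + b] - target) < TB_EPS) {
      mark_free(ctx, r);
      tb_node(ctx, l, a, b, 0);
      return;
    }
    if (std::fabs(tb.T3[l][a * W + b] - target) < TB_EPS) {
      mark_free(ctx, r);
      tb_node(ctx, l, a, b, 3);
      return;
    }
    for (int m = a; m <= b; ++m) {
      double val = tb.S[l][a * W + m] +
                   wl_cell(tb.T3[r], cm.insl(v, 0), cm.insl(v, 1), m, b, W, NULL);
      if (std::fabs(val - target) < TB_EPS) {
        tb_node(ctx, l, a, m, 0);
        tb_descend_lr(ctx, r, m, b, cm.insl(v, 0), cm.insl(v, 1), -1, -1, 3);
        return;
      }
    }
    Rcpp::stop("traceback failure at BIF/T3");
  }
}

// [[Rcpp::export]]
List cm_dp(List model, IntegerVector seq, int mode, bool allow_t5,
           bool allow_t3, bool want_parse) {
  CModel cm = unpack_model(model);
  int L = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  Tables tb;
  tb.L = L; tb.W = L + 1;
  tb.S.resize(cm.n);
  std::vector<int> order;
  postorder(cm, cm.root, order);
  for (size_t i = 0; i < order.size(); ++i) compute_node(cm, s, tb, order[i]);

  bool use_trunc = (mode == 1) && (allow_t5 || allow_t3);
  if (use_trunc) {
    if (allow_t5) {
      tb.T5.resize(cm.n);
      for (size_t i = 0; i < order.size(); ++i)
        compute_node_t5(cm, s, tb, order[i]);
    }
    if (allow_t3) {
      tb.T3.resize(cm.n);
      for (size_t i = 0; i < order.size(); ++i)
        compute_node_t3(cm, s, tb, order[i]);
    }
  }

  double best; int ba = 0, bb = L; int blayer = 0;
  if (mode == 0) {  // global
    best = tb.S[cm.root][0 * tb.W + L];
  } else {
    int rc = cm.child[cm.root];
    best = NEG;
    const std::vector<double> &S = tb.S[rc];
    for (int a = 0; a <= L; ++a)
      for (int b = a; b <= L; ++b)
        if (S[a * tb.W + b] > best) { best = S[a * tb.W + b]; ba = a; bb = b; }
    if (allow_t5 && !tb.T5.empty()) {
      const std::vector<double> &T = tb.T5[rc];
      for (int b = 0; b <= L; ++b)
        if (T[0 * tb.W + b] > best) { best = T[b]; ba = 0; bb = b; blayer = 5; }
    }
    if (allow_t3 && !tb.T3.empty()) {
      const std::vector<double> &T = tb.T3[rc];
      for (int a = 0; a <= L; ++a)
        if (T[a * tb.W + L] > best) {
          best = T[a * tb.W + L]; ba = a; bb = L; blayer = 3;
        }
    }
  }

  List out = List::create(
      _["score"] = best, _["begin"] = ba, _["end"] = bb,
      _["trunc5"] = (blayer == 5), _["trunc3"] = (blayer == 3));
  if (want_parse && best > NEG / 2) {
    TBCtx ctx; ctx.cm = &cm; ctx.s = &s; ctx.tb = &tb;
    ctx.colpos.assign(cm.clen, -1);
    if (mode == 0) tb_node(ctx, cm.root, 0, L, 0);
    else tb_node(ctx, cm.child[cm.root], ba, bb, blayer);
    out["colpos"] = wrap(ctx.colpos);
  }
  return out;
}

// ---- first-pass linear profile scan ----------------------------------------
//
// Fully local (Smith-Waterman style): the alignment may begin and end at any
// profile column and any sequence position, so genes whose ends or interior
// diverge from the profile still reach the cutoff on their best-matching
// stretch.  Per-column match/delete costs, affine insert slots between
// columns.  Returns all end positions with score >= cutoff together with the
// start of the optimal alignment ending there.

// [[Rcpp::export]]
List linear_scan(List profile, IntegerVector seq, double cutoff) {
  int C = as<int>(profile["clen"]);
  NumericMatrix e = as<NumericMatrix>(profile["e"]);  // C x 4
  NumericVector trM = as<NumericVector>(profile["trM"]);
  NumericVector trD = as<NumericVector>(profile["trD"]);
  NumericVector gpo = as<NumericVector>(profile["gpo"]);  // length C+1, [g]
  NumericVector gpe = as<NumericVector>(profile["gpe"]);
  int L = seq.size();
  // local begin/end cost: entry and exit columns drawn uniformly over the
  // C*(C+1)/2 choices, as in profile local alignment
  double local_pen = std::log2(2.0 / ((double)C * (C + 1)));

  std::vector<double> l0(C + 1), lpo(C + 1), lpe(C + 1), l1e(C + 1);
  for (int g = 0; g <= C; ++g) {
    if (g == 0 || g == C || gpo[g] < 0) {
      l0[g] = 0.0; lpo[g] = NEG; lpe[g] = NEG; l1e[g] = 0.0;
    } else {
      l0[g] = std::log2(1.0 - gpo[g]); lpo[g] = std::log2(gpo[g]);
      lpe[g] = std::log2(gpe[g]); l1e[g] = std::log2(1.0 - gpe[g]);
    }
  }

  std::vector<double> prevA(C + 1, NEG), prevB(C + 1, NEG), prevI(C + 1, NEG);
  std::vector<double> curA(C + 1, NEG), curB(C + 1, NEG), curI(C + 1, NEG);
  std::vector<int> psA(C + 1, 0), psB(C + 1, 0), psI(C + 1, 0);
  std::vector<int> csA(C + 1, 0), csB(C + 1, 0), csI(C + 1, 0);

  // row "i = -1": alignment may begin with deletions
  prevA[0] = 0.0; psA[0] = 0;
  for (int c = 1; c <= C; ++c) {
    prevB[c] = (c == 1 ? prevA[0] : prevA[c - 1]) + trD[c - 1];
    prevA[c] = prevB[c] + l0[c];
    psB[c] = 0; psA[c] = 0;
  }

  std::vector<int> ends; std::vector<int> starts; std::vector<double> scores;

  for (int i = 0; i < L; ++i) {
    int x = seq[i];
    prevA[0] = 0.0; psA[0] = i;  // fresh start: first match consumes pos i
    curA[0] = 0.0; csA[0] = i + 1;
    double rowbest = NEG; int rowstart = i;
    for (int c = 1; c <= C; ++c) {
      double emit = (x >= 4) ? 0.0 : e(c - 1, x);
      // local in the model: a match may open the alignment at any column
      double open = (prevA[c - 1] >= 0.0) ? prevA[c - 1] : 0.0;
      int open_s = (prevA[c - 1] >= 0.0) ? psA[c - 1] : i;
      double m = trM[c - 1] + emit + open;
      int ms = open_s;
      double d = trD[c - 1] + curA[c - 1];
      int ds = csA[c - 1];
      if (m >= d) { curB[c] = m; csB[c] = ms; }
      else        { curB[c] = d; csB[c] = ds; }
      // insert state in gap c
      double io = prevB[c] + lpo[c];
      double ie = prevI[c] + lpe[c];
      if (io >= ie) { curI[c] = io; csI[c] = psB[c]; }
      else          { curI[c] = ie; csI[c] = psI[c]; }
      double an = curB[c] + l0[c];
      double ai = curI[c] + l1e[c];
      if (c == C) { curA[c] = curB[c]; csA[c] = csB[c]; }
      else if (an >= ai) { curA[c] = an; csA[c] = csB[c]; }
      else               { curA[c] = ai; csA[c] = csI[c]; }
      // local in the model: the alignment may end at any column
      if (curB[c] > rowbest) { rowbest = curB[c]; rowstart = csB[c]; }
    }
    if (rowbest + local_pen >= cutoff) {
      ends.push_back(i + 1); starts.push_back(rowstart);
      scores.push_back(rowbest + local_pen);
    }
    std::swap(prevA, curA); std::swap(prevB, curB); std::swap(prevI, curI);
    std::swap(psA, csA); std::swap(psB, csB); std::swap(psI, csI);
  }
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                      _["score"] = wrap(scores));
}

// ---- fifth-order Markov generation ------------------------------------------

// [[Rcpp::export]]
IntegerVector markov_generate(NumericMatrix cond, NumericVector init, int order,
                              int len) {
  int nctx = cond.nrow();
  IntegerVector out(len);
  // initial context from `init` (distribution over order-mers)
  double u = R::unif_rand();
  int ctx = 0; double acc = 0.0;
  for (int i = 0; i < nctx; ++i) {
    acc += init[i];
    if (u <= acc) { ctx = i; break; }
    if (i == nctx - 1) ctx = i;
  }
  // emit the initial order-mer (most significant base first)
  int npre = std::min(order, len);
  for (int i = 0; i < npre; ++i) {
    int shift = 2 * (order - 1 - i);
    out[i] = (ctx >> shift) & 3;
  }
  int mask = nctx - 1;
  for (int i = order; i < len; ++i) {
    double u2 = R::unif_rand();
    int x = 3; double a2 = 0.0;
    for (int j = 0; j < 4; ++j) {
      a2 += cond(ctx, j);
      if (u2 <= a2) { x = j; break; }
    }
    out[i] = x;
    ctx = ((ctx << 2) | x) & mask;
  }
  return out;
}
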