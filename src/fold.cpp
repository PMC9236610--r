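// Nearest-neighbor secondary-structure engine: loop-decomposition energy
// evaluation, McCaskill partition function with outside pair probabilities,
// MFE folding with deterministic traceback, and stochastic Boltzmann sampling.
//
// Energy decomposition (kcal/mol):
//   hairpin(l)   = hairpin_base + loop_coef * log(l / 3)
//   internal(s)  = internal_base + internal_coef * log(s)        (s >= 1)
//   stack        = table lookup by (outer pair type, inner pair type)
//   multiloop    = ml_init + ml_branch * (branches + 1) + ml_unpaired * u
//   terminal_pen applied per AU/UA/GU/UG closing or branch pair
//   per-nucleotide reactivity pseudo-energy g[i] added for every paired i
// The DP restricts interior/bulge loops to <= maxloop unpaired nucleotides
// (standard search-space cap); energy evaluation itself scores any loop size.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int MIN_HP = 3;     // minimum hairpin loop length
static const double INF_E = 1e9;

struct Model {
  std::vector<double> stack; // 6x6 row-major [outer*6+inner]
  double hairpin_base, loop_coef;
  double internal_base, internal_coef;
  double ml_init, ml_branch, ml_unpaired;
  double terminal_pen;
  double RT;
  int maxloop;
};

static Model as_model(const List& m) {
  Model mod;
  NumericMatrix st = m["stack"];
  mod.stack.assign(36, 0.0);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) mod.stack[a * 6 + b] = st(a, b);
  mod.hairpin_base = as<double>(m["hairpin_base"]);
  mod.loop_coef = as<double>(m["loop_coef"]);
  mod.internal_base = as<double>(m["internal_base"]);
  mod.internal_coef = as<double>(m["internal_coef"]);
  mod.ml_init = as<double>(m["ml_init"]);
  mod.ml_branch = as<double>(m["ml_branch"]);
  mod.ml_unpaired = as<double>(m["ml_unpaired"]);
  mod.terminal_pen = as<double>(m["terminal_pen"]);
  mod.RT = as<double>(m["RT"]);
  mod.maxloop = as<int>(m["maxloop"]);
  return mod;
}

// bases: A=0, C=1, G=2, U=3
static inline int pairtype(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 1 && b == 2) return 2; // CG
  if (a == 2 && b == 1) return 3; // GC
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}
static inline double pen(const Model& m, int pt) {
  return (pt == 2 || pt == 3) ? 0.0 : m.terminal_pen; // CG/GC free
}
static inline double hairpinE(const Model& m, int l) {
  return m.hairpin_base + m.loop_coef * std::log((double)l / 3.0);
}
static inline double internalE(const Model& m, int s) {
  return m.internal_base + m.internal_coef * std::log((double)s);
}

// ---------------------------------------------------------------- energy ---

// [[Rcpp::export]]
double cpp_energy(IntegerVector seq, IntegerVector pairs, List model,
                  NumericVector g) {
  Model m = as_model(model);
  int n = seq.size();
  double E = 0.0;
  // loops closed by each pair (i, j), 1-based positions in `pairs`
  for (int i = 1; i <= n; ++i) {
    int j = pairs[i - 1];
    if (j <= i) continue;
    int pt0 = pairtype(seq[i - 1], seq[j - 1]);
    if (pt0 < 0) stop("non-complementary pair (%d,%d)", i, j);
    // scan interior of (i,j) for top-level branches
    int nb = 0, u = 0;
    int k1 = 0, l1 = 0;
    double branch_pen = 0.0;
    int k = i + 1;
    while (k < j) {
      int pk = pairs[k - 1];
      if (pk > k) {
        if (nb == 0) { k1 = k; l1 = pk; }
        ++nb;
        branch_pen += pen(m, pairtype(seq[k - 1], seq[pk - 1]));
        k = pk + 1;
      } else {
        ++u;
        ++k;
      }
    }
    if (nb == 0) {
      E += hairpinE(m, j - i - 1) + pen(m, pt0);
    } else if (nb == 1) {
      if (k1 == i + 1 && l1 == j - 1) {
        int pt1 = pairtype(seq[k1 - 1], seq[l1 - 1]);
        E += m.stack[pt0 * 6 + pt1];
      } else {
        int s = (k1 - i - 1) + (j - l1 - 1);
        E += internalE(m, s) + pen(m, pt0) +
             pen(m, pairtype(seq[k1 - 1], seq[l1 - 1]));
      }
    } else {
      E += m.ml_init + m.ml_branch * (nb + 1) + m.ml_unpaired * u +
           pen(m, pt0) + branch_pen;
    }
  }
  // exterior loop: per-branch terminal penalties
  {
    int k = 1;
    while (k <= n) {
      int pk = pairs[k - 1];
      if (pk > k) {
        E += pen(m, pairtype(seq[k - 1], seq[pk - 1]));
        k = pk + 1;
      } else ++k;
    }
  }
  // reactivity pseudo-energies for paired nucleotides
  for (int i = 1; i <= n; ++i)
    if (pairs[i - 1] > 0) E += g[i - 1];
  return E;
}

// [[Rcpp::export]]
NumericVector cpp_energy_batch(IntegerVector seq, IntegerMatrix pairs,
                               List model, NumericVector g) {
  int nr = pairs.nrow();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    IntegerVector p = pairs(r, _);
    out[r] = cpp_energy(seq, p, model, g);
  }
  return out;
}

// ----------------------------------------------------- partition function ---

struct PF {
  int n;
  Model m;
  std::vector<int> s;            // 0-based copy of sequence codes
  std::vector<double> g;         // pseudo-energies
  std::vector<double> qb, qm, qm1;
  std::vector<double> q5, q3;
  double beta;
  inline double& QB(int i, int j)  { return qb [i * (n + 2) + j]; }
  inline double& QM(int i, int j)  { return qm [i * (n + 2) + j]; }
  inline double& QM1(int i, int j) { return qm1[i * (n + 2) + j]; }
  inline double w(double E) const { return std::exp(-E * beta); }
  inline int pt(int i, int j) const { return pairtype(s[i - 1], s[j - 1]); }

  void fill(IntegerVector seq, List model, NumericVector gv) {
    m = as_model(model);
    n = seq.size();
    beta = 1.0 / m.RT;
    s.assign(n, 0);
    g.assign(n, 0.0);
    for (int i = 0; i < n; ++i) { s[i] = seq[i]; g[i] = gv[i]; }
    int sz = (n + 2) * (n + 2);
    qb.assign(sz, 0.0);
    qm.assign(sz, 0.0);
    qm1.assign(sz, 0.0);
    for (int len = MIN_HP + 2; len <= n; ++len) {
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        int pt0 = pt(i, j);
        if (pt0 >= 0) {
          double q = w(hairpinE(m, j - i - 1) + pen(m, pt0));
          // interior loops and stacks (interior size 0 = stack)
          for (int k = i + 1; k <= j - MIN_HP - 2 && k - i - 1 <= m.maxloop;
               ++k) {
            for (int l = j - 1; l > k + MIN_HP; --l) {
              int sizel = (k - i - 1) + (j - l - 1);
              if (sizel > m.maxloop) continue;
              double qkl = QB(k, l);
              if (qkl == 0.0) continue;
              if (sizel == 0) {
                q += w(m.stack[pt0 * 6 + pt(k, l)]) * qkl;
              } else {
                q += w(internalE(m, sizel) + pen(m, pt0) + pen(m, pt(k, l))) *
                     qkl;
              }
            }
          }
          // multiloop closing
          double qmulti = 0.0;
          for (int k = i + 2; k <= j - MIN_HP - 2; ++k)
            qmulti += QM(i + 1, k - 1) * QM1(k, j - 1);
          q += w(m.ml_init + m.ml_branch + pen(m, pt0)) * qmulti;
          QB(i, j) = q * w(g[i - 1] + g[j - 1]);
        }
        // qm1 / qm over [i, j] (any length >= MIN_HP+2 can host a branch)
      }
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        double q1 = 0.0;
        for (int l = i + MIN_HP + 1; l <= j; ++l)
          if (QB(i, l) > 0.0)
            q1 += QB(i, l) *
                  w(m.ml_branch + pen(m, pt(i, l)) + m.ml_unpaired * (j - l));
        QM1(i, j) = q1;
        double qq = 0.0;
        for (int k = i; k <= j - MIN_HP - 1; ++k) {
          double q1k = QM1(k, j);
          if (q1k == 0.0) continue;
          double lead = (k == i) ? 1.0 : w(m.ml_unpaired * (k - i));
          double more = (k > i) ? QM(i, k - 1) : 0.0;
          qq += (lead + more) * q1k;
        }
        QM(i, j) = qq;
      }
    }
    q5.assign(n + 2, 0.0);
    q5[0] = 1.0;
    for (int j = 1; j <= n; ++j) {
      double q = q5[j - 1];
      for (int i = 1; i <= j - MIN_HP - 1; ++i)
        if (QB(i, j) > 0.0)
          q += q5[i - 1] * QB(i, j) * w(pen(m, pt(i, j)));
      q5[j] = q;
      if (!std::isfinite(q)) stop("partition function overflow");
    }
    q3.assign(n + 3, 0.0);
    q3[n + 1] = 1.0;
    for (int i = n; i >= 1; --i) {
      double q = q3[i + 1];
      for (int j = i + MIN_HP + 1; j <= n; ++j)
        if (QB(i, j) > 0.0)
          q += QB(i, j) * w(pen(m, pt(i, j))) * q3[j + 1];
      q3[i] = q;
    }
  }
};

// [[Rcpp::export]]
List cpp_partition(IntegerVector seq, List model, NumericVector g,
                   bool pair_probs = true) {
  PF pf;
  pf.fill(seq, model, g);
  int n = pf.n;
  const Model& m = pf.m;
  double Z = pf.q5[n];
  NumericMatrix pr(n, n);
  if (pair_probs && n > MIN_HP + 1) {
    // exterior contributions
    for (int i = 1; i <= n; ++i)
      for (int j = i + MIN_HP + 1; j <= n; ++j)
        if (pf.QB(i, j) > 0.0)
          pr(i - 1, j - 1) = pf.QB(i, j) * pf.w(pen(m, pf.pt(i, j))) *
                             pf.q5[i - 1] * pf.q3[j + 1] / Z;
    // enclosed contributions, outer spans first
    for (int len = n; len >= MIN_HP + 4; --len) {
      for (int k = 1; k + len - 1 <= n; ++k) {
        int l = k + len - 1;
        double prkl = pr(k - 1, l - 1);
        if (prkl <= 0.0 || pf.QB(k, l) == 0.0) continue;
        double out = prkl / pf.QB(k, l) * pf.w(pf.g[k - 1] + pf.g[l - 1]);
        int ptkl = pf.pt(k, l);
        // stack + interior
        for (int i = k + 1; i <= l - MIN_HP - 2 && i - k - 1 <= m.maxloop;
             ++i) {
          for (int j = l - 1; j > i + MIN_HP; --j) {
            int sizel = (i - k - 1) + (l - j - 1);
            if (sizel > m.maxloop) continue;
            double qbij = pf.QB(i, j);
            if (qbij == 0.0) continue;
            double wloop;
            if (sizel == 0)
              wloop = pf.w(m.stack[ptkl * 6 + pf.pt(i, j)]);
            else
              wloop = pf.w(internalE(m, sizel) + pen(m, ptkl) +
                           pen(m, pf.pt(i, j)));
            pr(i - 1, j - 1) += out * qbij * wloop;
          }
        }
        // multiloop: (i,j) a branch inside (k,l) with >= 1 other branch
        double wml = pf.w(m.ml_init + 2.0 * m.ml_branch + pen(m, ptkl));
        for (int i = k + 1; i <= l - MIN_HP - 2; ++i) {
          for (int j = i + MIN_HP + 1; j <= l - 1; ++j) {
            double qbij = pf.QB(i, j);
            if (qbij == 0.0) continue;
            double left_m = (i - 1 >= k + 1) ? pf.QM(k + 1, i - 1) : 0.0;
            double right_m = (j + 1 <= l - 1) ? pf.QM(j + 1, l - 1) : 0.0;
            double left_u = pf.w(m.ml_unpaired * (i - 1 - k));
            double right_u = pf.w(m.ml_unpaired * (l - 1 - j));
            double combo = left_m * right_u + left_u * right_m +
                           left_m * right_m;
            if (combo == 0.0) continue;
            pr(i - 1, j - 1) += out * wml * pf.w(pen(m, pf.pt(i, j))) * qbij *
                                combo;
          }
        }
      }
    }
  }
  return List::create(_["logZ"] = std::log(Z), _["pair_prob"] = pr);
}

// ------------------------------------------------------------------- MFE ---

struct MFE {
  int n;
  Model m;
  std::vector<int> s;
  std::vector<double> g;
  std::vector<double> vb, vm, vm1, f5;
  inline double& VB(int i, int j)  { return vb [i * (n + 2) + j]; }
  inline double& VM(int i, int j)  { return vm [i * (n + 2) + j]; }
  inline double& VM1(int i, int j) { return vm1[i * (n + 2) + j]; }
  inline int pt(int i, int j) const { return pairtype(s[i - 1], s[j - 1]); }

  void fill(IntegerVector seq, List model, NumericVector gv) {
    m = as_model(model);
    n = seq.size();
    s.assign(n, 0);
    g.assign(n, 0.0);
    for (int i = 0; i < n; ++i) { s[i] = seq[i]; g[i] = gv[i]; }
    int sz = (n + 2) * (n + 2);
    vb.assign(sz, INF_E);
    vm.assign(sz, INF_E);
    vm1.assign(sz, INF_E);
    for (int len = MIN_HP + 2; len <= n; ++len) {
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        int pt0 = pt(i, j);
        if (pt0 >= 0) {
          double e = hairpinE(m, j - i - 1) + pen(m, pt0);
          for (int k = i + 1; k <= j - MIN_HP - 2 && k - i - 1 <= m.maxloop;
               ++k) {
            for (int l = j - 1; l > k + MIN_HP; --l) {
              int sizel = (k - i - 1) + (j - l - 1);
              if (sizel > m.maxloop) continue;
              double in = VB(k, l);
              if (in >= INF_E) continue;
              double cand;
              if (sizel == 0)
                cand = m.stack[pt0 * 6 + pt(k, l)] + in;
              else
                cand = internalE(m, sizel) + pen(m, pt0) +
                       pen(m, pt(k, l)) + in;
              if (cand < e) e = cand;
            }
          }
          for (int k = i + 2; k <= j - MIN_HP - 2; ++k) {
            double a = VM(i + 1, k - 1), b = VM1(k, j - 1);
            if (a >= INF_E || b >= INF_E) continue;
            double cand = m.ml_init + m.ml_branch + pen(m, pt0) + a + b;
            if (cand < e) e = cand;
          }
          VB(i, j) = e + g[i - 1] + g[j - 1];
        }
      }
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        double e1 = INF_E;
        for (int l = i + MIN_HP + 1; l <= j; ++l) {
          double in = VB(i, l);
          if (in >= INF_E) continue;
          double cand = in + m.ml_branch + pen(m, pt(i, l)) +
                        m.ml_unpaired * (j - l);
          if (cand < e1) e1 = cand;
        }
        VM1(i, j) = e1;
        double e = INF_E;
        for (int k = i; k <= j - MIN_HP - 1; ++k) {
          double in = VM1(k, j);
          if (in >= INF_E) continue;
          double lead = (k == i) ? 0.0 : m.ml_unpaired * (k - i);
          double cand = lead + in;
          if (k > i && VM(i, k - 1) < INF_E) {
            double alt = VM(i, k - 1) + in;
            if (alt < cand) cand = alt;
          }
          if (cand < e) e = cand;
        }
        VM(i, j) = e;
      }
    }
    f5.assign(n + 2, 0.0);
    for (int j = 1; j <= n; ++j) {
      double e = f5[j - 1];
      for (int i = 1; i <= j - MIN_HP - 1; ++i) {
        if (VB(i, j) >= INF_E) continue;
        double cand = f5[i - 1] + VB(i, j) + pen(m, pt(i, j));
        if (cand < e) e = cand;
      }
      f5[j] = e;
    }
  }
};

static const double TB_TOL = 1e-9;

// deterministic traceback: at ties within TB_TOL the alternatives are
// examined in a fixed order (unpaired / hairpin first, then by position)
static void trace_vb(MFE& mf, int i, int j, std::vector<int>& pairs);

static void trace_vm1(MFE& mf, int i, int j, std::vector<int>& pairs) {
  const Model& m = mf.m;
  double tgt = mf.VM1(i, j);
  for (int l = i + MIN_HP + 1; l <= j; ++l) {
    if (mf.VB(i, l) >= INF_E) continue;
    double cand = mf.VB(i, l) + m.ml_branch + pen(m, mf.pt(i, l)) +
                  m.ml_unpaired * (j - l);
    if (std::fabs(cand - tgt) < TB_TOL) { trace_vb(mf, i, l, pairs); return; }
  }
  stop("traceback failure (vm1)");
}

static void trace_vm(MFE& mf, int i, int j, std::vector<int>& pairs) {
  const Model& m = mf.m;
  double tgt = mf.VM(i, j);
  for (int k = i; k <= j - MIN_HP - 1; ++k) {
    double in = mf.VM1(k, j);
    if (in >= INF_E) continue;
    double lead = (k == i) ? 0.0 : m.ml_unpaired * (k - i);
    if (std::fabs(lead + in - tgt) < TB_TOL) {
      trace_vm1(mf, k, j, pairs);
      return;
    }
    if (k > i && mf.VM(i, k - 1) < INF_E &&
        std::fabs(mf.VM(i, k - 1) + in - tgt) < TB_TOL) {
      trace_vm(mf, i, k - 1, pairs);
      trace_vm1(mf, k, j, pairs);
      return;
    }
  }
  stop("traceback failure (vm)");
}

static void trace_vb(MFE& mf, int i, int j, std::vector<int>& pairs) {
  const Model& m = mf.m;
  pairs[i - 1] = j;
  pairs[j - 1] = i;
  int pt0 = mf.pt(i, j);
  double tgt = mf.VB(i, j) - mf.g[i - 1] - mf.g[j - 1];
  if (std::fabs(hairpinE(m, j - i - 1) + pen(m, pt0) - tgt) < TB_TOL) return;
  for (int k = i + 1; k <= j - MIN_HP - 2 && k - i - 1 <= m.maxloop; ++k) {
    for (int l = j - 1; l > k + MIN_HP; --l) {
      int sizel = (k - i - 1) + (j - l - 1);
      if (sizel > m.maxloop) continue;
      double in = mf.VB(k, l);
      if (in >= INF_E) continue;
      double cand = (sizel == 0)
          ? m.stack[pt0 * 6 + mf.pt(k, l)] + in
          : internalE(m, sizel) + pen(m, pt0) + pen(m, mf.pt(k, l)) + in;
      if (std::fabs(cand - tgt) < TB_TOL) { trace_vb(mf, k, l, pairs); return; }
    }
  }
  for (int k = i + 2; k <= j - MIN_HP - 2; ++k) {
    double a = mf.VM(i + 1, k - 1), b = mf.VM1(k, j - 1);
    if (a >= INF_E || b >= INF_E) continue;
    if (std::fabs(m.ml_init + m.ml_branch + pen(m, pt0) + a + b - tgt) <
        TB_TOL) {
      trace_vm(mf, i + 1, k - 1, pairs);
      trace_vm1(mf, k, j - 1, pairs);
      return;
    }
  }
  stop("traceback failure (vb)");
}

// [[Rcpp::export]]
List cpp_mfe(IntegerVector seq, List model, NumericVector g) {
  MFE mf;
  mf.fill(seq, model, g);
  int n = mf.n;
  std::vector<int> pairs(n, 0);
  int j = n;
  while (j > MIN_HP + 1) {
    if (std::fabs(mf.f5[j - 1] - mf.f5[j]) < TB_TOL) { --j; continue; }
    bool found = false;
    for (int i = 1; i <= j - MIN_HP - 1; ++i) {
      if (mf.VB(i, j) >= INF_E) continue;
      double cand = mf.f5[i - 1] + mf.VB(i, j) + pen(mf.m, mf.pt(i, j));
      if (std::fabs(cand - mf.f5[j]) < TB_TOL) {
        trace_vb(mf, i, j, pairs);
        j = i - 1;
        found = true;
        break;
      }
    }
    if (!found) stop("traceback failure (exterior)");
  }
  return List::create(_["energy"] = mf.f5[n],
                      _["pairs"] = IntegerVector(pairs.begin(), pairs.end()));
}

// ------------------------------------------------------ stochastic sample ---

static void strace_qb(PF& pf, int i, int j, std::vector<int>& pairs);

static void strace_qm1(PF& pf, int i, int j, std::vector<int>& pairs) {
  const Model& m = pf.m;
  double r = unif_rand() * pf.QM1(i, j);
  int last = -1;
  for (int l = i + MIN_HP + 1; l <= j; ++l) {
    if (pf.QB(i, l) == 0.0) continue;
    last = l;
    r -= pf.QB(i, l) *
         pf.w(m.ml_branch + pen(m, pf.pt(i, l)) + m.ml_unpaired * (j - l));
    if (r <= 0.0) { strace_qb(pf, i, l, pairs); return; }
  }
  if (last > 0) { strace_qb(pf, i, last, pairs); return; }
  stop("sampling failure (qm1)");
}

static void strace_qm(PF& pf, int i, int j, std::vector<int>& pairs) {
  const Model& m = pf.m;
  double r = unif_rand() * pf.QM(i, j);
  for (int k = i; k <= j - MIN_HP - 1; ++k) {
    double q1k = pf.QM1(k, j);
    if (q1k == 0.0) continue;
    double lead = (k == i) ? 1.0 : pf.w(m.ml_unpaired * (k - i));
    r -= lead * q1k;
    if (r <= 0.0) { strace_qm1(pf, k, j, pairs); return; }
    if (k > i && pf.QM(i, k - 1) > 0.0) {
      r -= pf.QM(i, k - 1) * q1k;
      if (r <= 0.0) {
        strace_qm(pf, i, k - 1, pairs);
        strace_qm1(pf, k, j, pairs);
        return;
      }
    }
  }
  stop("sampling failure (qm)");
}

static void strace_qb(PF& pf, int i, int j, std::vector<int>& pairs) {
  const Model& m = pf.m;
  pairs[i - 1] = j;
  pairs[j - 1] = i;
  int pt0 = pf.pt(i, j);
  double total = pf.QB(i, j) / pf.w(pf.g[i - 1] + pf.g[j - 1]);
  double r = unif_rand() * total;
  r -= pf.w(hairpinE(m, j - i - 1) + pen(m, pt0));
  if (r <= 0.0) return;
  for (int k = i + 1; k <= j - MIN_HP - 2 && k - i - 1 <= m.maxloop; ++k) {
    for (int l = j - 1; l > k + MIN_HP; --l) {
      int sizel = (k - i - 1) + (j - l - 1);
      if (sizel > m.maxloop) continue;
      double qkl = pf.QB(k, l);
      if (qkl == 0.0) continue;
      double wl = (sizel == 0)
          ? pf.w(m.stack[pt0 * 6 + pf.pt(k, l)])
          : pf.w(internalE(m, sizel) + pen(m, pt0) + pen(m, pf.pt(k, l)));
      r -= wl * qkl;
      if (r <= 0.0) { strace_qb(pf, k, l, pairs); return; }
    }
  }
  double wml = pf.w(m.ml_init + m.ml_branch + pen(m, pt0));
  for (int k = i + 2; k <= j - MIN_HP - 2; ++k) {
    double q = pf.QM(i + 1, k - 1) * pf.QM1(k, j - 1);
    if (q == 0.0) continue;
    r -= wml * q;
    if (r <= 0.0) {
      strace_qm(pf, i + 1, k - 1, pairs);
      strace_qm1(pf, k, j - 1, pairs);
      return;
    }
  }
  // floating-point remainder: fall back to hairpin
  return;
}

// [[Rcpp::export]]
IntegerMatrix cpp_sample(IntegerVector seq, List model, NumericVector g,
                         int n_samples) {
  PF pf;
  pf.fill(seq, model, g);
  int n = pf.n;
  const Model& m = pf.m;
  IntegerMatrix out(n_samples, n);
  for (int smp = 0; smp < n_samples; ++smp) {
    std::vector<int> pairs(n, 0);
    int j = n;
    while (j > MIN_HP + 1) {
      double r = unif_rand() * pf.q5[j];
      if (r <= pf.q5[j - 1]) { --j; continue; }
      r -= pf.q5[j - 1];
      bool done = false;
      for (int i = 1; i <= j - MIN_HP - 1; ++i) {
        if (pf.QB(i, j) == 0.0) continue;
        r -= pf.q5[i - 1] * pf.QB(i, j) * pf.w(pen(m, pf.pt(i, j)));
        if (r <= 0.0) {
          strace_qb(pf, i, j, pairs);
          j = i - 1;
          done = true;
          break;
        }
      }
      if (!done) --j; // numeric remainder: treat as unpaired
    }
    for (int c = 0; c < n; ++c) out(smp, c) = pairs[c];
  }
  return out;
}
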