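// Dense bounded-variable two-phase primal simplex.
//
// Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
// with finite or infinite bounds (|bound| >= 1e29 treated as infinite).
// Designed for the small, well-scaled LPs of flux balance analysis on
// curated networks (tens of metabolites x tens-to-hundreds of reactions),
// where determinism across repeated solves matters more than sparse speed.
//
// Pivoting: Dantzig pricing with smallest-index tie-break; falls back to
// Bland's rule after a stall threshold so cycling cannot occur. All rules
// are deterministic, so identical inputs give bit-identical solutions.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
const double BIGBND = 1e29;       // sentinel threshold for "infinite" bound
const double TOL_PIVOT = 1e-10;   // minimal usable pivot magnitude
const double TOL_COST = 1e-9;     // reduced-cost optimality tolerance
const double TOL_FEAS = 1e-9;     // phase-1 feasibility tolerance

enum Status { AT_LB = 0, AT_UB = 1, BASIC = 2, NB_FREE = 3 };

struct Simplex {
  int m, n, N;                    // rows, structural cols, total cols (n + m artificials)
  std::vector<double> T;          // m x N tableau, column-major: T[i + m*j] = (B^-1 A)[i,j]
  std::vector<double> lb, ub, cost, d, xB, xN;
  std::vector<int> basis;         // basis[i] = variable basic in row i
  std::vector<int> stat;          // per-variable Status
  std::vector<char> fixedcol;     // lb == ub: can never (re)enter the basis
  long iter, maxit;
  bool bland;

  // a fixed nonbasic column is never read again: skip it in pricing and
  // tableau updates (its entries are allowed to go stale)
  bool skip(int j) const { return fixedcol[j] && stat[j] != BASIC; }

  double &t(int i, int j) { return T[i + (size_t)m * j]; }

  double varValue(int j) const {
    if (stat[j] == BASIC) {
      for (int i = 0; i < m; ++i) if (basis[i] == j) return xB[i];
      return 0.0; // unreachable
    }
    return xN[j];
  }

  void refreshFixed() {
    fixedcol.assign(N, 0);
    for (int j = 0; j < N; ++j)
      if (ub[j] - lb[j] < 1e-14) fixedcol[j] = 1;
  }

  // recompute reduced costs d_j = cost_j - cost_B' T[,j]
  void priceAll() {
    for (int j = 0; j < N; ++j) {
      if (skip(j)) { d[j] = 0.0; continue; }
      double s = cost[j];
      for (int i = 0; i < m; ++i) {
        double cb = cost[basis[i]];
        if (cb != 0.0) s -= cb * t(i, j);
      }
      d[j] = s;
    }
  }

  // one simplex phase on current costs; returns 0 optimal, 2 unbounded, 3 iter limit
  int run() {
    long stall = 0;
    for (;;) {
      if (++iter > maxit) return 3;
      if (stall > 2L * (m + N)) bland = true;

      // ---- pricing (minimization) ----
      int enter = -1, dir = 0;
      double best = TOL_COST;
      for (int j = 0; j < N; ++j) {
        if (stat[j] == BASIC || skip(j)) continue;
        double viol = 0.0; int dj = 0;
        if (stat[j] == AT_LB && d[j] < -TOL_COST) { viol = -d[j]; dj = +1; }
        else if (stat[j] == AT_UB && d[j] > TOL_COST) { viol = d[j]; dj = -1; }
        else if (stat[j] == NB_FREE && std::fabs(d[j]) > TOL_COST) {
          viol = std::fabs(d[j]); dj = (d[j] < 0) ? +1 : -1;
        }
        if (dj != 0) {
          if (bland) { enter = j; dir = dj; break; }
          if (viol > best) { best = viol; enter = j; dir = dj; }
        }
      }
      if (enter < 0) return 0; // optimal

      // ---- ratio test ----
      double tmax = INF;       // step length
      int leaveRow = -1;       // blocking basic row (-1 -> entering hits own bound)
      int leaveAt = AT_LB;
      double range = (lb[enter] > -BIGBND && ub[enter] < BIGBND)
                         ? (ub[enter] - lb[enter]) : INF;
      if (stat[enter] != NB_FREE && range < tmax) { tmax = range; }

      double bestPiv = 0.0;
      for (int i = 0; i < m; ++i) {
        double a = dir * t(i, enter);
        if (std::fabs(a) <= TOL_PIVOT) continue;
        int bv = basis[i];
        double lim;
        int hit;
        if (a > 0) { // basic decreases toward its lb
          if (lb[bv] <= -BIGBND) continue;
          lim = (xB[i] - lb[bv]) / a; hit = AT_LB;
        } else {     // basic increases toward its ub
          if (ub[bv] >= BIGBND) continue;
          lim = (ub[bv] - xB[i]) / (-a); hit = AT_UB;
        }
        if (lim < -1e-9) lim = 0.0; // tiny infeasibility from roundoff
        if (lim < tmax - 1e-12 ||
            (lim < tmax + 1e-12 && leaveRow >= 0 &&
             (bland ? (bv < basis[leaveRow])
                    : (std::fabs(t(i, enter)) > bestPiv + 1e-15)))) {
          tmax = lim; leaveRow = i; leaveAt = hit;
          bestPiv = std::fabs(t(i, enter));
        }
      }

      if (!std::isfinite(tmax)) return 2; // unbounded

      if (tmax < 1e-12) ++stall; else stall = 0;

      // ---- move ----
      if (leaveRow < 0) {
        // entering flips to its opposite bound, no basis change
        for (int i = 0; i < m; ++i) xB[i] -= dir * tmax * t(i, enter);
        xN[enter] = (dir > 0) ? ub[enter] : lb[enter];
        stat[enter] = (dir > 0) ? AT_UB : AT_LB;
        continue;
      }

      double enterVal = xN[enter] + dir * tmax;
      for (int i = 0; i < m; ++i) xB[i] -= dir * tmax * t(i, enter);

      int leaveVar = basis[leaveRow];
      // pivot tableau on (leaveRow, enter)
      double piv = t(leaveRow, enter);
      double invp = 1.0 / piv;
      for (int j = 0; j < N; ++j) if (!skip(j)) t(leaveRow, j) *= invp;
      for (int i = 0; i < m; ++i) {
        if (i == leaveRow) continue;
        double f = t(i, enter);
        if (f != 0.0)
          for (int j = 0; j < N; ++j)
            if (!skip(j)) t(i, j) -= f * t(leaveRow, j);
      }
      double fd = d[enter];
      if (fd != 0.0)
        for (int j = 0; j < N; ++j)
          if (!skip(j)) d[j] -= fd * t(leaveRow, j);

      stat[leaveVar] = leaveAt;
      xN[leaveVar] = (leaveAt == AT_LB) ? lb[leaveVar] : ub[leaveVar];
      basis[leaveRow] = enter;
      stat[enter] = BASIC;
      xB[leaveRow] = enterVal;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".lp_simplex")]]
List lp_simplex(NumericMatrix A, NumericVector b, NumericVector cvec,
                NumericVector lower, NumericVector upper,
                bool maximize = false, double maxit = 200000.0) {
  int m = A.nrow(), n = A.ncol();
  Simplex S;
  S.m = m; S.n = n; S.N = n + m;
  S.iter = 0; S.maxit = (long)maxit; S.bland = false;
  S.T.assign((size_t)m * S.N, 0.0);
  S.lb.assign(S.N, 0.0); S.ub.assign(S.N, 0.0);
  S.cost.assign(S.N, 0.0); S.d.assign(S.N, 0.0);
  S.xB.assign(m, 0.0); S.xN.assign(S.N, 0.0);
  S.basis.assign(m, 0); S.stat.assign(S.N, AT_LB);

  for (int j = 0; j < n; ++j) {
    S.lb[j] = lower[j]; S.ub[j] = upper[j];
    for (int i = 0; i < m; ++i) S.t(i, j) = A(i, j);
  }

  // nonbasic start at the finite bound nearest zero (free vars at 0)
  for (int j = 0; j < n; ++j) {
    bool lf = S.lb[j] > -BIGBND, uf = S.ub[j] < BIGBND;
    if (lf && uf) {
      if (std::fabs(S.lb[j]) <= std::fabs(S.ub[j])) { S.stat[j] = AT_LB; S.xN[j] = S.lb[j]; }
      else { S.stat[j] = AT_UB; S.xN[j] = S.ub[j]; }
    } else if (lf) { S.stat[j] = AT_LB; S.xN[j] = S.lb[j]; }
    else if (uf) { S.stat[j] = AT_UB; S.xN[j] = S.ub[j]; }
    else { S.stat[j] = NB_FREE; S.xN[j] = 0.0; }
  }

  // residual and artificial basis; rows with negative residual are negated so
  // that the initial basis (artificial columns) is the identity
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < n; ++j) r -= A(i, j) * S.xN[j];
    if (r < 0) for (int j = 0; j < n; ++j) S.t(i, j) = -S.t(i, j);
    int aj = n + i;
    S.t(i, aj) = 1.0;
    S.lb[aj] = 0.0; S.ub[aj] = INF;
    S.basis[i] = aj; S.stat[aj] = BASIC;
    S.xB[i] = std::fabs(r);
    S.cost[aj] = 1.0; // phase-1 cost
  }

  // ---- phase 1 ----
  S.refreshFixed();
  S.priceAll();
  int st = S.run();
  if (st == 3)
    return List::create(_["status"] = 3, _["x"] = R_NilValue, _["objective"] = NA_REAL);
  double p1 = 0.0;
  for (int i = 0; i < m; ++i) if (S.basis[i] >= n) p1 += S.xB[i];
  if (p1 > 1e-7)
    return List::create(_["status"] = 1, _["x"] = R_NilValue, _["objective"] = NA_REAL);

  // ---- phase 2 ----
  double sgn = maximize ? -1.0 : 1.0;
  for (int j = 0; j < n; ++j) S.cost[j] = sgn * cvec[j];
  for (int i = 0; i < m; ++i) S.cost[n + i] = 0.0;
  for (int i = 0; i < m; ++i) { S.lb[n + i] = 0.0; S.ub[n + i] = 0.0; } // pin artificials
  for (int j = n; j < S.N; ++j)
    if (S.stat[j] != BASIC) { S.stat[j] = AT_LB; S.xN[j] = 0.0; }
  S.bland = false;
  S.refreshFixed();
  S.priceAll();
  st = S.run();

  if (st == 2)
    return List::create(_["status"] = 2, _["x"] = R_NilValue, _["objective"] = NA_REAL);
  if (st == 3)
    return List::create(_["status"] = 3, _["x"] = R_NilValue, _["objective"] = NA_REAL);

  NumericVector x(n);
  double obj = 0.0;
  for (int j = 0; j < n; ++j) {
    double v = S.varValue(j);
    // snap to bounds within feasibility tolerance
    if (S.lb[j] > -BIGBND && v < S.lb[j]) v = (S.lb[j] - v < 1e-7) ? S.lb[j] : v;
    if (S.ub[j] < BIGBND && v > S.ub[j]) v = (v - S.ub[j] < 1e-7) ? S.ub[j] : v;
    x[j] = v;
    obj += cvec[j] * v;
  }
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = obj);
}
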