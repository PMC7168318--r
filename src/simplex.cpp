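// Bounded-variable two-phase primal simplex for the small dense LPs that
// arise in constraint-based metabolic modelling (FBA, pFBA, leak tests).
//
//   min/max c'x   s.t.  A x = b,  l <= x <= u
//
// Variables may have infinite bounds (encoded as +/-1e30 or larger).
// The tableau B^{-1}A is kept explicitly: models handled here have a few
// hundred columns at most, so dense pivoting is cheap and simple.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e29;   // bounds beyond this are treated as infinite
static const double INF = std::numeric_limits<double>::infinity();

enum VarState { AT_LB = 0, AT_UB = 1, BASIC = 2, FREE_NB = 3, FIXED = 4 };

struct Tab {
  int m, N;                       // rows, total columns (structural + artificial)
  std::vector<double> T;          // m x N, column-major
  std::vector<double> lo, up, x;  // per column
  std::vector<int> state;         // VarState per column
  std::vector<int> basis;         // column basic in each row
  double& at(int i, int j) { return T[(size_t)j * m + i]; }
};

// entering-variable choice; returns -1 if optimal. dir_out: +1 increase, -1 decrease.
static int choose_entering(Tab& tb, const std::vector<double>& z, double tol,
                           bool bland, int nCols, int& dir_out) {
  int best = -1; double bestv = tol;
  for (int j = 0; j < nCols; ++j) {
    int st = tb.state[j];
    if (st == BASIC || st == FIXED) continue;
    double v = 0.0; int dir = 0;
    if (st == AT_LB) { if (z[j] < -tol) { v = -z[j]; dir = 1; } }
    else if (st == AT_UB) { if (z[j] > tol) { v = z[j]; dir = -1; } }
    else { // FREE_NB
      if (z[j] < -tol) { v = -z[j]; dir = 1; }
      else if (z[j] > tol) { v = z[j]; dir = -1; }
    }
    if (dir != 0) {
      if (bland) { dir_out = dir; return j; }  // first improving index
      if (v > bestv) { bestv = v; best = j; dir_out = dir; }
    }
  }
  return best;
}

// one simplex phase; cost vector over all N columns. returns:
// 0 optimal, 2 unbounded, 3 iteration limit
static int run_phase(Tab& tb, const std::vector<double>& cost, double tol,
                     int maxit, int& iters) {
  int m = tb.m, N = tb.N;
  std::vector<double> z(N);
  int stall = 0; bool bland = false;
  for (; iters < maxit; ++iters) {
    // reduced costs z = c - cB' * T
    std::vector<double> cB(m);
    for (int i = 0; i < m; ++i) cB[i] = cost[tb.basis[i]];
    for (int j = 0; j < N; ++j) {
      double s = cost[j];
      const double* col = &tb.T[(size_t)j * m];
      for (int i = 0; i < m; ++i) s -= cB[i] * col[i];
      z[j] = s;
    }
    int dir = 0;
    int q = choose_entering(tb, z, tol, bland, N, dir);
    if (q < 0) return 0;

    // ratio test
    double tmax = INF;                       // bound-flip limit for entering var
    if (tb.lo[q] > -BIG && tb.up[q] < BIG) tmax = tb.up[q] - tb.lo[q];
    double tbest = tmax; int leave = -1; double leave_to = 0.0;
    const double* col = &tb.T[(size_t)q * m];
    for (int i = 0; i < m; ++i) {
      double delta = -dir * col[i];          // change of basic var i per unit step
      int bi = tb.basis[i];
      if (delta > tol) {
        if (tb.up[bi] < BIG) {
          double t = (tb.up[bi] - tb.x[bi]) / delta;
          if (t < tbest - 1e-12 || (t < tbest + 1e-12 && leave >= 0 && bi < tb.basis[leave])) {
            tbest = t; leave = i; leave_to = tb.up[bi];
          }
        }
      } else if (delta < -tol) {
        if (tb.lo[bi] > -BIG) {
          double t = (tb.lo[bi] - tb.x[bi]) / delta;
          if (t < tbest - 1e-12 || (t < tbest + 1e-12 && leave >= 0 && bi < tb.basis[leave])) {
            tbest = t; leave = i; leave_to = tb.lo[bi];
          }
        }
      }
    }
    if (!std::isfinite(tbest)) return 2;     // unbounded ray
    if (tbest < 0) tbest = 0;
    if (tbest <= tol) { if (++stall > 40) bland = true; } else { stall = 0; bland = false; }

    // update values
    for (int i = 0; i < m; ++i) tb.x[tb.basis[i]] += -dir * col[i] * tbest;
    tb.x[q] += dir * tbest;

    if (leave < 0) {                         // bound flip, basis unchanged
      tb.state[q] = (dir > 0) ? AT_UB : AT_LB;
      tb.x[q] = (dir > 0) ? tb.up[q] : tb.lo[q];
      continue;
    }
    // pivot: q enters, basis[leave] exits at bound leave_to
    int p = tb.basis[leave];
    double piv = tb.at(leave, q);
    if (std::fabs(piv) < 1e-11) return 3;    // numerically void pivot; bail to caller
    for (int j = 0; j < N; ++j) tb.at(leave, j) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = tb.at(i, q);
      if (f != 0.0)
        for (int j = 0; j < N; ++j) tb.at(i, j) -= f * tb.at(leave, j);
    }
    tb.x[p] = leave_to;
    if (tb.lo[p] > -BIG && tb.up[p] < BIG && std::fabs(tb.up[p] - tb.lo[p]) < 1e-12)
      tb.state[p] = FIXED;
    else if (tb.lo[p] > -BIG && std::fabs(leave_to - tb.lo[p]) < 1e-9)
      tb.state[p] = AT_LB;
    else
      tb.state[p] = AT_UB;
    tb.state[q] = BASIC;
    tb.basis[leave] = q;
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericMatrix A, NumericVector b, NumericVector cvec,
                  NumericVector lb, NumericVector ub,
                  bool maximize = false, double tol = 1e-9, int maxit = 0) {
  int m = A.nrow(), n = A.ncol();
  Tab tb;
  tb.m = m; tb.N = n + m;
  tb.T.assign((size_t)tb.N * m, 0.0);
  tb.lo.resize(tb.N); tb.up.resize(tb.N); tb.x.resize(tb.N);
  tb.state.resize(tb.N); tb.basis.resize(m);

  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) tb.at(i, j) = A(i, j);
    double l = lb[j], u = ub[j];
    tb.lo[j] = l; tb.up[j] = u;
    if (l > -BIG && u < BIG && std::fabs(u - l) < 1e-12) {
      tb.x[j] = l; tb.state[j] = FIXED;
    } else if (l > -BIG && (u >= BIG || std::fabs(l) <= std::fabs(u))) {
      tb.x[j] = l; tb.state[j] = AT_LB;
    } else if (u < BIG) {
      tb.x[j] = u; tb.state[j] = AT_UB;
    } else {
      tb.x[j] = 0.0; tb.state[j] = FREE_NB;
    }
  }
  // residuals -> artificial columns (signed identity), basic
  for (int i = 0; i < m; ++i) {
    double r = b[i];
    for (int j = 0; j < n; ++j) r -= A(i, j) * tb.x[j];
    double s = (r >= 0.0) ? 1.0 : -1.0;
    int aj = n + i;
    tb.at(i, aj) = 1.0;                      // tableau is B^{-1}A with B = diag(s)
    if (s < 0) for (int j = 0; j <= n + i; ++j) tb.at(i, j) = -tb.at(i, j);
    tb.lo[aj] = 0.0; tb.up[aj] = INF;
    tb.x[aj] = std::fabs(r); tb.state[aj] = BASIC;
    tb.basis[i] = aj;
  }

  if (maxit <= 0) maxit = 100 * (tb.N + m) + 1000;
  int iters = 0, status;

  // phase 1
  std::vector<double> c1(tb.N, 0.0);
  for (int i = 0; i < m; ++i) c1[n + i] = 1.0;
  status = run_phase(tb, c1, tol, maxit, iters);
  double p1 = 0.0;
  for (int i = 0; i < m; ++i) p1 += tb.x[n + i];
  if (status == 3)
    return List::create(_["status"] = 3, _["x"] = R_NilValue, _["objective"] = NA_REAL,
                        _["iterations"] = iters);
  if (p1 > 1e-7)
    return List::create(_["status"] = 1, _["x"] = R_NilValue, _["objective"] = NA_REAL,
                        _["iterations"] = iters);
  // pin artificials at zero for phase 2
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    tb.lo[aj] = 0.0; tb.up[aj] = 0.0;
    if (tb.state[aj] != BASIC) { tb.state[aj] = FIXED; tb.x[aj] = 0.0; }
  }

  // phase 2
  std::vector<double> c2(tb.N, 0.0);
  for (int j = 0; j < n; ++j) c2[j] = maximize ? -cvec[j] : cvec[j];
  status = run_phase(tb, c2, tol, maxit, iters);
  if (status == 2)
    return List::create(_["status"] = 2, _["x"] = R_NilValue, _["objective"] = NA_REAL,
                        _["iterations"] = iters);
  if (status == 3)
    return List::create(_["status"] = 3, _["x"] = R_NilValue, _["objective"] = NA_REAL,
                        _["iterations"] = iters);

  NumericVector xout(n);
  double obj = 0.0;
  for (int j = 0; j < n; ++j) { xout[j] = tb.x[j]; obj += cvec[j] * tb.x[j]; }
  return List::create(_["status"] = 0, _["x"] = xout, _["objective"] = obj,
                      _["iterations"] = iters);
}
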