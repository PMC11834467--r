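#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex for
//     max c'x   s.t.   A x <= b,  x >= 0
// with b of arbitrary sign.  Intended for the small, well-scaled systems
// produced by pathway energy constraints (tens of rows/columns).
//
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.
//
// Dantzig pricing with a switch to Bland's rule after a burn-in, which
// guarantees finite termination on degenerate tableaus.

static const double EPS_PIV = 1e-10;

struct Tableau {
  int m, ncol;                 // rows, total columns incl. rhs
  std::vector<double> t;       // (m + 2) x ncol, row-major; last two rows are
                               // phase-2 and phase-1 objective rows
  std::vector<int> basis;      // basic variable of each row
  double &at(int i, int j) { return t[(size_t)i * ncol + j]; }
};

static void pivot(Tableau &T, int pr, int pc) {
  const double piv = T.at(pr, pc);
  for (int j = 0; j < T.ncol; ++j) T.at(pr, j) /= piv;
  T.at(pr, pc) = 1.0;
  for (int i = 0; i < T.m + 2; ++i) {
    if (i == pr) continue;
    const double f = T.at(i, pc);
    if (std::fabs(f) < EPS_PIV) { T.at(i, pc) = 0.0; continue; }
    for (int j = 0; j < T.ncol; ++j) T.at(i, j) -= f * T.at(pr, j);
    T.at(i, pc) = 0.0;
  }
  T.basis[pr] = pc;
}

// one simplex phase on objective row `orow`; columns `allowed[j]` may enter
static int run_phase(Tableau &T, int orow, const std::vector<bool> &allowed,
                     double tol, int maxit, int &iters) {
  const int nvar = T.ncol - 1;
  while (iters++ < maxit) {
    // entering column
    int pc = -1;
    bool bland = iters > maxit / 2;
    double best = -tol;
    for (int j = 0; j < nvar; ++j) {
      if (!allowed[j]) continue;
      const double rc = T.at(orow, j);
      if (rc < -tol) {
        if (bland) { pc = j; break; }
        if (rc < best) { best = rc; pc = j; }
      }
    }
    if (pc < 0) return 0;  // optimal for this phase
    // ratio test (ties -> smallest basis index, anti-cycling)
    int pr = -1;
    double bestRatio = 0.0;
    for (int i = 0; i < T.m; ++i) {
      const double a = T.at(i, pc);
      if (a > EPS_PIV) {
        const double ratio = T.at(i, T.ncol - 1) / a;
        if (pr < 0 || ratio < bestRatio - 1e-12 ||
            (ratio < bestRatio + 1e-12 && T.basis[i] < T.basis[pr])) {
          pr = i; bestRatio = ratio;
        }
      }
    }
    if (pr < 0) return 2;  // unbounded
    pivot(T, pr, pc);
  }
  return 3;
}

// [[Rcpp::export(rng = false)]]
List simplex_core(NumericMatrix A, NumericVector b, NumericVector c,
                  double tol = 1e-9, int maxit = 20000) {
  const int m = A.nrow(), n = A.ncol();
  // count artificials (rows with negative rhs)
  std::vector<int> artRow;
  for (int i = 0; i < m; ++i) if (b[i] < 0) artRow.push_back(i);
  const int na = (int)artRow.size();
  Tableau T;
  T.m = m;
  T.ncol = n + m + na + 1;
  T.t.assign((size_t)(m + 2) * T.ncol, 0.0);
  T.basis.assign(m, -1);

  // structural + slack columns; negate rows with b < 0
  int ak = 0;
  for (int i = 0; i < m; ++i) {
    const double sgn = (b[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) T.at(i, j) = sgn * A(i, j);
    T.at(i, n + i) = sgn;                  // slack
    T.at(i, T.ncol - 1) = sgn * b[i];      // |b|
    if (b[i] < 0) {
      T.at(i, n + m + ak) = 1.0;           // artificial
      T.basis[i] = n + m + ak;
      ++ak;
    } else {
      T.basis[i] = n + i;
    }
  }
  // phase-2 objective row (reduced costs of -c; rhs accumulates c'x)
  for (int j = 0; j < n; ++j) T.at(m, j) = -c[j];
  // phase-1 objective: min sum of artificials
  for (int k = 0; k < na; ++k) T.at(m + 1, n + m + k) = 1.0;
  for (int k = 0; k < na; ++k) {
    const int i = artRow[k];
    for (int j = 0; j < T.ncol; ++j) T.at(m + 1, j) -= T.at(i, j);
  }

  std::vector<bool> allowAll(T.ncol - 1, true);
  int iters = 0, st;
  if (na > 0) {
    st = run_phase(T, m + 1, allowAll, tol, maxit, iters);
    if (st == 3) return List::create(_["status"] = 3);
    // phase-1 optimum is -sum(artificials) in rhs
    if (-T.at(m + 1, T.ncol - 1) > 1e-7)
      return List::create(_["status"] = 1);
    // drive any basic artificial out of the basis
    for (int i = 0; i < m; ++i) {
      if (T.basis[i] >= n + m) {
        int pc = -1;
        for (int j = 0; j < n + m; ++j)
          if (std::fabs(T.at(i, j)) > 1e-8) { pc = j; break; }
        if (pc >= 0) pivot(T, i, pc);
        // else: redundant row, artificial stays basic at value 0
      }
    }
  }
  // artificials may not re-enter
  std::vector<bool> allowed(T.ncol - 1, true);
  for (int k = 0; k < na; ++k) allowed[n + m + k] = false;
  st = run_phase(T, m, allowed, tol, maxit, iters);
  if (st != 0) return List::create(_["status"] = st);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (T.basis[i] < n) x[T.basis[i]] = T.at(i, T.ncol - 1);
  return List::create(_["status"] = 0,
                      _["x"] = x,
                      _["objective"] = T.at(m, T.ncol - 1),
                      _["iterations"] = iters);
}
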