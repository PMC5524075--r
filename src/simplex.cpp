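// Dense two-phase primal simplex for small LPs with finite box bounds.
// Problems here are tiny (tens of variables); a dense tableau with
// Dantzig pricing and a Bland fallback for anti-cycling is adequate and
// keeps the package self-contained (no external LP solver available).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PIV_TOL = 1e-9;
static const double FEAS_TOL = 1e-7;

// Solve: minimize c'x  s.t.  A x = b,  lb <= x <= ub  (all bounds finite).
//
// Internally shifts x = lb + z, adds an explicit upper-bound row
// z_i + s_i = d_i per variable and runs phase-1 (artificials) then
// phase-2 on the tableau.
//
// status: 0 optimal, 1 infeasible, 2 iteration limit.
// [[Rcpp::export]]
List simplex_core(const arma::vec& c, const arma::mat& A, const arma::vec& b,
                  const arma::vec& lb, const arma::vec& ub,
                  bool phase1_only = false, int max_iter = 20000) {
  const int n = (int)c.n_elem;
  const int m = (int)A.n_rows;
  arma::vec d = ub - lb;               // z in [0, d]
  arma::vec b2 = b - A * lb;

  const int m_tot = m + n;             // equality rows + upper-bound rows
  const int n_struct = 2 * n;          // z then slack s
  const int ncol = n_struct + m_tot + 1;  // + artificials + rhs

  arma::mat T(m_tot + 1, ncol, arma::fill::zeros);
  // equality rows
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T(i, j) = A(i, j);
    T(i, ncol - 1) = b2(i);
  }
  // bound rows: z_i + s_i = d_i
  for (int i = 0; i < n; ++i) {
    T(m + i, i) = 1.0;
    T(m + i, n + i) = 1.0;
    T(m + i, ncol - 1) = d(i);
  }
  // flip rows with negative rhs, install artificial basis
  std::vector<int> basis(m_tot);
  for (int i = 0; i < m_tot; ++i) {
    if (T(i, ncol - 1) < 0) T.row(i) *= -1.0;
    T(i, n_struct + i) = 1.0;
    basis[i] = n_struct + i;
  }
  // phase-1 reduced costs: minimize sum of artificials
  for (int j = 0; j < ncol; ++j) {
    double s = 0.0;
    for (int i = 0; i < m_tot; ++i) s += T(i, j);
    if (j < n_struct || j == ncol - 1) T(m_tot, j) = -s;
  }

  int iter = 0;
  bool in_phase1 = true;
  int status = 0;

  auto pivot = [&](int prow, int pcol) {
    T.row(prow) /= T(prow, pcol);
    for (int i = 0; i <= m_tot; ++i) {
      if (i == prow) continue;
      double f = T(i, pcol);
      if (std::abs(f) > 0.0) T.row(i) -= f * T.row(prow);
    }
    basis[prow] = pcol;
  };

  auto run_phase = [&](bool allow_artificial) -> int {
    while (true) {
      if (++iter > max_iter) return 2;
      bool bland = iter > 2000;
      int enter = -1;
      double best = -PIV_TOL;
      int jmax = allow_artificial ? (n_struct + m_tot) : n_struct;
      for (int j = 0; j < jmax; ++j) {
        double rc = T(m_tot, j);
        if (rc < -PIV_TOL) {
          if (bland) { enter = j; break; }
          if (rc < best) { best = rc; enter = j; }
        }
      }
      if (enter < 0) return 0;  // optimal
      // ratio test
      int leave = -1;
      double best_ratio = arma::datum::inf;
      for (int i = 0; i < m_tot; ++i) {
        double a = T(i, enter);
        if (a > PIV_TOL) {
          double r = T(i, ncol - 1) / a;
          if (r < best_ratio - 1e-12 ||
              (r < best_ratio + 1e-12 && leave >= 0 && basis[i] < basis[leave])) {
            best_ratio = r;
            leave = i;
          }
        }
      }
      if (leave < 0) return 3;  // unbounded (cannot happen with box bounds)
      pivot(leave, enter);
    }
  };

  // artificials never enter the basis once out (jmax below excludes them)
  int rc1 = run_phase(false);
  if (rc1 != 0) status = rc1;
  double phase1_obj = -T(m_tot, ncol - 1);
  if (status == 0 && phase1_obj > FEAS_TOL * (1.0 + arma::norm(b2, "inf")))
    status = 1;  // infeasible

  if (status == 0 && !phase1_only) {
    // drive remaining artificials out of the basis where possible
    for (int i = 0; i < m_tot; ++i) {
      if (basis[i] >= n_struct) {
        int piv = -1;
        for (int j = 0; j < n_struct; ++j)
          if (std::abs(T(i, j)) > 1e-7) { piv = j; break; }
        if (piv >= 0) pivot(i, piv);
        // else: redundant row, artificial stays basic at zero
      }
    }
    // rebuild reduced costs for phase 2: costs are c on z, 0 on s
    arma::rowvec obj(ncol, arma::fill::zeros);
    for (int j = 0; j < n; ++j) obj(j) = c(j);
    for (int i = 0; i < m_tot; ++i) {
      int bj = basis[i];
      double cb = (bj < n) ? c(bj) : 0.0;
      if (cb != 0.0) obj -= cb * T.row(i);
    }
    for (int j = 0; j < ncol; ++j) T(m_tot, j) = obj(j);
    for (int j = n_struct; j < n_struct + m_tot; ++j) T(m_tot, j) = 0.0;

    in_phase1 = false;
    int rc2 = run_phase(false);
    if (rc2 != 0) status = rc2;
  }
  (void)in_phase1;

  arma::vec x = lb;  // z = 0 baseline
  if (status == 0 || status == 2) {
    for (int i = 0; i < m_tot; ++i)
      if (basis[i] < n) x(basis[i]) = lb(basis[i]) + T(i, ncol - 1);
  }
  double objval = arma::dot(c, x);
  return List::create(_["status"] = status, _["x"] = x, _["obj"] = objval);
}
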