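// Bounded-variable revised simplex for flux balance analysis LPs:
//
//   maximize c'x   subject to   S x = 0,   l <= x <= u,   with l <= 0 <= u.
//
// Every FBA polytope in this package contains x = 0 (irreversible [0,V],
// reversible [-V,V], uptake [-u,V]), so no phase-1 is needed: the chain starts
// from the all-artificial basis (artificial columns with bounds [0,0]) and the
// zero point. Nonbasic structural variables track their current value, which
// may be strictly interior (0 between a negative lower and positive upper
// bound); they may move in either improving direction.
//
// Anti-cycling: Dantzig pricing with a switch to Bland's rule after a long
// stall; the basis inverse is refactorized periodically to control drift.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double basic_lb(int b, int n, const arma::vec& l) {
  return b < n ? l[b] : 0.0;
}
static inline double basic_ub(int b, int n, const arma::vec& u) {
  return b < n ? u[b] : 0.0;
}

// [[Rcpp::export(name = ".simplex_fba")]]
List simplex_fba(const arma::sp_mat& S, const arma::vec& c,
                 const arma::vec& l, const arma::vec& u,
                 int max_iter = 0,
                 double tol_d = 1e-7,   // dual feasibility tolerance
                 double tol_x = 1e-9,   // primal bound tolerance
                 double tol_piv = 1e-9) // smallest acceptable pivot
{
  const int m = S.n_rows, n = S.n_cols;
  if ((int) c.n_elem != n || (int) l.n_elem != n || (int) u.n_elem != n)
    stop("dimension mismatch between S and c/l/u");
  for (int j = 0; j < n; ++j) {
    if (l[j] > tol_x || u[j] < -tol_x)
      stop("solver requires 0 within every variable's bounds");
  }
  if (max_iter <= 0) max_iter = 200 * (m + n) + 20000;

  arma::sp_mat St = S.t();

  arma::vec x(n, arma::fill::zeros);   // structural values
  arma::vec xa(m, arma::fill::zeros);  // artificial values
  arma::ivec basis(m);
  std::vector<char> in_basis(n + m, 0);
  for (int i = 0; i < m; ++i) { basis[i] = n + i; in_basis[n + i] = 1; }
  arma::mat Binv(m, m, arma::fill::eye);
  arma::vec cb(m, arma::fill::zeros);

  int status = 1; // 0 optimal, 1 iteration limit, 2 unbounded, 3 singular basis
  bool bland = false;
  int stall = 0, pivots_since_refactor = 0;
  double best_obj = 0.0;
  int iter = 0;

  auto refactor = [&]() -> bool {
    arma::mat B(m, m, arma::fill::zeros);
    for (int i = 0; i < m; ++i) {
      int b = basis[i];
      if (b < n) {
        for (arma::sp_mat::const_col_iterator it = S.begin_col(b); it != S.end_col(b); ++it)
          B(it.row(), i) = *it;
      } else {
        B(b - n, i) = 1.0;
      }
    }
    arma::mat Bi;
    if (!arma::inv(Bi, B)) return false;
    Binv = Bi;
    // recompute basic values from the nonbasic ones: B x_B = -A_N x_N
    arma::vec rhs(m, arma::fill::zeros);
    for (int j = 0; j < n; ++j) {
      if (!in_basis[j] && x[j] != 0.0) {
        for (arma::sp_mat::const_col_iterator it = S.begin_col(j); it != S.end_col(j); ++it)
          rhs(it.row()) -= (*it) * x[j];
      }
    }
    arma::vec xb = Binv * rhs;
    for (int i = 0; i < m; ++i) {
      int b = basis[i];
      if (b < n) x[b] = xb[i]; else xa[b - n] = xb[i];
    }
    pivots_since_refactor = 0;
    return true;
  };

  while (iter < max_iter) {
    ++iter;

    arma::vec y = Binv.t() * cb;
    arma::vec d = c - St * y;

    // entering variable (structural only; artificials are fixed at [0,0])
    int j_in = -1, dir = 0;
    double best = tol_d;
    for (int j = 0; j < n; ++j) {
      if (in_basis[j]) continue;
      double dj = d[j];
      if (dj > tol_d && x[j] < u[j] - tol_x) {
        if (bland) { j_in = j; dir = +1; break; }
        if (dj > best) { best = dj; j_in = j; dir = +1; }
      } else if (dj < -tol_d && x[j] > l[j] + tol_x) {
        if (bland) { j_in = j; dir = -1; break; }
        if (-dj > best) { best = -dj; j_in = j; dir = -1; }
      }
    }
    if (j_in < 0) { status = 0; break; }

    // direction through the basis: w = Binv * S[, j_in]
    arma::vec w(m, arma::fill::zeros);
    for (arma::sp_mat::const_col_iterator it = S.begin_col(j_in); it != S.end_col(j_in); ++it)
      w += (*it) * Binv.col(it.row());

    // ratio test: entering moves by sigma * t, basic i changes at rate -sigma*w[i]
    double sigma = (double) dir;
    double tmax = dir > 0 ? (u[j_in] - x[j_in]) : (x[j_in] - l[j_in]);
    int leave = -1;          // -1 means bound flip of the entering variable
    bool leave_to_lower = true;
    double leave_piv = 0.0;
    for (int i = 0; i < m; ++i) {
      double swi = sigma * w[i];
      if (swi > tol_piv) {
        int b = basis[i];
        double xb = b < n ? x[b] : xa[b - n];
        double t = (xb - basic_lb(b, n, l)) / swi;
        if (t < 0) t = 0;
        if (t < tmax - 1e-12 ||
            (t < tmax + 1e-12 && leave >= 0 && std::abs(w[i]) > std::abs(leave_piv)) ||
            (bland && t < tmax + 1e-12 && (leave < 0 || basis[i] < basis[leave]))) {
          tmax = t; leave = i; leave_to_lower = true; leave_piv = w[i];
        }
      } else if (swi < -tol_piv) {
        int b = basis[i];
        double xb = b < n ? x[b] : xa[b - n];
        double t = (basic_ub(b, n, u) - xb) / (-swi);
        if (t < 0) t = 0;
        if (t < tmax - 1e-12 ||
            (t < tmax + 1e-12 && leave >= 0 && std::abs(w[i]) > std::abs(leave_piv)) ||
            (bland && t < tmax + 1e-12 && (leave < 0 || basis[i] < basis[leave]))) {
          tmax = t; leave = i; leave_to_lower = false; leave_piv = w[i];
        }
      }
    }

    if (!std::isfinite(tmax)) { status = 2; break; }

    // apply the step
    x[j_in] += sigma * tmax;
    for (int i = 0; i < m; ++i) {
      int b = basis[i];
      double delta = sigma * tmax * w[i];
      if (b < n) x[b] -= delta; else xa[b - n] -= delta;
    }

    if (leave >= 0) {
      double piv = w[leave];
      if (std::abs(piv) < tol_piv) {
        if (!refactor()) { status = 3; break; }
        continue;
      }
      int b_out = basis[leave];
      double bound = leave_to_lower ? basic_lb(b_out, n, l) : basic_ub(b_out, n, u);
      if (b_out < n) x[b_out] = bound; else xa[b_out - n] = bound;
      in_basis[b_out] = 0;
      in_basis[j_in] = 1;
      basis[leave] = j_in;
      cb[leave] = c[j_in];
      // product-form update of Binv
      Binv.row(leave) /= piv;
      for (int i = 0; i < m; ++i) {
        if (i == leave) continue;
        double wi = w[i];
        if (wi != 0.0) Binv.row(i) -= wi * Binv.row(leave);
      }
      if (++pivots_since_refactor >= 150) {
        if (!refactor()) { status = 3; break; }
      }
    }

    double obj = arma::dot(c, x);
    if (obj > best_obj + 1e-10) { best_obj = obj; stall = 0; }
    else if (++stall > 2 * (m + n) + 200 && !bland) { bland = true; stall = 0; }
  }

  double obj = arma::dot(c, x);
  double resid = arma::norm(arma::vec(S * x), "inf");
  return List::create(_["status"] = status,
                      _["objective"] = obj,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = iter,
                      _["residual"] = resid);
}
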