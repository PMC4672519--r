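// Bounded-variable two-phase primal simplex.
//
// Solves   max  c'x   s.t.  A x = b,  lb <= x <= ub
// with an explicit basis inverse (eta updates, periodic refactorisation).
// Dantzig pricing switches to Bland's rule after a fixed iteration count so
// the method terminates on degenerate problems.  Dimensions here are small
// (community models are a few hundred columns), so dense algebra is fine.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PIV_TOL = 1e-9;   // minimum acceptable pivot magnitude
static const double DJ_TOL = 1e-9;    // reduced-cost optimality tolerance
static const double RATIO_TIE = 1e-9;

struct SimplexState {
  mat W;                 // m x N working matrix [A | signed artificials]
  vec lo, hi, x;         // length N
  std::vector<int> basis;     // row -> column in basis
  std::vector<int> in_basis;  // column -> row (-1 if nonbasic)
  std::vector<bool> at_upper; // for nonbasic columns
  mat Binv;
  int m, n, N;
};

static void refactorize(SimplexState &st) {
  mat B(st.m, st.m);
  for (int i = 0; i < st.m; ++i) B.col(i) = st.W.col(st.basis[i]);
  bool ok = inv(st.Binv, B);
  if (!ok) st.Binv = pinv(B);
}

static void recompute_basics(SimplexState &st, const vec &b) {
  vec rhs = b;
  for (int j = 0; j < st.N; ++j)
    if (st.in_basis[j] < 0 && st.x(j) != 0.0) rhs -= st.W.col(j) * st.x(j);
  vec xb = st.Binv * rhs;
  for (int i = 0; i < st.m; ++i) st.x(st.basis[i]) = xb(i);
}

// returns: 0 optimal, 1 unbounded, 2 iteration limit
static int simplex_phase(SimplexState &st, const vec &cost, const vec &b,
                         int max_iter) {
  int iter = 0;
  const int bland_after = 500 + 20 * st.N;
  while (iter++ < max_iter) {
    bool bland = iter > bland_after;
    if (iter % 100 == 0) { refactorize(st); recompute_basics(st, b); }

    vec cb(st.m);
    for (int i = 0; i < st.m; ++i) cb(i) = cost(st.basis[i]);
    vec y = st.Binv.t() * cb;

    int enter = -1, enter_sign = 0;
    double best = DJ_TOL;
    for (int j = 0; j < st.N; ++j) {
      if (st.in_basis[j] >= 0) continue;
      if (st.hi(j) - st.lo(j) <= 0) continue;  // fixed variable
      double dj = cost(j) - dot(y, st.W.col(j));
      int sgn = 0;
      if (!st.at_upper[j] && dj > DJ_TOL) sgn = +1;
      else if (st.at_upper[j] && dj < -DJ_TOL) sgn = -1;
      if (sgn == 0) continue;
      if (bland) { enter = j; enter_sign = sgn; break; }
      if (std::fabs(dj) > best) { best = std::fabs(dj); enter = j; enter_sign = sgn; }
    }
    if (enter < 0) return 0;  // optimal

    vec w = st.Binv * st.W.col(enter);

    // ratio test: entering moves by enter_sign * t, basics by -enter_sign*w*t
    double t_max = st.hi(enter) - st.lo(enter);  // bound-flip distance
    double t_best = t_max;
    int leave_row = -1, leave_side = 0;  // side: -1 lower, +1 upper
    double leave_delta = 0.0;
    for (int i = 0; i < st.m; ++i) {
      double delta = -enter_sign * w(i);
      int bi = st.basis[i];
      double lim;
      int side;
      if (delta > PIV_TOL) {
        if (!std::isfinite(st.hi(bi))) continue;
        lim = (st.hi(bi) - st.x(bi)) / delta; side = +1;
      } else if (delta < -PIV_TOL) {
        if (!std::isfinite(st.lo(bi))) continue;
        lim = (st.lo(bi) - st.x(bi)) / delta; side = -1;
      } else continue;
      if (lim < 0) lim = 0;
      bool take = false;
      if (lim < t_best - RATIO_TIE) take = true;
      else if (lim <= t_best + RATIO_TIE && leave_row >= 0) {
        if (bland) { if (st.basis[i] < st.basis[leave_row]) take = true; }
        else if (std::fabs(delta) > std::fabs(leave_delta)) take = true;
      } else if (lim <= t_best + RATIO_TIE && leave_row < 0 &&
                 lim <= t_best) take = true;
      if (take) { t_best = lim; leave_row = i; leave_side = side; leave_delta = delta; }
    }

    if (!std::isfinite(t_best)) return 1;  // unbounded

    // apply step
    for (int i = 0; i < st.m; ++i)
      st.x(st.basis[i]) -= enter_sign * w(i) * t_best;
    st.x(enter) += enter_sign * t_best;

    if (leave_row < 0) {
      // bound flip, basis unchanged
      st.at_upper[enter] = !st.at_upper[enter];
      st.x(enter) = st.at_upper[enter] ? st.hi(enter) : st.lo(enter);
      continue;
    }

    int leave_col = st.basis[leave_row];
    st.x(leave_col) = (leave_side > 0) ? st.hi(leave_col) : st.lo(leave_col);
    st.at_upper[leave_col] = (leave_side > 0);
    st.in_basis[leave_col] = -1;
    st.basis[leave_row] = enter;
    st.in_basis[enter] = leave_row;

    // eta update of Binv
    double piv = w(leave_row);
    rowvec prow = st.Binv.row(leave_row) / piv;
    for (int i = 0; i < st.m; ++i) {
      if (i == leave_row) continue;
      st.Binv.row(i) -= w(i) * prow;
    }
    st.Binv.row(leave_row) = prow;
  }
  return 2;
}

// [[Rcpp::export(name = ".cpp_simplex")]]
Rcpp::List cpp_simplex(const arma::mat &A, const arma::vec &b,
                       const arma::vec &c, const arma::vec &lb,
                       const arma::vec &ub, bool maximize = true,
                       int max_iter = 20000) {
  const int m = A.n_rows, n = A.n_cols;
  if ((int)b.n_elem != m || (int)c.n_elem != n || (int)lb.n_elem != n ||
      (int)ub.n_elem != n)
    Rcpp::stop("inconsistent LP dimensions");
  for (int j = 0; j < n; ++j) {
    if (lb(j) > ub(j) + 1e-12) Rcpp::stop("lower bound exceeds upper bound");
    if (!std::isfinite(lb(j)) && !std::isfinite(ub(j)))
      Rcpp::stop("free variables (both bounds infinite) are not supported");
  }

  vec cc = maximize ? c : vec(-c);

  if (m == 0) {
    vec x(n);
    double obj = 0.0;
    for (int j = 0; j < n; ++j) {
      double v = cc(j) > 0 ? ub(j) : (cc(j) < 0 ? lb(j) : (std::isfinite(lb(j)) ? std::max(0.0, lb(j)) : 0.0));
      if (!std::isfinite(v))
        return Rcpp::List::create(Rcpp::Named("status") = "unbounded");
      x(j) = v; obj += cc(j) * v;
    }
    return Rcpp::List::create(Rcpp::Named("status") = "optimal",
                              Rcpp::Named("x") = x,
                              Rcpp::Named("objective") = maximize ? obj : -obj);
  }

  SimplexState st;
  st.m = m; st.n = n; st.N = n + m;
  st.W.set_size(m, st.N);
  st.W.cols(0, n - 1) = A;
  st.lo.set_size(st.N); st.hi.set_size(st.N); st.x.set_size(st.N);
  st.at_upper.assign(st.N, false);
  st.in_basis.assign(st.N, -1);
  st.basis.resize(m);

  // structural variables start at the finite bound nearest zero
  for (int j = 0; j < n; ++j) {
    st.lo(j) = lb(j); st.hi(j) = ub(j);
    double v;
    if (std::isfinite(lb(j)) && std::isfinite(ub(j)))
      v = (std::fabs(lb(j)) <= std::fabs(ub(j))) ? lb(j) : ub(j);
    else v = std::isfinite(lb(j)) ? lb(j) : ub(j);
    st.x(j) = v;
    st.at_upper[j] = (v == ub(j) && v != lb(j));
  }
  vec r = b - A * st.x.subvec(0, n - 1);
  for (int i = 0; i < m; ++i) {
    double s = (r(i) >= 0) ? 1.0 : -1.0;
    int aj = n + i;
    st.W.col(aj).zeros();
    st.W(i, aj) = s;
    st.lo(aj) = 0.0; st.hi(aj) = datum::inf;
    st.x(aj) = std::fabs(r(i));
    st.basis[i] = aj; st.in_basis[aj] = i;
  }
  st.Binv.eye(m, m);
  for (int i = 0; i < m; ++i) st.Binv(i, i) = st.W(i, n + i);  // diag(+-1)

  // phase 1: maximise -(sum of artificials)
  vec cost1(st.N, fill::zeros);
  for (int i = 0; i < m; ++i) cost1(n + i) = -1.0;
  int rc = simplex_phase(st, cost1, b, max_iter);
  if (rc == 2)
    return Rcpp::List::create(Rcpp::Named("status") = "iteration_limit");
  refactorize(st); recompute_basics(st, b);
  double art_sum = 0.0;
  for (int i = 0; i < m; ++i) art_sum += st.x(n + i);
  if (art_sum > 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = "infeasible");

  // drive basic artificials out where possible; redundant rows keep a
  // zero-fixed artificial in the basis
  for (int i = 0; i < m; ++i) {
    int bi = st.basis[i];
    if (bi < n) continue;
    rowvec bri = st.Binv.row(i);
    int piv_col = -1; double piv = 0.0;
    for (int j = 0; j < n; ++j) {
      if (st.in_basis[j] >= 0) continue;
      double wij = dot(bri, st.W.col(j));
      if (std::fabs(wij) > 1e-7) { piv_col = j; piv = wij; break; }
    }
    if (piv_col < 0) continue;
    vec w = st.Binv * st.W.col(piv_col);
    st.in_basis[bi] = -1; st.at_upper[bi] = false; st.x(bi) = 0.0;
    st.basis[i] = piv_col; st.in_basis[piv_col] = i;
    rowvec prow = st.Binv.row(i) / piv;
    for (int k = 0; k < m; ++k) {
      if (k == i) continue;
      st.Binv.row(k) -= w(k) * prow;
    }
    st.Binv.row(i) = prow;
    recompute_basics(st, b);
  }
  for (int i = 0; i < m; ++i) st.hi(n + i) = 0.0;  // artificials now fixed

  // phase 2
  vec cost2(st.N, fill::zeros);
  cost2.subvec(0, n - 1) = cc;
  rc = simplex_phase(st, cost2, b, max_iter);
  if (rc == 2)
    return Rcpp::List::create(Rcpp::Named("status") = "iteration_limit");
  if (rc == 1)
    return Rcpp::List::create(Rcpp::Named("status") = "unbounded");
  refactorize(st); recompute_basics(st, b);

  vec x = st.x.subvec(0, n - 1);
  // snap tiny bound violations introduced by floating point
  for (int j = 0; j < n; ++j) {
    if (x(j) < lb(j) && x(j) > lb(j) - 1e-8) x(j) = lb(j);
    if (x(j) > ub(j) && x(j) < ub(j) + 1e-8) x(j) = ub(j);
  }
  double obj = dot(c, x);
  return Rcpp::List::create(Rcpp::Named("status") = "optimal",
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = obj);
}
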