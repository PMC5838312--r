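// Dense bounded-variable two-phase primal simplex.
//
// Solves   max  c'x   s.t.  A x = b,  lb <= x <= ub
// with an explicit basis inverse maintained by rank-1 (product-form) updates
// and periodic refactorization. Sized for constraint-based metabolic models
// of a few hundred variables; every FBA/FVA/NGAM call in the package goes
// through this routine.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double OPT_TOL   = 1e-9;
const double PIVOT_TOL = 1e-10;
const double BIG_BND   = 1e6;   // stand-in for +/-Inf bounds
const int    REFACTOR_EVERY = 80;

struct LpResult {
  int status;        // 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  double objective;
  vec x;
};

enum NB { AT_LB = 0, AT_UB = 1 };

struct Simplex {
  const mat& Afull;
  const vec& b;
  vec LB, UB;
  uword n, M;
  std::vector<uword> basis;
  std::vector<bool> in_basis;
  std::vector<int> nb_state;
  vec xval;    // nonbasic values (basic entries stale)
  vec xB;      // basic values
  mat Binv;
  int pivots_since_refactor;

  Simplex(const mat& A, const vec& b_, vec LB_, vec UB_)
    : Afull(A), b(b_), LB(LB_), UB(UB_), n(A.n_rows), M(A.n_cols),
      pivots_since_refactor(0) {}

  bool refactor() {
    mat B(n, n);
    for (uword i = 0; i < n; ++i) B.col(i) = Afull.col(basis[i]);
    mat Bi;
    if (!inv(Bi, B)) return false;
    Binv = Bi;
    pivots_since_refactor = 0;
    recompute_xB();
    return true;
  }

  void recompute_xB() {
    vec rhs = b;
    for (uword j = 0; j < M; ++j)
      if (!in_basis[j]) rhs -= Afull.col(j) * xval(j);
    xB = Binv * rhs;
  }

  // returns 0 optimal, 2 unbounded, 3 iteration limit, 4 numeric failure
  int run_phase(const vec& obj, bool phase1) {
    const uword max_iter = 60 * (M + n) + 5000;
    const uword bland_after = 6 * (M + n) + 500;
    for (uword iter = 0; iter < max_iter; ++iter) {
      vec cB(n);
      for (uword i = 0; i < n; ++i) cB(i) = obj(basis[i]);
      vec y = Binv.t() * cB;
      sword enter = -1;
      int dir = 0;
      double best = 0.0;
      bool bland = iter > bland_after;
      for (uword j = 0; j < M; ++j) {
        if (in_basis[j]) continue;
        if (!phase1 && j >= M) continue;
        if (LB(j) == UB(j)) continue;
        double dj = obj(j) - dot(y, Afull.col(j));
        int d = 0;
        if (nb_state[j] == AT_LB && dj >  OPT_TOL) d = +1;
        else if (nb_state[j] == AT_UB && dj < -OPT_TOL) d = -1;
        if (d != 0) {
          if (bland) { enter = j; dir = d; break; }
          double score = std::abs(dj);
          if (score > best) { best = score; enter = j; dir = d; }
        }
      }
      if (enter < 0) return 0;

      vec w = Binv * Afull.col(enter);
      double tmax = UB(enter) - LB(enter);  // bound-flip distance
      sword leave = -1;
      int leave_to = 0;
      for (uword i = 0; i < n; ++i) {
        double wi = dir * w(i);
        if (std::abs(wi) < PIVOT_TOL) continue;
        double room;
        int to;
        if (wi > 0) { room = (xB(i) - LB(basis[i])) / wi; to = AT_LB; }
        else        { room = (xB(i) - UB(basis[i])) / wi; to = AT_UB; }
        if (room < -1e-9) room = 0;
        if (room < tmax - 1e-12) {
          tmax = room; leave = i; leave_to = to;
        } else if (leave >= 0 && bland && std::abs(room - tmax) <= 1e-12 &&
                   basis[i] < basis[leave]) {
          leave = i; leave_to = to;
        }
      }
      if (!std::isfinite(tmax)) return 2;
      double t = std::max(tmax, 0.0);
      xB -= (dir * t) * w;
      double xenter = xval(enter) + dir * t;
      if (leave < 0) {
        xval(enter) = xenter;
        nb_state[enter] = (dir > 0) ? AT_UB : AT_LB;
      } else {
        uword out = basis[leave];
        in_basis[out] = false;
        xval(out) = (leave_to == AT_LB) ? LB(out) : UB(out);
        nb_state[out] = leave_to;
        basis[leave] = (uword) enter;
        in_basis[enter] = true;
        xB(leave) = xenter;
        xval(enter) = xenter;
        // product-form update of Binv
        double piv = w(leave);
        if (std::abs(piv) < PIVOT_TOL) { if (!refactor()) return 4; continue; }
        rowvec br = Binv.row(leave) / piv;
        for (uword i = 0; i < n; ++i) {
          if ((sword) i == leave) continue;
          double wi = w(i);
          if (wi != 0.0) Binv.row(i) -= wi * br;
        }
        Binv.row(leave) = br;
        if (++pivots_since_refactor >= REFACTOR_EVERY) {
          if (!refactor()) return 4;
        }
      }
    }
    return 3;
  }
};

LpResult simplex_core(const mat& A, const vec& b, const vec& c,
                      const vec& lb_in, const vec& ub_in) {
  const uword n = A.n_rows;
  const uword m = A.n_cols;
  LpResult res;
  res.status = 1;
  res.objective = NA_REAL;

  vec lb = lb_in, ub = ub_in;
  for (uword j = 0; j < m; ++j) {
    if (!std::isfinite(lb(j))) lb(j) = -BIG_BND;
    if (!std::isfinite(ub(j))) ub(j) =  BIG_BND;
  }

  const uword M = m + n;
  vec LB(M), UB(M);
  LB.head(m) = lb; UB.head(m) = ub;

  vec xval(M, fill::zeros);
  std::vector<int> nb_state(M, AT_LB);
  for (uword j = 0; j < m; ++j) {
    if (std::abs(lb(j)) <= std::abs(ub(j))) { nb_state[j] = AT_LB; xval(j) = lb(j); }
    else                                    { nb_state[j] = AT_UB; xval(j) = ub(j); }
  }

  vec r = (n > 0) ? vec(b - A * xval.head(m)) : vec();
  mat Afull(n, M, fill::zeros);
  if (m > 0) Afull.cols(0, m - 1) = A;
  for (uword i = 0; i < n; ++i) {
    Afull(i, m + i) = (r(i) >= 0) ? 1.0 : -1.0;
    LB(m + i) = 0.0;
    UB(m + i) = datum::inf;
  }

  Simplex sx(Afull, b, LB, UB);
  sx.xval = xval;
  sx.nb_state = nb_state;
  sx.basis.resize(n);
  sx.in_basis.assign(M, false);
  for (uword i = 0; i < n; ++i) { sx.basis[i] = m + i; sx.in_basis[m + i] = true; }
  sx.Binv = eye(n, n);
  for (uword i = 0; i < n; ++i) if (Afull(i, m + i) < 0) sx.Binv(i, i) = -1.0;
  sx.xB = abs(r);

  if (n > 0) {
    vec obj1(M, fill::zeros);
    for (uword i = 0; i < n; ++i) obj1(m + i) = -1.0;
    int st = sx.run_phase(obj1, true);
    if (st == 4) { res.status = 3; return res; }
    if (st == 3) { res.status = 3; return res; }
    sx.refactor();
    double art = 0.0;
    for (uword i = 0; i < n; ++i) {
      uword aj = m + i;
      if (sx.in_basis[aj]) {
        for (uword k = 0; k < n; ++k)
          if (sx.basis[k] == aj) art += std::abs(sx.xB(k));
      } else {
        art += std::abs(sx.xval(aj));
      }
    }
    if (art > 1e-7) { res.status = 1; return res; }
    for (uword i = 0; i < n; ++i) {
      sx.LB(m + i) = 0.0; sx.UB(m + i) = 0.0; sx.xval(m + i) = 0.0;
    }
  }

  vec obj2(M, fill::zeros);
  obj2.head(m) = c;
  int st = sx.run_phase(obj2, false);
  if (st == 2) { res.status = 2; return res; }
  if (st == 3 || st == 4) { res.status = 3; return res; }
  sx.refactor();

  vec x(m);
  for (uword j = 0; j < m; ++j) x(j) = sx.xval(j);
  for (uword i = 0; i < n; ++i) if (sx.basis[i] < m) x(sx.basis[i]) = sx.xB(i);
  for (uword j = 0; j < m; ++j) {
    if (x(j) < lb(j)) x(j) = lb(j);
    if (x(j) > ub(j)) x(j) = ub(j);
  }
  res.status = 0;
  res.x = x;
  res.objective = dot(c, x);
  return res;
}

} // namespace

//' @useDynLib oenoflux, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".cpp_simplex")]]
Rcpp::List cpp_simplex(const arma::mat& A, const arma::vec& b, const arma::vec& c,
                       const arma::vec& lb, const arma::vec& ub,
                       const bool maximize) {
  vec cc = maximize ? vec(c) : vec(-c);
  LpResult r = simplex_core(A, b, cc, lb, ub);
  std::string status =
    r.status == 0 ? "optimal" :
    r.status == 1 ? "infeasible" :
    r.status == 2 ? "unbounded" : "iteration_limit";
  double obj = NA_REAL;
  Rcpp::NumericVector x;
  if (r.status == 0) {
    obj = maximize ? r.objective : -r.objective;
    x = Rcpp::wrap(r.x);
  }
  return Rcpp::List::create(Rcpp::Named("status") = status,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = x);
}
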