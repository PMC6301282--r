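// Dense two-phase revised simplex with variable bounds.
//
// Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
// via phase-1 artificial variables and Bland's rule (anti-cycling).
// Intended for the small LPs arising from toy-scale metabolic models;
// basis systems are re-solved from scratch every iteration, trading raw
// speed for numerical freshness and implementation simplicity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double RTOL  = 1e-9;   // reduced-cost / ratio tolerance
static const double FTOL  = 1e-6;   // phase-1 feasibility tolerance
static const double BIG   = 1e30;   // stands in for +infinity
static const int    MAXIT = 50000;

namespace {

struct SimplexState {
  mat A;            // m x (n + m), structural + artificial columns
  vec b, cost, lo, hi, x;
  uvec basis;       // m basic variable indices
  std::vector<int> at_upper; // nonbasic rest status (1 = at upper bound)
  unsigned m, ntot;
};

// One run of the bounded-variable simplex on the current cost vector.
// Returns 0 optimal, 2 iteration limit, 3 numerically unbounded.
int run_simplex(SimplexState &S) {
  const unsigned m = S.m, ntot = S.ntot;
  for (int iter = 0; iter < MAXIT; ++iter) {
    mat B = S.A.cols(S.basis);
    std::vector<char> is_basic(ntot, 0);
    for (unsigned i = 0; i < m; ++i) is_basic[S.basis(i)] = 1;
    // residual demand once nonbasic contributions are removed
    vec r = S.b;
    for (unsigned j = 0; j < ntot; ++j)
      if (!is_basic[j] && S.x(j) != 0.0) r -= S.A.col(j) * S.x(j);
    vec xB;
    if (!solve(xB, B, r)) return 3;
    for (unsigned i = 0; i < m; ++i) S.x(S.basis(i)) = xB(i);

    vec cB(m);
    for (unsigned i = 0; i < m; ++i) cB(i) = S.cost(S.basis(i));
    vec y;
    if (!solve(y, B.t(), cB)) return 3;

    // Entering variable: Dantzig (most improving) normally, switching to
    // Bland's smallest-index rule after many iterations to break cycles.
    const bool bland = iter > 2000;
    int enter = -1, sigma = 0;
    double best = 0;
    for (unsigned j = 0; j < ntot; ++j) {
      if (is_basic[j]) continue;
      if (S.hi(j) - S.lo(j) < 1e-12) continue; // fixed
      double d = S.cost(j) - dot(y, S.A.col(j));
      double gain = 0; int sg = 0;
      if (S.at_upper[j] == 0 && d < -RTOL) { gain = -d; sg = +1; }
      else if (S.at_upper[j] == 1 && d > RTOL) { gain = d; sg = -1; }
      else continue;
      if (bland) { enter = j; sigma = sg; break; }
      if (gain > best) { best = gain; enter = j; sigma = sg; }
    }
    if (enter < 0) return 0; // optimal

    vec w;
    if (!solve(w, B, S.A.col(enter))) return 3;

    double tmax = S.hi(enter) - S.lo(enter); // own-bound flip distance
    if (tmax > BIG) tmax = datum::inf;
    int leave = -1; int leave_dir = 0;
    for (unsigned i = 0; i < m; ++i) {
      double delta = -sigma * w(i); // d xB_i / d t
      double limit; int dir;
      if (delta > RTOL) {
        double cap = S.hi(S.basis(i));
        if (cap > BIG) continue;
        limit = (cap - xB(i)) / delta; dir = 1;
      } else if (delta < -RTOL) {
        double cap = S.lo(S.basis(i));
        if (cap < -BIG) continue;
        limit = (cap - xB(i)) / delta; dir = 0;
      } else continue;
      if (limit < 0) limit = 0;
      if (limit < tmax - 1e-12 ||
          (leave >= 0 && std::abs(limit - tmax) <= 1e-12 &&
           S.basis(i) < S.basis(leave))) {
        tmax = limit; leave = i; leave_dir = dir;
      }
    }
    if (!std::isfinite(tmax)) return 3; // unbounded direction

    if (leave < 0) {
      // entering variable flips to its opposite bound
      S.x(enter) = S.at_upper[enter] ? S.lo(enter) : S.hi(enter);
      S.at_upper[enter] = 1 - S.at_upper[enter];
    } else {
      double xe = (S.at_upper[enter] ? S.hi(enter) : S.lo(enter)) + sigma * tmax;
      unsigned out = S.basis(leave);
      S.x(out) = leave_dir ? S.hi(out) : S.lo(out);
      S.at_upper[out] = leave_dir;
      S.basis(leave) = enter;
      S.x(enter) = xe;
    }
  }
  return 2;
}

} // namespace

// [[Rcpp::export(name = ".simplex_lp")]]
Rcpp::List simplex_lp(const arma::mat &A, const arma::vec &b,
                      const arma::vec &cvec, const arma::vec &lb,
                      const arma::vec &ub, bool maximize) {
  const unsigned m = A.n_rows, n = A.n_cols;
  SimplexState S;
  S.m = m; S.ntot = n + m;
  S.A.set_size(m, n + m);
  S.A.cols(0, n - 1) = A;
  S.b = b;
  S.lo.set_size(n + m); S.hi.set_size(n + m);
  S.x.zeros(n + m);
  S.at_upper.assign(n + m, 0);

  for (unsigned j = 0; j < n; ++j) {
    S.lo(j) = std::isfinite(lb(j)) ? lb(j) : -BIG * 10;
    S.hi(j) = std::isfinite(ub(j)) ? ub(j) :  BIG * 10;
    // rest at the bound of smaller magnitude (finite preferred)
    double l = S.lo(j), h = S.hi(j);
    if (std::abs(l) <= std::abs(h)) { S.x(j) = l; S.at_upper[j] = 0; }
    else                            { S.x(j) = h; S.at_upper[j] = 1; }
  }

  // artificial columns signed so their initial values are >= 0
  vec resid = b;
  for (unsigned j = 0; j < n; ++j)
    if (S.x(j) != 0.0) resid -= A.col(j) * S.x(j);
  S.basis.set_size(m);
  for (unsigned i = 0; i < m; ++i) {
    unsigned j = n + i;
    double s = (resid(i) >= 0) ? 1.0 : -1.0;
    S.A.col(j).zeros();
    S.A(i, j) = s;
    S.lo(j) = 0; S.hi(j) = datum::inf;
    S.basis(i) = j;
    S.x(j) = std::abs(resid(i));
  }

  // phase 1: drive artificials to zero
  S.cost.zeros(n + m);
  for (unsigned i = 0; i < m; ++i) S.cost(n + i) = 1.0;
  int st = run_simplex(S);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = (st == 2 ? 2 : 1),
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("objective") = NA_REAL);
  double infeas = 0;
  for (unsigned i = 0; i < m; ++i) infeas += S.x(n + i);
  double scale = std::max(1.0, norm(b, "inf"));
  if (infeas > FTOL * scale)
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("objective") = NA_REAL);

  // phase 2: artificials pinned at zero, structural objective active
  for (unsigned i = 0; i < m; ++i) { S.lo(n + i) = 0; S.hi(n + i) = 0; }
  S.cost.zeros(n + m);
  for (unsigned j = 0; j < n; ++j) S.cost(j) = maximize ? -cvec(j) : cvec(j);
  st = run_simplex(S);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("objective") = NA_REAL);

  vec xout = S.x.subvec(0, n - 1);
  double obj = dot(cvec, xout);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = Rcpp::NumericVector(xout.begin(), xout.end()),
                            Rcpp::Named("objective") = obj);
}
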