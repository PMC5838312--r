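// Artificial-centering hit-and-run over {v : S v = b, lb <= v <= ub}.
//
// Directions are differences between previously visited points and the running
// center, so every proposal stays in the affine space S v = b exactly (up to
// floating drift); bounds are enforced by the line-segment computation.
// Uses R's RNG, so chains are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cpp_achr")]]
arma::mat cpp_achr(const arma::mat& warmup,   // m x K feasible points
                   const arma::vec& lb, const arma::vec& ub,
                   const int n_samples, const int thinning,
                   const int n_warmup_steps) {
  const uword m = warmup.n_rows;
  const uword K = warmup.n_cols;
  if (K < 2) Rcpp::stop("need at least two warmup points");

  mat pts = warmup;                 // pool the chain draws directions from
  vec center = mean(pts, 1);
  double npts = (double) K;

  vec x = center;                   // start at the centroid (convex => feasible)
  mat out(m, n_samples);

  Rcpp::RNGScope scope;
  const double eps = 1e-10;
  long total = (long) n_warmup_steps + (long) n_samples * (long) thinning;
  int kept = 0;
  for (long step = 0; step < total; ++step) {
    // pick a stored point, direction toward/away from center
    uword pick = (uword) std::floor(R::unif_rand() * (double) pts.n_cols);
    if (pick >= pts.n_cols) pick = pts.n_cols - 1;
    vec d = pts.col(pick) - center;
    double nrm = norm(d);
    if (nrm < 1e-12) continue;
    d /= nrm;

    double amin = -datum::inf, amax = datum::inf;
    for (uword j = 0; j < m; ++j) {
      double dj = d(j);
      if (std::abs(dj) < 1e-12) continue;
      double lo = (lb(j) - x(j)) / dj;
      double hi = (ub(j) - x(j)) / dj;
      if (dj < 0) std::swap(lo, hi);
      if (lo > amin) amin = lo;
      if (hi < amax) amax = hi;
    }
    if (!std::isfinite(amin) || !std::isfinite(amax) || amax - amin < eps)
      continue;
    double alpha = amin + R::unif_rand() * (amax - amin);
    x += alpha * d;
    // clamp tiny excursions
    for (uword j = 0; j < m; ++j) {
      if (x(j) < lb(j)) x(j) = lb(j);
      if (x(j) > ub(j)) x(j) = ub(j);
    }
    // running center over everything seen keeps the chain "artificially centered"
    center = (center * npts + x) / (npts + 1.0);
    npts += 1.0;

    if (step >= n_warmup_steps && ((step - n_warmup_steps + 1) % thinning == 0)) {
      out.col(kept) = x;
      ++kept;
      if (kept >= n_samples) break;
    }
  }
  if (kept < n_samples) {
    // degenerate polytope (single point): pad with current x
    for (int k = kept; k < n_samples; ++k) out.col(k) = x;
  }
  return out;
}
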