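#include <Rcpp.h>
using namespace Rcpp;

// Mass-action right-hand side evaluated column-wise over a matrix of states
// (one column per spatial position). Reaction structure is passed sparsely:
//  - term_r / term_s / term_p : for each flux factor, the reaction index,
//    state-species index and integer power (1-based indices);
//  - kfac : n_reactions x n_positions matrix of rate constants already
//    multiplied by the constant-species factors at each position;
//  - g_i / g_j / g_v : sparse triplets of the stoichiometric matrix
//    (species row, reaction column, net change).
// States are clamped at zero before evaluation so small negative integrator
// excursions cannot produce spurious fluxes.

// [[Rcpp::export]]
NumericMatrix ma_rhs_field(const NumericMatrix& x,
                           const IntegerVector& term_r,
                           const IntegerVector& term_s,
                           const IntegerVector& term_p,
                           const NumericMatrix& kfac,
                           const IntegerVector& g_i,
                           const IntegerVector& g_j,
                           const NumericVector& g_v) {
  const int S = x.nrow(), P = x.ncol(), R = kfac.nrow();
  NumericMatrix flux(R, P);
  for (int p = 0; p < P; ++p)
    for (int r = 0; r < R; ++r)
      flux(r, p) = kfac(r, p);
  const int nt = term_r.size();
  for (int t = 0; t < nt; ++t) {
    const int r = term_r[t] - 1, s = term_s[t] - 1, pw = term_p[t];
    for (int p = 0; p < P; ++p) {
      double v = x(s, p);
      if (v < 0) v = 0;
      double f = v;
      for (int q = 1; q < pw; ++q) f *= v;
      flux(r, p) *= f;
    }
  }
  NumericMatrix dx(S, P);
  const int ng = g_i.size();
  for (int t = 0; t < ng; ++t) {
    const int i = g_i[t] - 1, j = g_j[t] - 1;
    const double v = g_v[t];
    for (int p = 0; p < P; ++p) dx(i, p) += v * flux(j, p);
  }
  return dx;
}

// Flux vector itself (used by the pretty printer/tests), same conventions.
// [[Rcpp::export]]
NumericMatrix ma_flux_field(const NumericMatrix& x,
                            const IntegerVector& term_r,
                            const IntegerVector& term_s,
                            const IntegerVector& term_p,
                            const NumericMatrix& kfac) {
  const int P = x.ncol(), R = kfac.nrow();
  NumericMatrix flux(R, P);
  for (int p = 0; p < P; ++p)
    for (int r = 0; r < R; ++r)
      flux(r, p) = kfac(r, p);
  const int nt = term_r.size();
  for (int t = 0; t < nt; ++t) {
    const int r = term_r[t] - 1, s = term_s[t] - 1, pw = term_p[t];
    for (int p = 0; p < P; ++p) {
      double v = x(s, p);
      if (v < 0) v = 0;
      double f = v;
      for (int q = 1; q < pw; ++q) f *= v;
      flux(r, p) *= f;
    }
  }
  return flux;
}
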