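// Composite-likelihood kernel for the convergence-mode models.
//
// Data: standardized allele frequencies x_s = (p - pbar)/sqrt(pbar(1-pbar))
// per SNP, which sum to zero across populations by construction. All
// densities are therefore evaluated in the (k-1)-dimensional subspace
// orthogonal to the ones vector, via an orthonormal basis Q (k x k-1):
// x* = Q'x, Sigma* = Q'(F + D)Q.
//
// D is the sweep-induced inflation on the raw scale, approximate second
// moments of the package's implant generator. With y = exp(-r tau),
// tau = log(4 Ne s)/s, sharing group G, origin population o, and any
// population u outside G:
//   independent:  D_ii = y                                   (i selected)
//   migration (origin = source population o in G):
//                 w    = exp(-2 r / (4 Ne m))   (recombination during the
//                                                migrant's arrival delay)
//                 D_ii = y (1 - F_ii)
//                 D_ij = w y^2 (1 - F_ij)
//                 D_iu = y (F_ou - F_iu)
//   standing (origin = the ancestral population, coancestry 0):
//                 q    = exp(-r t_st)
//                 D_ii = y (1 - q F_ii)
//                 D_ij = q^2 (1-g) y^2 (1 - F_ij)
//                 D_iu = -y q F_iu
// Mixed models apply the shared-mode terms within the designated subgroup
// and the independent diagonal to the remaining selected populations.
// Rationale: a swept population's frequency is a single haplotype's allele
// state with probability y; that haplotype has unit standardized variance
// and carries its origin's coancestry with every other population (zero
// for the ancestral origin, the source's row of F for migration). Shared
// capture across two populations requires both lineages to be captured
// (y^2) and, for standing variants, survival of t_st generations of
// recombination in each population (q^2). The origin's own drift variance
// is deliberately left out of the diagonal and pair terms so that the
// standing and migration models differ only in decay shape and origin
// coancestry, not in overall scale (scale is the quantity most distorted
// by per-site standardization). Standing reduces to independent as
// t_st -> Inf, and every model reduces to F as y -> 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// The model covariances use approximate mixture moments; at high sharing
// they can dip slightly below PSD. Rather than rejecting such parameter
// combinations (which would silently censor parts of the grid), negative
// eigenvalues are clipped to a small floor.
static double mvn_loglik(const arma::vec& x, arma::mat Sigma) {
  arma::mat L;
  if (!arma::chol(L, Sigma, "lower")) {
    arma::vec ev;
    arma::mat V;
    if (!arma::eig_sym(ev, V, Sigma)) return -1e300;
    ev = arma::clamp(ev, 1e-4, ev.max() > 1e-4 ? ev.max() : 1e-4);
    Sigma = V * arma::diagmat(ev) * V.t();
    if (!arma::chol(L, Sigma, "lower")) return -1e300;
  }
  arma::vec z = arma::solve(arma::trimatl(L), x);
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  double k = x.n_elem;
  return -0.5 * (k * std::log(2.0 * M_PI) + logdet + arma::dot(z, z));
}

// model codes: 0 neutral, 1 independent, 2 standing, 3 migration,
// 4 mixed_migration, 5 mixed_standing
// [[Rcpp::export]]
arma::mat cpp_dmc_grid(const arma::mat& Xs,         // (k-1) x S reduced freqs
                       const arma::vec& pos,        // S positions (bp)
                       const arma::vec& prop,       // P proposed sites (bp)
                       const arma::mat& F,          // k x k neutral covariance
                       const arma::mat& Q,          // k x (k-1) basis of 1-perp
                       const arma::uvec& sel,       // 0-based selected pops
                       const arma::uvec& grp,       // 0-based sharing subgroup
                       const int origin,            // 0-based origin pop
                       const int model,
                       const arma::mat& combos,     // C x 4: s, t_st, g, m
                       const double ne,
                       const double rec,
                       const arma::vec& svar) {     // per-pop sampling variance
  const arma::uword k = F.n_rows, S = Xs.n_cols;
  const arma::uword P = prop.n_elem, C = combos.n_rows;
  arma::mat out(C, P);
  // binomial sampling variance of the frequency estimates rides on the
  // diagonal of every model's covariance (it never cancels between models
  // and keeps the full-sharing corner non-degenerate)
  const arma::mat Fs = Q.t() * (F + arma::diagmat(svar)) * Q;

  std::vector<bool> in_grp(k, false);
  for (arma::uword a = 0; a < grp.n_elem; ++a) in_grp[grp(a)] = true;

  if (model == 0) { // neutral: constant across sites and combos
    double ll = 0.0;
    for (arma::uword j = 0; j < S; ++j) ll += mvn_loglik(Xs.col(j), Fs);
    out.fill(ll);
    return out;
  }

  const bool standing_like = (model == 2 || model == 5);
  const bool migration_like = (model == 3 || model == 4);

  for (arma::uword c = 0; c < C; ++c) {
    double s = combos(c, 0), t_st = combos(c, 1);
    double g = combos(c, 2), m = combos(c, 3);
    double tau = std::log(4.0 * ne * s) / s;
    double t_mig = migration_like ? 1.0 / (4.0 * ne * m) : 0.0;
    for (arma::uword p = 0; p < P; ++p) {
      double ll = 0.0;
      for (arma::uword j = 0; j < S; ++j) {
        double r = std::fabs(pos(j) - prop(p)) * rec;
        double y = std::exp(-r * tau);
        double q = standing_like ? std::exp(-r * t_st) : 1.0;
        double share = 0.0;
        if (standing_like) share = q * q * (1.0 - g);
        else if (migration_like) share = std::exp(-2.0 * r * t_mig);

        arma::mat D(k, k, arma::fill::zeros);
        for (arma::uword a = 0; a < sel.n_elem; ++a) {
          arma::uword i = sel(a);
          if (model == 1 || !in_grp[i])
            D(i, i) = y;
          else if (standing_like)
            D(i, i) = y * (1.0 - q * F(i, i));
          else
            D(i, i) = y * (1.0 - F(i, i));
        }
        if (model != 1) {
          for (arma::uword a = 0; a < grp.n_elem; ++a) {
            arma::uword i = grp(a);
            // pairs within the sharing group
            for (arma::uword b = a + 1; b < grp.n_elem; ++b) {
              arma::uword jj = grp(b);
              double d = share * y * y * (1.0 - F(i, jj));
              D(i, jj) = d;
              D(jj, i) = d;
            }
            // origin coancestry with populations outside the group
            for (arma::uword u = 0; u < k; ++u) {
              if (in_grp[u] || u == i) continue;
              double d = standing_like
                ? -y * q * F(i, u)
                : y * (F(origin, u) - F(i, u));
              D(i, u) += d;
              D(u, i) += d;
            }
          }
        }
        arma::mat Sigma = Fs + Q.t() * D * Q;
        ll += mvn_loglik(Xs.col(j), Sigma);
      }
      out(c, p) = ll;
    }
    if (c % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
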