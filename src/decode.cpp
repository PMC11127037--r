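// Pairwise cross-validated Fisher linear discriminant decoding.
//
// For one stimulus pair the kernel runs, at every timepoint, repeated
// stratified k-fold cross-validation: the discriminant direction is
// w = S^-1 (mu_b - mu_a) with S the pooled within-class covariance of the
// training trials shrunk toward a scaled identity (Ledoit-Wolf intensity),
// and the dissimilarity is the AUC of the held-out decision values,
// averaged over folds and then over repetitions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Mann-Whitney AUC with midrank ties: P(b > a) + 0.5 P(b = a)
static double auc_from_scores(const arma::vec &sa, const arma::vec &sb) {
  const arma::uword na = sa.n_elem, nb = sb.n_elem, n = na + nb;
  arma::vec all(n);
  all.head(na) = sa;
  all.tail(nb) = sb;
  arma::uvec ord = arma::sort_index(all);
  arma::vec ranks(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && all(ord(j + 1)) == all(ord(i))) ++j;
    const double mid = 0.5 * (double)(i + j) + 1.0;  // 1-based midrank
    for (arma::uword k = i; k <= j; ++k) ranks(ord(k)) = mid;
    i = j + 1;
  }
  const double rank_b = arma::accu(ranks.tail(nb));
  return (rank_b - (double)nb * ((double)nb + 1.0) / 2.0) /
         ((double)na * (double)nb);
}

// Pooled within-class covariance with Ledoit-Wolf shrinkage toward nu*I.
// za, zb: training rows already centered on their class means.
static arma::mat shrunk_pooled_cov(const arma::mat &za, const arma::mat &zb) {
  const arma::uword c = za.n_cols;
  const arma::uword n = za.n_rows + zb.n_rows;
  arma::mat z = arma::join_cols(za, zb);
  arma::mat s = (z.t() * z) / (double)n;
  const double nu = arma::trace(s) / (double)c;
  if (nu < 1e-300) {
    // no within-class variance at all (noiseless toy data)
    return arma::eye(c, c);
  }
  // b2 = (1/n^2) sum_i || z_i z_i' - S ||_F^2, d2 = || S - nu I ||_F^2
  double sum4 = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double q = arma::dot(z.row(i), z.row(i));
    sum4 += q * q;
  }
  const double s_f2 = arma::accu(s % s);
  double b2 = sum4 / ((double)n * (double)n) - s_f2 / (double)n;
  arma::mat dev = s;
  dev.diag() -= nu;
  const double d2 = arma::accu(dev % dev);
  double lambda = 1.0;
  if (d2 > 0.0) lambda = std::min(1.0, std::max(0.0, b2) / d2);
  arma::mat sh = (1.0 - lambda) * s;
  sh.diag() += lambda * nu + 1e-12 * nu;
  return sh;
}

// xa, xb: trials x channels x timepoints cubes for the two stimuli.
// folds_a, folds_b: repetitions x trials integer matrices of fold ids in
// 1..n_folds (stratified per class, computed and seeded in R).
// [[Rcpp::export]]
arma::vec decode_pair_cpp(const arma::cube &xa, const arma::cube &xb,
                          const arma::imat &folds_a, const arma::imat &folds_b,
                          const int n_folds) {
  const arma::uword nt = xa.n_slices;
  const arma::uword n_rep = folds_a.n_rows;
  arma::vec out(nt);

  for (arma::uword t = 0; t < nt; ++t) {
    const arma::mat &a = xa.slice(t);
    const arma::mat &b = xb.slice(t);
    double rep_sum = 0.0;
    for (arma::uword r = 0; r < n_rep; ++r) {
      double fold_sum = 0.0;
      for (int f = 1; f <= n_folds; ++f) {
        arma::uvec te_a = arma::find(folds_a.row(r).t() == f);
        arma::uvec te_b = arma::find(folds_b.row(r).t() == f);
        arma::uvec tr_a = arma::find(folds_a.row(r).t() != f);
        arma::uvec tr_b = arma::find(folds_b.row(r).t() != f);
        arma::mat a_tr = a.rows(tr_a), b_tr = b.rows(tr_b);
        arma::rowvec ma = arma::mean(a_tr, 0), mb = arma::mean(b_tr, 0);
        a_tr.each_row() -= ma;
        b_tr.each_row() -= mb;
        arma::mat s = shrunk_pooled_cov(a_tr, b_tr);
        arma::vec w = arma::solve(s, (mb - ma).t(),
                                  arma::solve_opts::likely_sympd);
        arma::vec sa = a.rows(te_a) * w;
        arma::vec sb = b.rows(te_b) * w;
        fold_sum += auc_from_scores(sa, sb);
      }
      rep_sum += fold_sum / (double)n_folds;
    }
    out(t) = rep_sum / (double)n_rep;
  }
  return out;
}
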