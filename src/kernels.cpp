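// Compiled kernels for the hot paths: GY94 transition matrices under uniform
// codon frequencies (symmetric case), categorical codon sampling, and NG86
// count accumulation. The R implementations of the same operations remain
// the reference; these only accelerate cohort-scale loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Row-cumulative GY94 transition probabilities exp(Q t) for uniform codon
// frequencies, where the scaled generator is symmetric. Index vectors are
// 1-based linear indices into the n x n matrix, as produced in R.
// [[Rcpp::export]]
NumericMatrix gy94_cum_pmatrix_cpp(double kappa, double omega, double t,
                                   int n,
                                   IntegerVector syn_tv, IntegerVector syn_ts,
                                   IntegerVector non_tv, IntegerVector non_ts) {
  arma::mat q(n, n, arma::fill::zeros);
  const double pi = 1.0 / n;
  for (int k = 0; k < syn_tv.size(); ++k) q(syn_tv[k] - 1) = pi;
  for (int k = 0; k < syn_ts.size(); ++k) q(syn_ts[k] - 1) = kappa * pi;
  for (int k = 0; k < non_tv.size(); ++k) q(non_tv[k] - 1) = omega * pi;
  for (int k = 0; k < non_ts.size(); ++k) q(non_ts[k] - 1) = kappa * omega * pi;
  arma::vec rs = arma::sum(q, 1);
  q.diag() = -rs;
  double rate = arma::dot(arma::vec(n, arma::fill::value(pi)), rs);
  if (rate > 0) q /= rate;
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, q);
  arma::mat p = evec * arma::diagmat(arma::exp(eval * t)) * evec.t();
  p.clamp(0.0, arma::datum::inf);
  p.each_col() /= arma::sum(p, 1);
  // cumulative sums along rows
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += p(i, j);
      p(i, j) = acc;
    }
  }
  return wrap(p);
}

// Inverse-CDF sampling of descendant codon states; uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector sample_codons_cpp(IntegerVector anc, NumericMatrix cum_p) {
  const int n = anc.size();
  const int k = cum_p.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double u = R::runif(0.0, 1.0);
    const int row = anc[i] - 1;
    int j = 0;
    while (j < k - 1 && cum_p(row, j) < u) ++j;
    out[i] = j + 1;
  }
  return out;
}

// Map a CDS string to 1-based sense-codon indices (NA for gaps, ambiguity or
// stop codons) using a 64-entry lookup built in R (T=0, C=1, A=2, G=3).
// [[Rcpp::export]]
IntegerVector cds_to_codon_indices_cpp(std::string cds,
                                       IntegerVector lookup64) {
  const int n = cds.size() / 3;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int idx = 0;
    bool ok = true;
    for (int p = 0; p < 3; ++p) {
      const char c = cds[3 * i + p];
      int v;
      switch (c) {
        case 'T': v = 0; break;
        case 'C': v = 1; break;
        case 'A': v = 2; break;
        case 'G': v = 3; break;
        default: v = -1; ok = false;
      }
      if (!ok) break;
      idx = idx * 4 + v;
    }
    if (!ok) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = lookup64[idx];  // may itself be NA (stop codon)
    }
  }
  return out;
}

// NG86 site and difference sums over paired codon index vectors; pairs with
// an NA on either side are skipped (pairwise deletion).
// [[Rcpp::export]]
NumericVector ng86_accumulate_cpp(IntegerVector ia, IntegerVector ib,
                                  NumericVector n_sites, NumericVector s_sites,
                                  NumericMatrix nd, NumericMatrix sd) {
  double N = 0, S = 0, Nd = 0, Sd = 0;
  int used = 0;
  for (int i = 0; i < ia.size(); ++i) {
    if (ia[i] == NA_INTEGER || ib[i] == NA_INTEGER) continue;
    const int a = ia[i] - 1, b = ib[i] - 1;
    N += 0.5 * (n_sites[a] + n_sites[b]);
    S += 0.5 * (s_sites[a] + s_sites[b]);
    Nd += nd(a, b);
    Sd += sd(a, b);
    ++used;
  }
  return NumericVector::create(N, S, Nd, Sd, used);
}
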