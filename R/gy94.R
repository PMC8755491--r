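# Goldman-Yang (1994) one-ratio codon substitution model: the generator used
# both to simulate ortholog divergence and to fit M0 by maximum likelihood.

#' Goldman-Yang M0 instantaneous rate matrix
#'
#' Builds the 61x61 generator over the sense codons: zero for changes at more
#' than one codon position; proportional to the target codon's equilibrium
#' frequency for single-nucleotide changes, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes. The diagonal is set so
#' rows sum to zero, and the matrix is rescaled so the expected number of
#' substitutions per codon per unit time equals one (so branch lengths are in
#' substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio (> 0 allowed to be 0 only
#'   in the degenerate no-transition case; must be >= 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param codon_frequencies Equilibrium frequencies over [sense_codons()]
#'   (positive, summing to 1). Defaults to uniform.
#' @return 61x61 numeric matrix with codon dimnames.
#' @export
build_m0_generator <- function(kappa, omega,
                               codon_frequencies = uniform_codon_frequencies()) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    abort("`kappa` must be a single non-negative number")
  }
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0) {
    abort("`omega` must be a single non-negative number")
  }
  pm <- codon_pair_masks()
  pi <- as.numeric(codon_frequencies[pm$codons])
  if (anyNA(pi) || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    abort("`codon_frequencies` must be positive over the 61 sense codons and sum to 1")
  }
  q <- gy94_fill(kappa, omega, pi)
  dimnames(q) <- list(pm$codons, pm$codons)
  attr(q, "codon_frequencies") <- setNames(pi, pm$codons)
  q
}

# hot-path generator construction from precomputed linear index sets
gy94_fill <- function(kappa, omega, pi) {
  ix <- gy94_index()
  n <- length(pi)
  q <- numeric(n * n)
  q[ix$syn_tv] <- pi[ix$col_syn_tv]
  q[ix$syn_ts] <- kappa * pi[ix$col_syn_ts]
  q[ix$non_tv] <- omega * pi[ix$col_non_tv]
  q[ix$non_ts] <- kappa * omega * pi[ix$col_non_ts]
  dim(q) <- c(n, n)
  diag(q) <- -rowSums(q)
  rate <- -sum(pi * diag(q))
  if (rate > 0) q <- q / rate
  q
}

gy94_index <- function() {
  if (!is.null(the$gy94_index)) return(the$gy94_index)
  pm <- codon_pair_masks()
  n <- length(pm$codons)
  lin <- function(mask) which(mask)
  col_of <- function(idx) ((idx - 1L) %/% n) + 1L
  sets <- list(
    syn_tv = lin(pm$single & !pm$nonsyn & !pm$transition),
    syn_ts = lin(pm$single & !pm$nonsyn & pm$transition),
    non_tv = lin(pm$single & pm$nonsyn & !pm$transition),
    non_ts = lin(pm$single & pm$nonsyn & pm$transition)
  )
  the$gy94_index <- c(sets, setNames(lapply(sets, col_of),
                                     paste0("col_", names(sets))))
  the$gy94_index
}

# exp(Q t) for a reversible generator with stationary distribution pi, via
# symmetrisation D^{1/2} Q D^{-1/2} and a symmetric eigendecomposition.
# Returns the eigensystem so repeated t values reuse one decomposition.
gy94_eigen <- function(q, pi) {
  s <- sqrt(pi)
  b <- q * outer(s, 1 / s)
  b <- (b + t(b)) / 2  # symmetric up to round-off by reversibility
  e <- eigen(b, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, s = s)
}

gy94_prob_from_eigen <- function(es, t) {
  p <- (es$vectors %*% (exp(es$values * t) * t(es$vectors))) *
    outer(1 / es$s, es$s)
  p[p < 0] <- 0
  p / rowSums(p)
}

#' M0 codon transition probability matrix
#'
#' `exp(Q t)` for the [build_m0_generator()] rate matrix; rows sum to one.
#'
#' @inheritParams build_m0_generator
#' @param t Branch length in expected substitutions per codon (>= 0).
#' @return 61x61 stochastic matrix.
#' @export
m0_transition_matrix <- function(kappa, omega,
                                 codon_frequencies = uniform_codon_frequencies(),
                                 t = 1) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    abort("`t` must be a single non-negative number")
  }
  q <- build_m0_generator(kappa, omega, codon_frequencies)
  pi <- as.numeric(codon_frequencies[rownames(q)])
  pi <- pi / sum(pi)
  p <- gy94_prob_from_eigen(gy94_eigen(q, pi), t)
  dimnames(p) <- dimnames(q)
  p
}

# Proportion of the model's substitution flux that is synonymous:
# sum_{i != j, syn} pi_i Q_ij for a generator scaled to unit total flux.
gy94_syn_flux <- function(q, pi) {
  pm <- codon_pair_masks()
  syn_off <- pm$single & !pm$nonsyn
  flux <- pi * q
  sum(flux[syn_off]) / sum(flux[pm$single])
}

# PAML-convention dN and dS from fitted (t, kappa, omega, pi): expected
# substitutions are split into synonymous/nonsynonymous classes and divided by
# the per-class site proportions, the latter computed from the same mutational
# process with omega = 1. With this convention dN/dS equals omega exactly.
gy94_dn_ds <- function(t, kappa, omega, pi) {
  q <- build_m0_generator(kappa, omega, pi)
  rho_s <- gy94_syn_flux(q, pi)
  q1 <- build_m0_generator(kappa, 1, pi)
  rho_s1 <- gy94_syn_flux(q1, pi)
  syn_sites_frac <- rho_s1          # per-codon fraction of the 3 sites
  ds <- t * rho_s / (3 * syn_sites_frac)
  dn <- t * (1 - rho_s) / (3 * (1 - syn_sites_frac))
  list(dN = dn, dS = ds)
}
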