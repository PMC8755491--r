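# Maximum-likelihood pairwise dN/dS under the Goldman-Yang one-ratio (M0)
# codon model, the same model family the simulator uses.

#' Fit the M0 codon model to one pairwise codon alignment
#'
#' Maximises `sum_sites log(pi_x P_xy(t))` over divergence `t`, the
#' transition/transversion ratio `kappa` and `omega`, with codon equilibrium
#' frequencies either F3x4 (estimated jointly from both sequences) or uniform.
#' Codon columns with a gap, ambiguity or stop codon are skipped. Box
#' constraints (`t` in [1e-6, 50], `kappa` in [0.01, 99], `omega` in
#' [1e-4, 99]) and a three-point multistart over omega guard against the
#' occasional multimodality of low-divergence pairwise likelihoods; ties in
#' log-likelihood go to the smallest omega. dN and dS are derived from the
#' fitted generator by splitting the expected substitutions into
#' nonsynonymous and synonymous classes and dividing by the corresponding
#' site proportions, so dN/dS equals the fitted omega.
#'
#' @param codon_a,codon_b Gap-aligned CDS strings of equal length divisible
#'   by 3.
#' @param freqs `"f3x4"` (default) or `"uniform"`.
#' @param omega_starts Starting omega values for the multistart.
#' @return Object of class `"m0_fit"`: a list with `t`, `kappa`, `omega`,
#'   `lnL`, `dN`, `dS`, `valid`, `n_codons_used`, `freqs`, `convergence`.
#' @export
m0_fit <- function(codon_a, codon_b, freqs = c("f3x4", "uniform"),
                   omega_starts = c(0.1, 0.5, 2.0)) {
  freqs <- match.arg(freqs)
  sc <- sense_codons()
  ca <- split_codons(codon_a)
  cb <- split_codons(codon_b)
  if (length(ca) != length(cb)) abort("alignment rows differ in length")
  ia <- match(ca, sc)
  ib <- match(cb, sc)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]
  ib <- ib[ok]
  n_used <- length(ia)
  if (n_used == 0L) abort("no usable codon columns")
  pi <- if (freqs == "f3x4") {
    f3x4_frequencies(c(paste(ca[ok], collapse = ""), paste(cb[ok], collapse = "")))
  } else {
    uniform_codon_frequencies()
  }
  out_base <- list(n_codons_used = n_used, freqs = freqs)
  if (all(ia == ib)) {
    # no variable sites: t is at its lower boundary and omega is undefined
    out <- c(list(t = 0, kappa = NA_real_, omega = NA_real_,
                  lnL = sum(log(pi[ia])), dN = 0, dS = 0, valid = FALSE,
                  convergence = 0L), out_base)
    class(out) <- "m0_fit"
    return(out)
  }
  counts <- table(factor((ib - 1L) * length(sc) + ia,
                         levels = seq_len(length(sc)^2)))
  nz <- which(counts > 0)
  n_xy <- as.numeric(counts[nz])
  x_idx <- ((nz - 1L) %% length(sc)) + 1L
  y_idx <- ((nz - 1L) %/% length(sc)) + 1L
  log_pi_term <- sum(n_xy * log(pi[x_idx]))
  pi_num <- as.numeric(pi)

  lower <- log(c(t = 1e-6, kappa = 0.01, omega = 1e-4))
  upper <- log(c(t = 50, kappa = 99, omega = 99))
  negll <- function(par) {
    q <- build_m0_generator(exp(par[2]), exp(par[3]), pi)
    p <- gy94_prob_from_eigen(gy94_eigen(q, pi_num), exp(par[1]))
    pxy <- p[cbind(x_idx, y_idx)]
    if (any(pxy <= 0)) return(1e10)
    -(log_pi_term + sum(n_xy * log(pxy)))
  }
  p_diff <- mean(ia != ib)
  t_start <- max(0.1, 1.5 * p_diff)
  fits <- lapply(omega_starts, function(w0) {
    stats::optim(
      par = log(c(t_start, 2, w0)), fn = negll, method = "L-BFGS-B",
      lower = lower, upper = upper,
      control = list(maxit = 200, factr = 1e9)
    )
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-6)
  omegas <- vapply(fits[cand], function(f) exp(f$par[3]), numeric(1))
  best <- fits[[cand[which.min(omegas)]]]
  if (all(vapply(fits, function(f) f$convergence != 0, logical(1)))) {
    abort(paste0("M0 optimisation failed to converge from all starts (codes: ",
                 paste(vapply(fits, function(f) f$convergence, numeric(1)),
                       collapse = ", "), ")"))
  }
  t_hat <- exp(best$par[1])
  kappa_hat <- exp(best$par[2])
  omega_hat <- exp(best$par[3])
  rates <- gy94_dn_ds(t_hat, kappa_hat, omega_hat, pi)
  valid <- rates$dS > 0 && t_hat > 2e-6
  out <- c(list(t = t_hat, kappa = kappa_hat, omega = omega_hat,
                lnL = -best$value, dN = rates$dN, dS = rates$dS,
                valid = valid, convergence = best$convergence), out_base)
  class(out) <- "m0_fit"
  out
}

#' M0 log-likelihood of a codon alignment at given parameters
#'
#' @inheritParams m0_fit
#' @param t,kappa,omega Model parameters.
#' @param codon_frequencies Equilibrium frequencies over the sense codons.
#' @return Log-likelihood (scalar).
#' @export
m0_loglik <- function(codon_a, codon_b, t, kappa, omega,
                      codon_frequencies = uniform_codon_frequencies()) {
  sc <- sense_codons()
  ia <- match(split_codons(codon_a), sc)
  ib <- match(split_codons(codon_b), sc)
  ok <- !is.na(ia) & !is.na(ib)
  pi <- as.numeric(codon_frequencies)
  p <- m0_transition_matrix(kappa, omega, codon_frequencies, t)
  sum(log(pi[ia[ok]] * p[cbind(ia[ok], ib[ok])]))
}

#' @export
print.m0_fit <- function(x, ...) {
  cat("M0 pairwise fit (", x$n_codons_used, " codons, ", x$freqs,
      " frequencies)\n", sep = "")
  cat(sprintf("  t = %.4g  kappa = %.4g  omega = %.4g  lnL = %.4f\n",
              x$t, x$kappa, x$omega, x$lnL))
  cat(sprintf("  dN = %.4g  dS = %.4g  valid = %s\n", x$dN, x$dS, x$valid))
  invisible(x)
}

#' Tidy an M0 fit into a term/estimate tibble
#' @param x An `m0_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term` and `estimate`.
#' @export
tidy.m0_fit <- function(x, ...) {
  tibble(
    term = c("t", "kappa", "omega", "dN", "dS"),
    estimate = c(x$t, x$kappa, x$omega, x$dN, x$dS)
  )
}

#' One-row model summary of an M0 fit
#' @param x An `m0_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `logLik`, `n_codons`, `valid`, `freqs`.
#' @export
glance.m0_fit <- function(x, ...) {
  tibble(logLik = x$lnL, n_codons = x$n_codons_used, valid = x$valid,
         freqs = x$freqs)
}

#' Estimate per-domain rates for a partitioned cohort
#'
#' Runs the chosen engine on every (gene, domain) subalignment.
#'
#' @param subalignments Tibble with `gene`, `domain`, `codon_a`, `codon_b`
#'   (as from [partition_cohort()]).
#' @param engine `"ng86"` or `"m0"`.
#' @param freqs Frequency model for the M0 engine.
#' @return Long tibble: `gene`, `domain`, `n_codons`, `dN`, `dS`, `omega`,
#'   `valid`, `engine`, plus `kappa`, `t`, `lnL` for M0.
#' @export
estimate_domain_rates <- function(subalignments, engine = c("ng86", "m0"),
                                  freqs = c("f3x4", "uniform")) {
  engine <- match.arg(engine)
  freqs <- match.arg(freqs)
  n <- nrow(subalignments)
  codon_a <- subalignments$codon_a
  codon_b <- subalignments$codon_b
  n_codons <- integer(n)
  dN <- dS <- omega <- kappa <- t_hat <- lnL <- rep(NA_real_, n)
  valid <- logical(n)
  for (k in seq_len(n)) {
    if (is.na(codon_a[k]) || nchar(codon_a[k]) == 0L) next
    if (engine == "ng86") {
      est <- ng86_stats(codon_a[k], codon_b[k])
      n_codons[k] <- est$n_codons_used
      dN[k] <- est$dN
      dS[k] <- est$dS
      omega[k] <- est$omega
      valid[k] <- est$valid
    } else {
      fit <- m0_fit(codon_a[k], codon_b[k], freqs = freqs)
      n_codons[k] <- fit$n_codons_used
      dN[k] <- fit$dN
      dS[k] <- fit$dS
      omega[k] <- fit$omega
      valid[k] <- fit$valid
      kappa[k] <- fit$kappa
      t_hat[k] <- fit$t
      lnL[k] <- fit$lnL
    }
  }
  out <- tibble(
    gene = subalignments$gene, domain = subalignments$domain,
    n_codons = n_codons, dN = dN, dS = dS, omega = omega, valid = valid
  )
  if (engine == "m0") {
    out$kappa <- kappa
    out$t <- t_hat
    out$lnL <- lnL
  }
  out$engine <- if (engine == "ng86") "NG86" else "M0"
  out
}

#' Remove genes or domains with dS = 0
#'
#' A synonymous divergence of zero makes omega infinite, so such estimates are
#' excluded. Under the default `"per-domain"` scope only the affected domain's
#' estimate is dropped; under `"whole-gene"` the gene is dropped from every
#' domain as soon as any domain with codons has `dS = 0` or an invalid
#' estimate. Domains with no codon columns are unused and do not penalise the
#' gene under either scope.
#'
#' @param rates Long rates tibble from [estimate_domain_rates()].
#' @param scope `"per-domain"` (default) or `"whole-gene"`.
#' @return The rates tibble restricted to usable rows.
#' @export
apply_ds_filter <- function(rates, scope = c("per-domain", "whole-gene")) {
  scope <- match.arg(scope)
  usable <- rates$valid & !is.na(rates$dS) & rates$dS > 0
  if (scope == "per-domain") {
    return(rates[usable, , drop = FALSE])
  }
  bad_genes <- unique(rates$gene[rates$n_codons > 0 & !usable])
  rates[usable & !(rates$gene %in% bad_genes), , drop = FALSE]
}
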