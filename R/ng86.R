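# Nei-Gojobori (1986) counting estimator of dN and dS with Jukes-Cantor
# multiple-hit correction. Site and path tables over the 61 sense codons are
# built once per session and cached.

#' Nonsynonymous and synonymous site counts of one codon
#'
#' Each of the nine single-nucleotide neighbours contributes one third of a
#' site to the synonymous or nonsynonymous class; neighbours that are stop
#' codons are excluded entirely, so the two counts sum to 3 minus the
#' stop-neighbour correction.
#'
#' @param codon A sense codon.
#' @return Named numeric vector `c(nonsyn_sites, syn_sites)`.
#' @export
ng86_sites <- function(codon) {
  code <- genetic_code()
  if (is.na(code[codon]) || code[codon] == "*") {
    abort(paste0("not a sense codon: ", codon))
  }
  aa <- code[[codon]]
  nts <- strsplit(codon, "")[[1]]
  syn <- 0
  nonsyn <- 0
  for (p in 1:3) {
    for (x in setdiff(NUC, nts[p])) {
      nb <- nts
      nb[p] <- x
      nb_codon <- paste(nb, collapse = "")
      if (code[[nb_codon]] == "*") next
      if (code[[nb_codon]] == aa) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
    }
  }
  c(nonsyn_sites = nonsyn, syn_sites = syn)
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons: equal-weight average over the minimal substitution paths that avoid
# stop codons (all paths if every ordering passes through a stop).
ng86_pair_differences <- function(codon_a, codon_b) {
  code <- genetic_code()
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  if (d == 0L) return(c(nonsyn_diffs = 0, syn_diffs = 0))
  perms <- permutations_of(diff_pos)
  count_path <- function(order) {
    cur <- a
    sd <- 0
    nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      c1 <- paste(cur, collapse = "")
      c2 <- paste(nxt, collapse = "")
      if (code[[c2]] == "*" && !identical(nxt, b)) return(NULL)
      if (code[[c1]] == code[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd, sd)
  }
  counts <- Filter(Negate(is.null), lapply(perms, count_path))
  if (length(counts) == 0L) {
    # no stop-free ordering: average over all orderings
    counts <- lapply(perms, function(o) {
      cur <- a
      sd <- 0
      nd <- 0
      for (p in o) {
        nxt <- cur
        nxt[p] <- b[p]
        if (code[[paste(cur, collapse = "")]] ==
            code[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd, sd)
    })
  }
  m <- colMeans(do.call(rbind, counts))
  c(nonsyn_diffs = m[1], syn_diffs = m[2])
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in permutations_of(x[-k])) out[[length(out) + 1L]] <- c(x[k], rest)
  }
  out
}

# cached site vectors and 61x61 difference matrices
ng86_tables <- function() {
  if (!is.null(the$ng86)) return(the$ng86)
  sc <- sense_codons()
  n <- length(sc)
  sites <- t(vapply(sc, ng86_sites, numeric(2)))
  nd <- matrix(0, n, n, dimnames = list(sc, sc))
  sd <- matrix(0, n, n, dimnames = list(sc, sc))
  pm <- codon_pair_masks()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (pm$ndiff[i, j] == 0L) next
      dd <- ng86_pair_differences(sc[i], sc[j])
      nd[i, j] <- dd[1]
      sd[i, j] <- dd[2]
    }
  }
  the$ng86 <- list(codons = sc, n_sites = sites[, 1], s_sites = sites[, 2],
                   nd = nd, sd = sd)
  the$ng86
}

#' NG86 estimate of dN, dS and omega for one pairwise codon alignment
#'
#' Codon columns with a gap, an ambiguity character or a stop codon in either
#' sequence are skipped (pairwise deletion). Differences at multi-hit codons
#' are averaged with equal weight over the minimal substitution paths through
#' sense codons. Proportions are corrected with the Jukes-Cantor transform
#' `d = -(3/4) log(1 - 4p/3)`. `dS = 0` (or an inapplicable correction) marks
#' the estimate invalid: omega would be undefined or infinite.
#'
#' @param codon_a,codon_b Gap-aligned CDS strings of equal length divisible
#'   by 3.
#' @return One-row tibble: `dN`, `dS`, `omega`, `N`, `S` (site counts), `Nd`,
#'   `Sd` (difference counts), `n_codons_used`, `valid`.
#' @export
ng86_estimate <- function(codon_a, codon_b) {
  as_tibble(ng86_stats(codon_a, codon_b))
}

# 64-entry map from base-4 codon rank (T=0, C=1, A=2, G=3) to sense-codon
# index (NA for stops)
ng86_lookup64 <- function() {
  if (is.null(the$lookup64)) {
    the$lookup64 <- match(names(genetic_code()), sense_codons())
  }
  the$lookup64
}

# plain-list workhorse behind ng86_estimate (compiled accumulation because it
# runs once per gene and domain over whole cohorts)
ng86_stats <- function(codon_a, codon_b) {
  tab <- ng86_tables()
  if (nchar(codon_a) != nchar(codon_b)) abort("alignment rows differ in length")
  if (nchar(codon_a) %% 3L != 0L) abort("alignment length must be a multiple of 3")
  ia <- cds_to_codon_indices_cpp(codon_a, ng86_lookup64())
  ib <- cds_to_codon_indices_cpp(codon_b, ng86_lookup64())
  acc <- ng86_accumulate_cpp(ia, ib, tab$n_sites, tab$s_sites, tab$nd, tab$sd)
  N <- acc[1]
  S <- acc[2]
  Nd <- acc[3]
  Sd <- acc[4]
  n_used <- as.integer(acc[5])
  if (n_used == 0L) {
    return(list(dN = NA_real_, dS = NA_real_, omega = NA_real_, N = 0, S = 0,
                Nd = 0, Sd = 0, n_codons_used = 0L, valid = FALSE))
  }
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dN <- if (N > 0) jc(Nd / N) else NA_real_
  dS <- if (S > 0) jc(Sd / S) else NA_real_
  valid <- !is.na(dN) && !is.na(dS) && dS > 0
  list(
    dN = dN, dS = dS, omega = if (valid) dN / dS else NA_real_,
    N = N, S = S, Nd = Nd, Sd = Sd, n_codons_used = n_used, valid = valid
  )
}
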