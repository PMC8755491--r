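# The statistical layer: Spearman correlations of per-domain omega with
# abundance, Fisher r-to-z comparison of two correlation coefficients, exact
# binomial ordering tests, abundance terciles, and multi-tissue sweeps.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks for ties; the coefficient is the Pearson correlation of the
#' rank vectors and the two-tailed p-value uses the t approximation with
#' n - 2 degrees of freedom. Inputs must already be pairwise-complete.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param label Optional description of the comparison.
#' @return One-row tibble: `label`, `rho`, `n`, `p_two_tailed`. A constant
#'   vector yields `rho = NA`.
#' @export
spearman_cor <- function(x, y, label = "") {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) abort("inputs must be pairwise-complete (no NA)")
  n <- length(x)
  if (n < 4) abort("need at least 4 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(tibble(label = label, rho = NA_real_, n = n,
                  p_two_tailed = NA_real_))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE, continuity = FALSE)
  )
  tibble(label = label, rho = unname(ct$estimate), n = n,
         p_two_tailed = ct$p.value)
}

#' Fisher r-to-z comparison of two correlation coefficients
#'
#' Independent-samples form:
#' `Z = (atanh(rho_1) - atanh(rho_2)) / sqrt(1/(n_1-3) + 1/(n_2-3))`, with
#' `p_one_tailed = Phi(Z)` (alternative `rho_1 < rho_2`) and
#' `p_two_tailed = 2 Phi(-|Z|)`. An optional Steiger-type correction for two
#' correlations sharing a variable and computed on the same sample is
#' available via `overlap_r12` (the correlation between the two omega
#' variables); the independent form is the default reporting convention.
#'
#' @param rho_1,rho_2 Correlation coefficients, strictly inside (-1, 1).
#' @param n_1,n_2 Sample sizes (>= 4).
#' @param comparison Optional description.
#' @param overlap_r12 If non-`NULL`, the correlation between the two
#'   correlated variables; the dependent-overlapping-correlations statistic
#'   is used (requires `n_1 == n_2`).
#' @return One-row tibble: `comparison`, `rho_1`, `n_1`, `rho_2`, `n_2`, `Z`,
#'   `p_one_tailed`, `p_two_tailed`.
#' @export
fisher_r_to_z <- function(rho_1, n_1, rho_2, n_2, comparison = "",
                          overlap_r12 = NULL) {
  for (r in c(rho_1, rho_2)) {
    if (is.na(r) || abs(r) >= 1) abort("correlations must lie strictly inside (-1, 1)")
  }
  if (n_1 < 4 || n_2 < 4) abort("sample sizes must be at least 4")
  if (is.null(overlap_r12)) {
    z <- (atanh(rho_1) - atanh(rho_2)) / sqrt(1 / (n_1 - 3) + 1 / (n_2 - 3))
  } else {
    if (n_1 != n_2) abort("overlapping-correlation form requires n_1 == n_2")
    n <- n_1
    r12 <- overlap_r12
    rbar <- (rho_1 + rho_2) / 2
    # Steiger (1980) Z for H0: rho_1 = rho_2 with a shared third variable
    psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
    sbar <- psi / (1 - rbar^2)^2
    z <- (atanh(rho_1) - atanh(rho_2)) * sqrt((n - 3) / (2 * (1 - sbar)))
  }
  tibble(
    comparison = comparison, rho_1 = rho_1, n_1 = as.integer(n_1),
    rho_2 = rho_2, n_2 = as.integer(n_2), Z = z,
    p_one_tailed = pnorm(z), p_two_tailed = 2 * pnorm(-abs(z))
  )
}

#' Exact binomial tail test
#'
#' `direction = "greater"` gives the exact upper tail `P(X >= k)`;
#' `direction = "two-sided"` sums the probabilities of all outcomes no more
#' likely than the observed one (the minimum-likelihood convention).
#'
#' @param k Successes observed.
#' @param n Trials.
#' @param null_p Null success probability, in (0, 1).
#' @param direction `"greater"` or `"two-sided"`.
#' @return One-row tibble: `k_success`, `n_trials`, `null_p`, `direction`,
#'   `p_value`.
#' @export
binomial_test <- function(k, n, null_p, direction = c("greater", "two-sided")) {
  direction <- match.arg(direction)
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  if (null_p <= 0 || null_p >= 1) abort("null_p must be in (0, 1)")
  alt <- if (direction == "greater") "greater" else "two.sided"
  p <- stats::binom.test(k, n, p = null_p, alternative = alt)$p.value
  tibble(k_success = as.integer(k), n_trials = as.integer(n), null_p = null_p,
         direction = direction, p_value = p)
}

# wide per-gene omega table (omega_i / omega_t / omega_e columns; a domain's
# value is NA when the gene did not pass its filters)
rates_to_wide <- function(rates) {
  rates |>
    select("gene", "domain", "omega") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "omega",
                       names_prefix = "omega_")
}

#' Ordering statistics among the per-domain omegas
#'
#' Counts, over genes with all compared domains available, how often
#' `omega_e > omega_i` (tested against 1/2, two-sided) and how often
#' `omega_t < min(omega_i, omega_e)` (tested against 1/3, upper tail). Ties
#' count as failures.
#'
#' @param rates Filtered long rates tibble (see [apply_ds_filter()]).
#' @return Tibble of [binomial_test()] rows with a `comparison` column.
#' @export
ordering_fractions <- function(rates) {
  wide <- rates_to_wide(rates)
  out <- list()
  pair <- wide |> filter(!is.na(.data$omega_i), !is.na(.data$omega_e))
  if (nrow(pair) > 0) {
    out$pair <- binomial_test(sum(pair$omega_e > pair$omega_i), nrow(pair),
                              1 / 2, "two-sided") |>
      mutate(comparison = "omega_e > omega_i")
  }
  if ("omega_t" %in% names(wide)) {
    trip <- wide |> filter(!is.na(.data$omega_i), !is.na(.data$omega_t),
                           !is.na(.data$omega_e))
    if (nrow(trip) > 0) {
      k <- sum(trip$omega_t < pmin(trip$omega_i, trip$omega_e))
      out$trip <- binomial_test(k, nrow(trip), 1 / 3, "greater") |>
        mutate(comparison = "omega_t < min(omega_i, omega_e)")
    }
  }
  bind_rows(out) |> select("comparison", everything())
}

#' Fraction of genes with omega_e > omega_i within abundance terciles
#'
#' Genes are ranked by abundance (stable order for ties) and cut into three
#' bins; when n is not divisible by 3 the extra genes go to the lowest bins
#' first (n = 10 gives bins of 4/3/3).
#'
#' @param rates Filtered long rates tibble.
#' @param abundances Tibble with `gene`, `abundance`.
#' @return Tibble with `bin` (`low`/`mid`/`high`), `n`, `k` (genes with
#'   `omega_e > omega_i`) and `percent`.
#' @export
abundance_terciles <- function(rates, abundances) {
  wide <- rates_to_wide(rates) |>
    inner_join(abundances[, c("gene", "abundance")], by = "gene") |>
    filter(!is.na(.data$omega_i), !is.na(.data$omega_e),
           .data$abundance > 0)
  n <- nrow(wide)
  if (n < 3) abort("need at least 3 genes with both omegas and abundance")
  base <- n %/% 3L
  extra <- n %% 3L
  sizes <- base + c(extra >= 1L, extra >= 2L, 0L)
  ord <- order(wide$abundance)  # stable for ties
  bin <- rep(c("low", "mid", "high"), times = sizes)
  wide$bin <- NA_character_
  wide$bin[ord] <- bin
  wide |>
    group_by(bin = factor(.data$bin, levels = c("low", "mid", "high"))) |>
    summarise(n = dplyr::n(), k = sum(.data$omega_e > .data$omega_i),
              .groups = "drop") |>
    mutate(percent = 100 * .data$k / .data$n)
}

#' Average abundances across tissues per gene
#'
#' Arithmetic mean over the contexts in which each gene is measured; missing
#' tissues are dropped, not treated as zero. Genes with no measured context
#' do not appear.
#'
#' @param abundance_long Tibble with `gene`, `context`, `abundance`.
#' @return Tibble with `gene`, `abundance` (the mean).
#' @export
average_across_tissues <- function(abundance_long) {
  abundance_long |>
    group_by(.data$gene) |>
    summarise(abundance = mean(.data$abundance), .groups = "drop")
}

#' Per-domain expression-rate correlations on one abundance vector
#'
#' For each domain, the Spearman correlation between omega and abundance
#' (rank-based, so any monotone transform of abundance gives the same result)
#' over the genes with a usable omega and a positive abundance (zero
#' abundance is treated as below detection, i.e. missing).
#'
#' @param rates Filtered long rates tibble.
#' @param abundances Tibble with `gene`, `abundance`.
#' @param abundance_label Name of the abundance variable for labels.
#' @return Tibble of [spearman_cor()] rows, one per domain present, with a
#'   `domain` column.
#' @export
domain_correlations <- function(rates, abundances,
                                abundance_label = "abundance") {
  joined <- rates |>
    inner_join(abundances[, c("gene", "abundance")], by = "gene") |>
    filter(!is.na(.data$omega), .data$abundance > 0)
  doms <- intersect(c("i", "t", "e"), unique(joined$domain))
  bind_rows(lapply(doms, function(d) {
    sub <- joined |> filter(.data$domain == d)
    spearman_cor(sub$omega, sub$abundance,
                 label = paste0("omega_", d, " vs ", abundance_label)) |>
      mutate(domain = d)
  }))
}

#' Per-tissue correlation sweep with intermediacy counts
#'
#' For each tissue, the three domain correlations on that tissue's gene set,
#' the intermediacy indicator `min(rho_i, rho_e) < rho_t < max(rho_i, rho_e)`
#' and, across tissues, a binomial test of the intermediacy count against a
#' null probability of 1/3.
#'
#' @param rates Filtered long rates tibble.
#' @param tissue_abundances Tibble with `gene`, `context` (tissue),
#'   `abundance`.
#' @return List with `per_tissue` (tibble: `tissue`, `rho_i`, `rho_t`,
#'   `rho_e`, `n`, `intermediate`) and `intermediacy_test` (a
#'   [binomial_test()] row, `NULL` when omega_t is absent).
#' @export
tissue_sweep <- function(rates, tissue_abundances) {
  tissues <- sort(unique(tissue_abundances$context))
  if (length(tissues) == 0) abort("no tissues in abundance table")
  rows <- lapply(tissues, function(ts) {
    ab <- tissue_abundances |>
      filter(.data$context == ts) |>
      select("gene", "abundance")
    cors <- domain_correlations(rates, ab, abundance_label = ts)
    rho <- setNames(rep(NA_real_, 3), c("i", "t", "e"))
    nn <- setNames(rep(NA_integer_, 3), c("i", "t", "e"))
    rho[cors$domain] <- cors$rho
    nn[cors$domain] <- cors$n
    inter <- if (anyNA(rho)) NA else
      min(rho["i"], rho["e"]) < rho["t"] & rho["t"] < max(rho["i"], rho["e"])
    tibble(tissue = ts, rho_i = rho[["i"]], rho_t = rho[["t"]],
           rho_e = rho[["e"]],
           n = if (all(is.na(nn))) NA_integer_ else max(nn, na.rm = TRUE),
           intermediate = as.logical(inter))
  })
  per_tissue <- bind_rows(rows)
  test <- NULL
  if (!all(is.na(per_tissue$intermediate))) {
    done <- per_tissue |> filter(!is.na(.data$intermediate))
    test <- binomial_test(sum(done$intermediate), nrow(done), 1 / 3, "greater")
  }
  list(per_tissue = per_tissue, intermediacy_test = test)
}

#' Compare the domain E-R correlations with Fisher r-to-z tests
#'
#' Emits the pairwise comparisons (i vs e, i vs t, t vs e) for the domains
#' present in a [domain_correlations()] table.
#'
#' @param correlations Output of [domain_correlations()].
#' @return Tibble of [fisher_r_to_z()] rows.
#' @export
compare_domain_correlations <- function(correlations) {
  get <- function(d) correlations[correlations$domain == d, ]
  pairs <- list(c("i", "e"), c("i", "t"), c("t", "e"))
  out <- list()
  for (p in pairs) {
    a <- get(p[1])
    b <- get(p[2])
    if (nrow(a) == 1 && nrow(b) == 1 && !is.na(a$rho) && !is.na(b$rho)) {
      out[[paste(p, collapse = "")]] <- fisher_r_to_z(
        a$rho, a$n, b$rho, b$n,
        comparison = paste0("omega_", p[1], " vs omega_", p[2])
      )
    }
  }
  bind_rows(out)
}
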