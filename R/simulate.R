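# Synthetic ortholog cohorts: codon pairs evolved under domain-specific omega,
# membrane topologies, and abundances with a controllable rank correlation to
# each domain's omega. Ground truth for validating the estimation pipeline.

#' Configuration for a synthetic ortholog cohort
#'
#' Builds and validates the parameter set for [sample_cohort()]. Gene-level
#' omegas vary log-normally around the configured per-domain targets, and a
#' Gaussian copula links log-abundance to each domain's log-omega at the
#' requested Spearman correlations (the Pearson parameter is obtained by
#' inverting rho_S = (6/pi) asin(r/2)).
#'
#' @param n_genes Number of ortholog pairs.
#' @param domain_architecture Data frame with columns `label` (one of
#'   `"inside"`, `"TMhelix"`, `"outside"`) and `length` (residues), in
#'   N-to-C order, or a function of the gene index returning one. Must contain
#'   at least one inside and one outside segment.
#' @param kappa Transition/transversion rate ratio.
#' @param t Total divergence between the two orthologs, in expected
#'   substitutions per codon (split symmetrically, `t/2` per lineage).
#' @param omega_i,omega_t,omega_e Median dN/dS for intracellular,
#'   transmembrane and extracellular codons.
#' @param sigma_log_omega Standard deviation of gene-level log-omega around
#'   each domain median.
#' @param target_rho_i,target_rho_e Desired Spearman correlation between
#'   log-abundance and the gene's true omega_i (resp. omega_e), in (-1, 1).
#' @param target_rho_t Same for omega_t; defaults to the midpoint of the
#'   intracellular and extracellular targets (the intermediacy seen in real
#'   transmembrane proteins).
#' @param rho_omega Rank correlation among the three domain omegas of a gene.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   integrated abundance (natural log of ppm).
#' @param n_tissues Number of per-tissue abundance columns to emit (0 = only
#'   the integrated abundance).
#' @param tissue_sdlog Log-scale noise added independently per tissue.
#' @param n_missing_domain Number of extra genes whose species-B topology has
#'   its extracellular segments relabelled intracellular, so the
#'   both-domains-in-both-species retention filter must drop them.
#' @param seed Integer root seed; per-gene substreams are derived from it so
#'   results do not depend on iteration order.
#' @return A list of class `"domainer_sim_config"`.
#' @export
simulation_config <- function(n_genes = 500,
                              domain_architecture = default_architecture(),
                              kappa = 2,
                              t = 0.6,
                              omega_i = 0.15,
                              omega_t = 0.10,
                              omega_e = 0.25,
                              sigma_log_omega = 0.6,
                              target_rho_i = -0.3,
                              target_rho_e = 0,
                              target_rho_t = (target_rho_i + target_rho_e) / 2,
                              rho_omega = 0.45,
                              abundance_meanlog = 3,
                              abundance_sdlog = 2,
                              n_tissues = 0,
                              tissue_sdlog = 0.75,
                              n_missing_domain = 0,
                              seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    domain_architecture = domain_architecture,
    kappa = kappa, t = t,
    omega_i = omega_i, omega_t = omega_t, omega_e = omega_e,
    sigma_log_omega = sigma_log_omega,
    target_rho_i = target_rho_i, target_rho_e = target_rho_e,
    target_rho_t = target_rho_t, rho_omega = rho_omega,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    n_tissues = as.integer(n_tissues), tissue_sdlog = tissue_sdlog,
    n_missing_domain = as.integer(n_missing_domain),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L) abort("`n_genes` must be >= 1")
  if (cfg$kappa < 0 || cfg$t < 0) abort("`kappa` and `t` must be non-negative")
  for (f in c("omega_i", "omega_t", "omega_e")) {
    if (cfg[[f]] < 0) abort(paste0("`", f, "` must be non-negative"))
  }
  for (f in c("target_rho_i", "target_rho_e", "target_rho_t")) {
    r <- cfg[[f]]
    if (abs(r) > 1) abort(paste0("`", f, "` must lie in [-1, 1]"))
    if (abs(r) == 1 && cfg$sigma_log_omega > 0) {
      abort(paste0("|", f, "| = 1 is inconsistent with nondegenerate omega noise"))
    }
  }
  if (!is.function(cfg$domain_architecture)) {
    validate_architecture(cfg$domain_architecture)
  }
  class(cfg) <- "domainer_sim_config"
  cfg
}

#' Default single-pass transmembrane architecture
#'
#' An 80-residue intracellular segment, a 21-residue transmembrane helix and
#' an 80-residue extracellular segment.
#' @return Data frame with columns `label` and `length`.
#' @export
default_architecture <- function() {
  tibble(
    label = c("inside", "TMhelix", "outside"),
    length = c(80L, 21L, 80L)
  )
}

validate_architecture <- function(arch) {
  if (!all(c("label", "length") %in% names(arch))) {
    abort("architecture needs columns `label` and `length`")
  }
  if (!all(arch$label %in% c("inside", "TMhelix", "outside"))) {
    abort("architecture labels must be inside/TMhelix/outside")
  }
  if (any(arch$length < 1)) abort("architecture segment lengths must be >= 1")
  if (!("inside" %in% arch$label) || !("outside" %in% arch$label)) {
    abort("architecture must contain at least one inside and one outside segment")
  }
  invisible(arch)
}

# Pearson correlation of a Gaussian copula that yields Spearman rho_s
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Correlation matrix over (log-abundance, log omega_i, log omega_t, log
# omega_e) on the Gaussian-copula scale.
copula_correlation <- function(cfg) {
  r_ai <- spearman_to_pearson(cfg$target_rho_i)
  r_at <- spearman_to_pearson(cfg$target_rho_t)
  r_ae <- spearman_to_pearson(cfg$target_rho_e)
  r_oo <- spearman_to_pearson(cfg$rho_omega)
  m <- matrix(c(
    1,    r_ai, r_at, r_ae,
    r_ai, 1,    r_oo, r_oo,
    r_at, r_oo, 1,    r_oo,
    r_ae, r_oo, r_oo, 1
  ), 4, 4, byrow = TRUE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort("requested rank-correlation targets are not jointly attainable (copula matrix not positive definite)")
  }
  m
}

# Deterministic per-gene substream seed below 2^31, derived by integer hashing
# of (root seed, gene index) so evolution is order-independent.
gene_substream_seed <- function(seed, idx) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(idx) * 69621 + 7919
  as.integer(x %% 2147483629)
}

#' Evolve one ortholog codon pair from a common ancestor
#'
#' Each lineage evolves independently for `t/2` using per-site transition
#' probabilities `exp(Q t/2)`; no indels are introduced.
#'
#' @param ancestral_codons Character vector of sense codons.
#' @param generator Rate matrix from [build_m0_generator()].
#' @param t Total divergence in expected substitutions per codon.
#' @return List with elements `cds_a` and `cds_b` (CDS strings).
#' @export
evolve_pair <- function(ancestral_codons, generator, t) {
  if (t < 0) abort("`t` must be non-negative")
  sc <- rownames(generator)
  anc <- match(ancestral_codons, sc)
  if (anyNA(anc)) abort("ancestral codons must be sense codons")
  if (t == 0) {
    s <- paste(ancestral_codons, collapse = "")
    return(list(cds_a = s, cds_b = s))
  }
  pi <- stationary_frequencies(generator)
  p_half <- gy94_prob_from_eigen(gy94_eigen(generator, pi), t / 2)
  cp <- p_half %*% (upper.tri(diag(length(sc)), diag = TRUE) * 1)
  list(
    cds_a = paste(sc[sample_rows(cp, anc)], collapse = ""),
    cds_b = paste(sc[sample_rows(cp, anc)], collapse = "")
  )
}

# stationary distribution of a reversible generator built by
# build_m0_generator: recoverable from detailed balance pi_i q_ij = pi_j q_ji
stationary_frequencies <- function(q) {
  pi <- attr(q, "codon_frequencies")
  if (!is.null(pi)) return(as.numeric(pi))
  e <- eigen(t(q))
  v <- Re(e$vectors[, which.min(abs(e$values))])
  abs(v) / sum(abs(v))
}

# inverse-CDF categorical sampling: row i of cum_probs is the cumulative
# distribution for ancestral state anc[i]
sample_rows <- function(cum_probs, anc) {
  u <- runif(length(anc))
  rowSums(cum_probs[anc, , drop = FALSE] < u) + 1L
}

#' Simulate a synthetic ortholog cohort with known per-domain omega
#'
#' Draws gene-level omegas and abundances from the configured copula, then
#' evolves an indel-free CDS pair for every gene, segment by segment, with the
#' gene's domain-specific omega. Both species share the same topology except
#' for the optional missing-domain genes.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"synthetic_cohort"` with elements
#'   * `genes`: tibble with `gene`, `abundance`, true `omega_i`, `omega_t`,
#'     `omega_e`, `cds_a`, `cds_b`, `retain_expected`;
#'   * `topology_a`, `topology_b`: segment tibbles (`gene`, `label`, `start`,
#'     `end`);
#'   * `tissues`: tibble of per-tissue abundances (empty if `n_tissues = 0`);
#'   * `config`: the input configuration.
#' @export
sample_cohort <- function(config) {
  cfg <- if (inherits(config, "domainer_sim_config")) config else
    do.call(simulation_config, config)
  n_main <- cfg$n_genes
  n_all <- n_main + cfg$n_missing_domain
  corr <- copula_correlation(cfg)
  ch <- chol(corr)

  set.seed(cfg$seed)
  z <- matrix(rnorm(n_all * 4), n_all, 4) %*% ch
  abundance <- exp(cfg$abundance_meanlog + cfg$abundance_sdlog * z[, 1])
  omega <- cbind(
    i = cfg$omega_i * exp(cfg$sigma_log_omega * z[, 2]),
    t = cfg$omega_t * exp(cfg$sigma_log_omega * z[, 3]),
    e = cfg$omega_e * exp(cfg$sigma_log_omega * z[, 4])
  )
  tissue_noise <- if (cfg$n_tissues > 0) {
    matrix(rnorm(n_all * cfg$n_tissues, sd = cfg$tissue_sdlog),
           n_all, cfg$n_tissues)
  }
  archs <- lapply(seq_len(n_all), function(g) {
    a <- if (is.function(cfg$domain_architecture)) {
      cfg$domain_architecture(g)
    } else {
      cfg$domain_architecture
    }
    validate_architecture(a)
  })

  sc <- sense_codons()
  n_codon_states <- length(sc)
  ix <- gy94_index()
  ut <- upper.tri(diag(n_codon_states), diag = TRUE) * 1  # row-cumsum operator
  gene_ids <- sprintf("g%05d", seq_len(n_all))
  class_of <- c(inside = "i", TMhelix = "t", outside = "e")

  cds_a_vec <- character(n_all)
  cds_b_vec <- character(n_all)
  topo_gene <- vector("list", n_all)
  for (g in seq_len(n_all)) {
    arch <- archs[[g]]
    set.seed(gene_substream_seed(cfg$seed, g))
    parts_a <- character(nrow(arch))
    parts_b <- character(nrow(arch))
    p_cache <- list()
    for (s in seq_len(nrow(arch))) {
      cls <- class_of[[arch$label[s]]]
      len <- arch$length[s]
      anc <- sample.int(n_codon_states, len, replace = TRUE)
      cp <- p_cache[[cls]]
      if (is.null(cp)) {
        if (cfg$t == 0) {
          cp <- ut
        } else {
          # uniform frequencies make the scaled generator symmetric, so the
          # compiled kernel can use a plain symmetric eigendecomposition
          cp <- gy94_cum_pmatrix_cpp(cfg$kappa, omega[g, cls], cfg$t / 2,
                                     n_codon_states, ix$syn_tv, ix$syn_ts,
                                     ix$non_tv, ix$non_ts)
        }
        p_cache[[cls]] <- cp
      }
      parts_a[s] <- paste(sc[sample_codons_cpp(anc, cp)], collapse = "")
      parts_b[s] <- paste(sc[sample_codons_cpp(anc, cp)], collapse = "")
    }
    ends <- as.integer(cumsum(arch$length))
    topo_gene[[g]] <- list(label = arch$label, end = ends)
    cds_a_vec[g] <- paste(parts_a, collapse = "")
    cds_b_vec[g] <- paste(parts_b, collapse = "")
  }

  genes_tbl <- tibble(
    gene = gene_ids,
    abundance = abundance,
    omega_i = omega[, "i"], omega_t = omega[, "t"], omega_e = omega[, "e"],
    retain_expected = seq_len(n_all) <= n_main,
    cds_a = cds_a_vec, cds_b = cds_b_vec
  )

  seg_counts <- vapply(topo_gene, function(x) length(x$end), integer(1))
  topology_a <- tibble(
    gene = rep(gene_ids, seg_counts),
    label = unlist(lapply(topo_gene, `[[`, "label")),
    end = unlist(lapply(topo_gene, `[[`, "end"))
  ) |>
    group_by(.data$gene) |>
    mutate(start = c(1L, head(.data$end, -1) + 1L)) |>
    ungroup() |>
    select("gene", "label", "start", "end")
  topology_b <- topology_a
  if (cfg$n_missing_domain > 0) {
    drop_ids <- gene_ids[(n_main + 1):n_all]
    topology_b <- topology_b |>
      mutate(label = ifelse(.data$gene %in% drop_ids &
                              .data$label == "outside", "inside", .data$label))
    topology_b <- merge_adjacent_segments(topology_b)
  }

  tissues <- if (cfg$n_tissues > 0) {
    tidyr::expand_grid(gene = gene_ids, tissue = sprintf("tissue%02d", seq_len(cfg$n_tissues))) |>
      arrange(.data$tissue, .data$gene) |>
      mutate(abundance = exp(log(rep(abundance, times = cfg$n_tissues)) +
                               as.vector(tissue_noise)))
  } else {
    tibble(gene = character(), tissue = character(), abundance = numeric())
  }

  structure(
    list(genes = genes_tbl, topology_a = topology_a, topology_b = topology_b,
         tissues = tissues, config = cfg),
    class = "synthetic_cohort"
  )
}

# collapse runs of equal labels within a gene into single segments
merge_adjacent_segments <- function(topology) {
  topology |>
    group_by(.data$gene) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(run = cumsum(c(TRUE, .data$label[-1] != .data$label[-dplyr::n()]))) |>
    group_by(.data$gene, .data$run) |>
    summarise(label = .data$label[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop") |>
    select("gene", "label", "start", "end") |>
    arrange(.data$gene, .data$start)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits CDS FASTA files for both species, per-species topology TSVs, an
#' abundance TSV (integrated column plus any tissues) and a ground-truth TSV.
#'
#' @param cohort A [sample_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- cohort$genes
  write_fasta(tibble(id = g$gene, seq = g$cds_a), file.path(dir, "cds_a.fasta"))
  write_fasta(tibble(id = g$gene, seq = g$cds_b), file.path(dir, "cds_b.fasta"))
  write_topology(cohort$topology_a, file.path(dir, "topology_a.tsv"))
  write_topology(cohort$topology_b, file.path(dir, "topology_b.tsv"))
  ab <- tibble(gene = g$gene, integrated = g$abundance)
  if (nrow(cohort$tissues) > 0) {
    wide <- tidyr::pivot_wider(cohort$tissues, names_from = "tissue",
                               values_from = "abundance")
    ab <- left_join(ab, wide, by = "gene")
  }
  readr::write_tsv(ab, file.path(dir, "abundance.tsv"), progress = FALSE)
  readr::write_tsv(
    g |> select("gene", "abundance", "omega_i", "omega_t", "omega_e",
                "retain_expected"),
    file.path(dir, "truth.tsv"), progress = FALSE
  )
  invisible(dir)
}
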