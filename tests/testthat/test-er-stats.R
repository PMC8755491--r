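test_that("Spearman correlation matches the rank-then-Pearson definition", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_cor(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  set.seed(17)
  for (r in 1:10) {
    x <- sample(1:6, 12, replace = TRUE)  # guaranteed ties
    y <- rnorm(12) + x / 3
    expect_equal(spearman_cor(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }

  const <- spearman_cor(rep(2, 6), rnorm(6))
  expect_true(is.na(const$rho))
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("Fisher r-to-z reproduces the printed worked examples", {
  human <- fisher_r_to_z(-0.124, 3308, -0.041, 3308)
  expect_equal(round(human$Z, 2), -3.40)
  expect_equal(signif(human$p_one_tailed, 1), 3e-4)

  yeast <- fisher_r_to_z(-0.049, 829, 0.049, 829)
  expect_lt(abs(yeast$Z - (-2.00)), 0.01)

  # equality gives Z = 0 and a one-tailed probability of one half
  eq <- fisher_r_to_z(0.3, 50, 0.3, 80)
  expect_equal(eq$Z, 0)
  expect_equal(eq$p_one_tailed, 0.5)
})

test_that("Fisher r-to-z is antisymmetric and rejects degenerate input", {
  set.seed(23)
  for (r in 1:10) {
    r1 <- runif(1, -0.9, 0.9)
    r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(10:500, 1)
    n2 <- sample(10:500, 1)
    expect_equal(fisher_r_to_z(r1, n1, r2, n2)$Z,
                 -fisher_r_to_z(r2, n2, r1, n1)$Z)
  }
  expect_error(fisher_r_to_z(1, 100, 0.2, 100), "inside")
  expect_error(fisher_r_to_z(0.2, 3, 0.1, 100), "at least 4")
})

test_that("exact binomial tails match closed forms and are monotone in k", {
  expect_equal(binomial_test(10, 10, 0.5, "greater")$p_value, 0.5^10)
  expect_equal(binomial_test(0, 7, 0.3, "greater")$p_value, 1)

  p_prev <- 1.1
  for (k in 0:15) {
    p <- binomial_test(k, 15, 1 / 3, "greater")$p_value
    expect_lt(p, p_prev)
    p_prev <- p
  }
  expect_error(binomial_test(5, 4, 0.5), "\\[0, n\\]")
})

test_that("omega ordering counts treat ties as failures", {
  rates <- tibble::tibble(
    gene = rep(c("g1", "g2", "g3"), each = 3),
    domain = rep(c("i", "t", "e"), 3),
    n_codons = 50L, dN = 0.1,
    dS = 0.2,
    omega = c(0.2, 0.1, 0.5,   0.3, 0.05, 0.4,   0.3, 0.2, 0.3),
    valid = TRUE, engine = "NG86"
  )
  ord <- ordering_fractions(rates)
  pair <- ord[ord$comparison == "omega_e > omega_i", ]
  expect_equal(pair$k_success, 2L)  # the tie in g3 is a failure
  expect_equal(pair$n_trials, 3L)
  trip <- ord[ord$comparison == "omega_t < min(omega_i, omega_e)", ]
  expect_equal(trip$k_success, 3L)

  # a cohort simulated with a strongly constrained membrane domain puts
  # omega_t lowest in nearly every gene
  co <- sample_cohort(simulation_config(
    n_genes = 150, omega_t = 0.02, omega_i = 0.3, omega_e = 0.3,
    sigma_log_omega = 0.2, seed = 91
  ))
  res <- analyse_cohort(co)
  ord2 <- ordering_fractions(res$filtered)
  trip2 <- ord2[ord2$comparison == "omega_t < min(omega_i, omega_e)", ]
  expect_gt(trip2$k_success / trip2$n_trials, 0.9)
  expect_lt(trip2$p_value, 1e-10)
})

test_that("abundance terciles cut by rank with the stated remainder rule", {
  mk_rates <- function(n, omega_i, omega_e) tibble::tibble(
    gene = rep(sprintf("g%03d", 1:n), each = 2),
    domain = rep(c("i", "e"), n),
    n_codons = 50L, dN = 0.1, dS = 0.2,
    omega = as.vector(rbind(omega_i, omega_e)),
    valid = TRUE, engine = "NG86"
  )
  set.seed(41)
  ab9 <- tibble::tibble(gene = sprintf("g%03d", 1:9), abundance = 9:1)
  terc9 <- abundance_terciles(mk_rates(9, runif(9), runif(9)), ab9)
  expect_equal(terc9$n, c(3L, 3L, 3L))

  ab10 <- tibble::tibble(gene = sprintf("g%03d", 1:10), abundance = 1:10)
  terc10 <- abundance_terciles(mk_rates(10, runif(10), runif(10)), ab10)
  expect_equal(terc10$n, c(4L, 3L, 3L))
  expect_equal(terc10$bin, factor(c("low", "mid", "high"),
                                  levels = c("low", "mid", "high")))

  # abundance-independent omegas: per-bin fractions sit near the global one
  n <- 1200
  oi <- runif(n)
  oe <- runif(n)
  ab <- tibble::tibble(gene = sprintf("g%03d", 1:n),
                       abundance = exp(rnorm(n)))
  terc <- abundance_terciles(mk_rates(n, oi, oe), ab)
  global_frac <- sum(oe > oi) / n
  for (b in 1:3) {
    se <- sqrt(global_frac * (1 - global_frac) / terc$n[b])
    expect_lt(abs(terc$k[b] / terc$n[b] - global_frac), 3 * se)
  }
})

test_that("tissue averaging drops missing tissues rather than zero-filling", {
  long <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g2", "g2"),
    context = c("liver", "brain", "liver", "brain", "lung"),
    abundance = c(2, 4, 3, 6, NA_real_)
  )
  long <- long[!is.na(long$abundance), ]
  avg <- average_across_tissues(long)
  expect_equal(avg$abundance[avg$gene == "g1"], 3)
  expect_equal(avg$abundance[avg$gene == "g2"], 4.5)

  # dense case equals matrix row means
  set.seed(52)
  mat <- matrix(rexp(30), nrow = 6,
                dimnames = list(sprintf("g%d", 1:6), sprintf("t%d", 1:5)))
  dense <- tibble::tibble(
    gene = rep(rownames(mat), 5),
    context = rep(colnames(mat), each = 6),
    abundance = as.vector(mat)
  )
  avg2 <- average_across_tissues(dense)
  expect_equal(avg2$abundance[match(rownames(mat), avg2$gene)],
               unname(rowMeans(mat)))
})

test_that("the tissue sweep matches a scalar per-tissue recomputation", {
  set.seed(63)
  n <- 120
  genes <- sprintf("g%03d", 1:n)
  omega_i <- exp(rnorm(n, log(0.2), 0.5))
  omega_t <- exp(rnorm(n, log(0.1), 0.5))
  omega_e <- exp(rnorm(n, log(0.3), 0.5))
  rates <- tibble::tibble(
    gene = rep(genes, each = 3), domain = rep(c("i", "t", "e"), n),
    n_codons = 50L, dN = 0.1, dS = 0.2,
    omega = as.vector(rbind(omega_i, omega_t, omega_e)),
    valid = TRUE, engine = "NG86"
  )
  shared <- rnorm(n)
  tissues <- sprintf("tissue%02d", 1:10)
  tab <- tidyr::expand_grid(gene = genes, context = tissues)
  tab$abundance <- exp(rep(shared, each = 10) + rnorm(nrow(tab), sd = 0.4) -
                         0.8 * rep(log(omega_i), each = 10))
  sweep <- tissue_sweep(rates, tab)
  expect_equal(nrow(sweep$per_tissue), 10)
  for (ts in tissues) {
    sub <- tab[tab$context == ts, ]
    row <- sweep$per_tissue[sweep$per_tissue$tissue == ts, ]
    expect_equal(row$rho_i,
                 oracle_spearman(omega_i, sub$abundance[match(genes, sub$gene)]),
                 tolerance = 1e-12)
    expect_equal(row$rho_e,
                 oracle_spearman(omega_e, sub$abundance[match(genes, sub$gene)]),
                 tolerance = 1e-12)
    expect_equal(row$intermediate,
                 min(row$rho_i, row$rho_e) < row$rho_t &
                   row$rho_t < max(row$rho_i, row$rho_e))
  }
  k <- sum(sweep$per_tissue$intermediate)
  expect_equal(sweep$intermediacy_test$k_success, k)
  expect_equal(sweep$intermediacy_test$p_value,
               stats::binom.test(k, 10, 1 / 3, "greater")$p.value)

  # single-tissue intermediacy predicate
  one <- tissue_sweep(rates, tab[tab$context == "tissue01", ])
  expect_equal(nrow(one$per_tissue), 1)
})

test_that("intermediacy is strict betweenness", {
  rates <- tibble::tibble(
    gene = rep(sprintf("g%02d", 1:20), each = 3),
    domain = rep(c("i", "t", "e"), 20), n_codons = 10L,
    dN = 0.1, dS = 0.2,
    omega = runif(60), valid = TRUE, engine = "NG86"
  )
  # construct abundances so rho_t falls below both (not intermediate)
  wide <- tidyr::pivot_wider(rates[, c("gene", "domain", "omega")],
                             names_from = "domain", values_from = "omega")
  ab <- tibble::tibble(gene = wide$gene, context = "t1",
                       abundance = rank(-wide$t) + runif(20, 0, 0.1))
  sw <- tissue_sweep(rates, ab)
  expect_false(sw$per_tissue$intermediate[1])
})
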