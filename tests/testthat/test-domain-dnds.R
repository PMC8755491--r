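test_that("NG86 site counts match exhaustive neighbour enumeration", {
  s <- ng86_sites("TTT")
  o <- oracle_ng86_sites("TTT")
  expect_equal(unname(s["syn_sites"]), unname(o["syn"]))
  expect_equal(unname(s["nonsyn_sites"]), unname(o["nonsyn"]))

  # Met has no synonymous neighbour
  expect_equal(unname(ng86_sites("ATG")["syn_sites"]), 0)

  # all 61 sense codons: totals equal 3 minus the stop-neighbour correction
  for (codon in sense_codons()) {
    s <- ng86_sites(codon)
    o <- oracle_ng86_sites(codon)
    expect_equal(unname(s["syn_sites"]), unname(o["syn"]), tolerance = 1e-12)
    expect_equal(unname(s["nonsyn_sites"]), unname(o["nonsyn"]),
                 tolerance = 1e-12)
    expect_lte(sum(s), 3 + 1e-12)
  }
  expect_error(ng86_sites("TAA"), "sense")
})

test_that("NG86 pairwise estimates follow the counting definitions", {
  ident <- ng86_estimate("AAACCC", "AAACCC")
  expect_equal(ident$dN, 0)
  expect_equal(ident$dS, 0)
  expect_false(ident$valid)

  lys <- ng86_estimate("AAA", "AAG")
  expect_equal(lys$Sd, 1)
  expect_equal(lys$Nd, 0)
})

test_that("NG86 counts equal the path-enumeration oracle on random alignments", {
  set.seed(61)
  for (r in 1:50) {
    ca <- random_cds(30)
    cb <- random_cds(30)
    est <- ng86_estimate(ca, cb)
    orc <- oracle_ng86_alignment(ca, cb)
    expect_equal(est$N, orc$N, tolerance = 1e-10)
    expect_equal(est$S, orc$S, tolerance = 1e-10)
    expect_equal(est$Nd, orc$Nd, tolerance = 1e-10)
    expect_equal(est$Sd, orc$Sd, tolerance = 1e-10)
    expect_equal(est$n_codons_used, orc$used)
  }
})

test_that("gapped and ambiguous codon pairs are skipped pairwise", {
  est <- ng86_estimate("AAA---CCN", "AAGCCC---")
  expect_equal(est$n_codons_used, 1L)
  expect_equal(est$Sd, 1)
})

test_that("M0 transition matrices are stochastic and match a series oracle", {
  p0 <- m0_transition_matrix(2, 0.5, t = 0)
  expect_equal(unname(p0), diag(61), tolerance = 1e-10)

  set.seed(83)
  for (r in 1:5) {
    kappa <- runif(1, 0.5, 6)
    omega <- runif(1, 0.05, 2)
    t <- runif(1, 0.01, 0.8)
    p <- m0_transition_matrix(kappa, omega, t = t)
    expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
    q <- build_m0_generator(kappa, omega)
    expect_lt(max(abs(p - oracle_expm_taylor(unclass(q), t))), 1e-8)
  }
})

test_that("the M0 fit recovers simulating parameters and bounds identicals", {
  ident <- m0_fit("AAACCCGGGTTT", "AAACCCGGGTTT")
  expect_false(ident$valid)
  expect_equal(ident$dN, 0)
  expect_equal(ident$dS, 0)

  set.seed(97)
  q <- build_m0_generator(2, 0.2)
  lnl_gaps <- numeric(5)
  for (r in 1:5) {
    anc <- sample_codons_fixture(1200)
    pr <- evolve_pair(anc, q, 0.4)
    fit <- m0_fit(pr$cds_a, pr$cds_b)
    expect_true(fit$valid)
    expect_gt(fit$omega, 0.1)
    expect_lt(fit$omega, 0.35)
    # the optimum cannot be worse than the true simulating parameters
    pi_fit <- domainer:::f3x4_frequencies(c(pr$cds_a, pr$cds_b))
    lnl_true <- m0_loglik(pr$cds_a, pr$cds_b, 0.4, 2, 0.2, pi_fit)
    expect_gte(fit$lnL, lnl_true - 1e-6)
    lnl_gaps[r] <- fit$lnL - lnl_true
  }
  expect_true(all(lnl_gaps >= 0 | abs(lnl_gaps) < 1e-6))
})

test_that("dN/dS from the fitted generator equals the fitted omega", {
  for (omega in c(0.1, 0.7, 1.5)) {
    r <- domainer:::gy94_dn_ds(0.5, 2.5, omega, uniform_codon_frequencies())
    expect_equal(r$dN / r$dS, omega, tolerance = 1e-10)
  }
})

test_that("NG86 and M0 omega estimates agree in rank across a cohort", {
  set.seed(120)
  omegas <- exp(seq(log(0.05), log(1), length.out = 40))
  ng <- numeric(40)
  m0 <- numeric(40)
  for (k in seq_along(omegas)) {
    q <- build_m0_generator(2, omegas[k])
    pr <- evolve_pair(sample_codons_fixture(400), q, 0.5)
    ng[k] <- ng86_estimate(pr$cds_a, pr$cds_b)$omega
    m0[k] <- m0_fit(pr$cds_a, pr$cds_b)$omega
  }
  ok <- !is.na(ng) & !is.na(m0)
  expect_gt(sum(ok), 35)
  expect_gt(cor(ng[ok], m0[ok], method = "spearman"), 0.9)
})

test_that("the dS = 0 filter removes genes per scope", {
  rates <- tibble::tibble(
    gene = rep(c("g1", "g2", "g3"), each = 3),
    domain = rep(c("i", "t", "e"), 3),
    n_codons = c(50L, 20L, 60L, 50L, 0L, 60L, 50L, 20L, 60L),
    dN = 0.1, dS = c(0.2, 0.3, 0, 0.2, NA, 0.3, 0.2, 0.1, 0.3),
    omega = 0.5,
    valid = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    engine = "NG86"
  )
  per_domain <- apply_ds_filter(rates, "per-domain")
  expect_true(all(per_domain$dS > 0))
  expect_setequal(per_domain$gene[per_domain$domain == "i"],
                  c("g1", "g2", "g3"))
  expect_false("g1" %in% per_domain$gene[per_domain$domain == "e"])

  whole <- apply_ds_filter(rates, "whole-gene")
  expect_false("g1" %in% whole$gene)      # dS_e = 0 removes the whole gene
  expect_true("g2" %in% whole$gene)       # unused domain (0 codons) is ignored
  expect_setequal(unique(whole$gene), c("g2", "g3"))

  # a cohort without zero-dS genes passes unchanged
  clean <- rates[rates$gene == "g3", ]
  expect_equal(apply_ds_filter(clean, "per-domain"), clean)
})
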