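test_that("topology projects onto gapped alignment rows", {
  topo <- "iiMoo"
  expect_equal(project_topology(topo, "ABCDE"),
               c("i", "i", "M", "o", "o"))
  expect_equal(project_topology(topo, "AB-CDE"),
               c("i", "i", "-", "M", "o", "o"))
  expect_error(project_topology(topo, "ABCD"), "does not match")

  # stripping gap labels recovers the ungapped label string
  set.seed(14)
  for (r in 1:20) {
    n <- sample(5:40, 1)
    labels <- paste(sample(c("i", "M", "o"), n, replace = TRUE),
                    collapse = "")
    res <- sample(c(LETTERS[1:20]), n, replace = TRUE)
    gaps <- sample(0:5, 1)
    row <- append(res, rep("-", gaps),
                  after = sample(0:n, 1))
    row <- paste(row, collapse = "")
    proj <- project_topology(labels, row)
    expect_equal(paste(proj[proj != "-"], collapse = ""), labels)
  }
})

test_that("column classification follows the concordance policy", {
  la <- c("i", "i", "M", "o", "o")
  part <- classify_columns(la, la)
  expect_equal(part$cols_i, c(0L, 1L))
  expect_equal(part$cols_t, 2L)
  expect_equal(part$cols_e, c(3L, 4L))

  part2 <- classify_columns(c("i", "o"), c("i", "i"))
  expect_equal(part2$cols_i, 0L)
  expect_length(part2$cols_t, 0)
  expect_length(part2$cols_e, 0)

  # reference policy takes species A's label where both are residues
  part3 <- classify_columns(c("i", "o", "-"), c("i", "i", "o"), "reference")
  expect_equal(part3$cols_i, 0L)
  expect_equal(part3$cols_e, 1L)

  # disjointness: assigned columns never exceed the column count
  set.seed(3)
  for (r in 1:20) {
    n <- sample(1:30, 1)
    la <- sample(c("i", "M", "o", "-"), n, replace = TRUE)
    lb <- sample(c("i", "M", "o", "-"), n, replace = TRUE)
    p <- classify_columns(la, lb)
    assigned <- c(p$cols_i, p$cols_t, p$cols_e)
    expect_equal(anyDuplicated(assigned), 0L)
    expect_lte(length(assigned), n)
  }
})

test_that("retention requires both domain kinds in both species", {
  p_all <- domain_presence("iiMMoo")
  p_in <- domain_presence("iiii")
  p_io <- domain_presence("iioo")
  expect_true(retain_gene(p_all, p_all))
  expect_false(retain_gene(p_all, p_in))
  expect_false(retain_gene(p_io, p_in))
  expect_true(retain_gene(p_io, p_all))
})

test_that("subalignment extraction selects whole codon columns", {
  a <- "AAACCCGGG"
  b <- "TTTAAATTT"
  sub <- extract_subalignment(a, b, c(0L, 2L))
  expect_equal(sub$codon_a, "AAAGGG")
  expect_equal(sub$codon_b, "TTTTTT")
  expect_equal(sub$n_codons, 2L)

  all_cols <- extract_subalignment(a, b, 0:2)
  expect_equal(all_cols$codon_a, a)

  empty <- extract_subalignment(a, b, integer(0))
  expect_false(empty$valid)
  expect_equal(empty$n_codons, 0L)
  expect_error(extract_subalignment(a, b, 5L), "outside")

  set.seed(25)
  for (r in 1:10) {
    n <- sample(2:30, 1)
    ca <- random_cds(n)
    cb <- random_cds(n)
    cs <- sample(0:(n - 1), sample(1:n, 1))
    sub <- extract_subalignment(ca, cb, cs)
    expect_equal(nchar(sub$codon_a), 3L * length(unique(cs)))
  }
})

test_that("synthetic concordant cohorts partition into the configured lengths", {
  arch <- tibble::tibble(label = c("inside", "TMhelix", "outside", "TMhelix",
                                   "inside"),
                         length = c(25L, 21L, 40L, 21L, 12L))
  co <- sample_cohort(simulation_config(n_genes = 15,
                                        domain_architecture = arch,
                                        seed = 55))
  al <- align_codon_pairs(co$genes[, c("gene", "cds_a", "cds_b")], "direct")
  part <- partition_cohort(al, co$topology_a, co$topology_b)
  expect_true(all(part$report$retained))
  lens <- tidyr::pivot_wider(part$subalignments[, c("gene", "domain",
                                                    "n_codons")],
                             names_from = "domain", values_from = "n_codons")
  expect_true(all(lens$i == 25 + 12))
  expect_true(all(lens$t == 21 + 21))
  expect_true(all(lens$e == 40))
})

test_that("genes missing a domain kind in one species are excluded", {
  co <- sample_cohort(simulation_config(n_genes = 10, n_missing_domain = 4,
                                        seed = 66))
  al <- align_codon_pairs(co$genes[, c("gene", "cds_a", "cds_b")], "direct")
  part <- partition_cohort(al, co$topology_a, co$topology_b)
  expect_equal(sum(part$report$retained), 10)
  dropped <- part$report$gene[!part$report$retained]
  expect_setequal(dropped,
                  co$genes$gene[!co$genes$retain_expected])
  expect_false(any(part$subalignments$gene %in% dropped))
})
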