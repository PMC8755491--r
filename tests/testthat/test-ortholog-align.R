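test_that("select_longest keeps the longest transcript, ties to smallest id", {
  recs <- tibble::tibble(
    gene = "g1", id = c("a", "b", "c"),
    seq = c(strrep("M", 100), strrep("M", 250), strrep("K", 250))
  )
  out <- select_longest(recs)
  expect_equal(out$id, "b")

  single <- tibble::tibble(gene = "g2", id = "x", seq = "MKV")
  expect_equal(select_longest(single)$id, "x")

  set.seed(12)
  groups <- tibble::tibble(
    gene = rep(sprintf("g%02d", 1:20), each = 3),
    id = paste0("t", 1:60),
    seq = vapply(sample(5:80, 60, replace = TRUE),
                 function(n) strrep("A", n), character(1))
  )
  out <- select_longest(groups)
  brute <- tapply(nchar(groups$seq), groups$gene, max)
  expect_equal(nchar(out$seq), as.vector(brute[out$gene]))
})

test_that("global alignment matches an independent affine-gap DP oracle", {
  b62 <- domainer:::blosum62()
  al <- global_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(al$score,
               oracle_affine_nw_score("HEAGAWGHEE", "PAWHEAE", b62, 11, 1))
  expect_equal(gsub("-", "", al$aligned_a), "HEAGAWGHEE")
  expect_equal(gsub("-", "", al$aligned_b), "PAWHEAE")

  # identical sequences align gap-free at the sum of diagonal scores
  s <- "MKWVTFISLLFLFSSAYS"
  ali <- global_align(s, s)
  expect_false(grepl("-", ali$aligned_a))
  expect_equal(ali$score,
               sum(diag(b62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))

  set.seed(9)
  aas <- rownames(b62)[1:20]
  for (r in 1:10) {
    a <- paste(sample(aas, sample(5:25, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(5:25, 1), replace = TRUE), collapse = "")
    al <- global_align(a, b)
    expect_equal(al$score, oracle_affine_nw_score(a, b, b62, 11, 1))
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
  }

  expect_error(global_align("MK1V", "MKV"), "non-amino-acid")
})

test_that("reciprocal best hits match an exhaustive oracle and are symmetric", {
  # three mutually best pairs are all recovered
  pa <- tibble::tibble(id = c("a1", "a2", "a3"),
                       seq = c("MKWVTFISLL", "HEAGAWGHEE", "PAWHEAEMKV"))
  pb <- tibble::tibble(id = c("b1", "b2", "b3"),
                       seq = c("MKWVTFISLL", "HEAGAWGHEE", "PAWHEAEMKV"))
  rbh <- reciprocal_best_hits(pa, pb, min_score = 10)
  expect_equal(nrow(rbh), 3)
  expect_equal(rbh$id_b[match(c("a1", "a2", "a3"), rbh$id_a)],
               c("b1", "b2", "b3"))

  # an exact duplicate in A ties for the best score, excluding the pair
  pa_dup <- dplyr::bind_rows(pa, tibble::tibble(id = "a1bis",
                                                seq = "MKWVTFISLL"))
  rbh_dup <- reciprocal_best_hits(pa_dup, pb, min_score = 10)
  expect_false("b1" %in% rbh_dup$id_b)

  # random proteomes against a brute-force score-matrix RBH
  set.seed(33)
  aas <- rownames(domainer:::blosum62())[1:20]
  rand_prot <- function(ids) tibble::tibble(
    id = ids,
    seq = vapply(seq_along(ids), function(i) {
      paste(sample(aas, 30, replace = TRUE), collapse = "")
    }, character(1))
  )
  qa <- rand_prot(sprintf("qa%02d", 1:10))
  qb <- rand_prot(sprintf("qb%02d", 1:10))
  scores <- domainer:::alignment_score_matrix(qa, qb)
  floored <- ifelse(scores < -20, -Inf, scores)
  brute <- list()
  for (i in 1:10) {
    for (j in 1:10) {
      s <- floored[i, j]
      if (!is.finite(s)) next
      if (s == max(floored[i, ]) && sum(floored[i, ] == s) == 1 &&
          s == max(floored[, j]) && sum(floored[, j] == s) == 1) {
        brute[[length(brute) + 1]] <- c(rownames(scores)[i],
                                        colnames(scores)[j])
      }
    }
  }
  rbh_rand <- reciprocal_best_hits(qa, qb, min_score = -20)
  brute_df <- do.call(rbind, brute)
  expect_equal(nrow(rbh_rand), NROW(brute_df))
  expect_setequal(paste(rbh_rand$id_a, rbh_rand$id_b),
                  paste(brute_df[, 1], brute_df[, 2]))

  # symmetry under swapping proteomes
  rbh_swap <- reciprocal_best_hits(qb, qa, min_score = -20)
  expect_setequal(paste(rbh_rand$id_a, rbh_rand$id_b),
                  paste(rbh_swap$id_b, rbh_swap$id_a))
})

test_that("backtranslation mirrors residue gaps as codon gaps", {
  # gap-free alignment: concatenated codons
  al <- list(aligned_a = "MEK", aligned_b = "MEK")
  bt <- backtranslate(al, "ATGGAAAAA", "ATGGAGAAG")
  expect_equal(bt$codon_a, "ATGGAAAAA")
  expect_equal(bt$codon_b, "ATGGAGAAG")

  al2 <- list(aligned_a = "ME-K", aligned_b = "MEAK")
  bt2 <- backtranslate(al2, "ATGGAAAAA", "ATGGAGGCTAAG")
  expect_equal(bt2$codon_a, "ATGGAA---AAA")
  expect_equal(bt2$codon_b, "ATGGAGGCTAAG")

  expect_error(backtranslate(al, "ATGGAAAAG", "ATGGAGTGG"),
               "residue 3")
})

test_that("translate after backtranslate reproduces the protein alignment", {
  set.seed(21)
  for (r in 1:100) {
    cds_a <- random_cds(sample(8:30, 1))
    cds_b <- random_cds(sample(8:30, 1))
    pa <- translate_cds(cds_a)
    pb <- translate_cds(cds_b)
    if (grepl("\\*", pa) || grepl("\\*", pb)) next
    al <- global_align(pa, pb)
    bt <- backtranslate(al, cds_a, cds_b)
    expect_equal(domainer:::codon_row_to_protein_row(bt$codon_a),
                 al$aligned_a)
    expect_equal(domainer:::codon_row_to_protein_row(bt$codon_b),
                 al$aligned_b)
    # gap consistency: codon gaps exactly mirror residue gaps
    expect_equal(
      which(domainer:::split_codons(bt$codon_a) == "---"),
      which(strsplit(al$aligned_a, "")[[1]] == "-")
    )
  }
})

test_that("CDS pairs with internal stops are dropped with a warning", {
  pairs <- tibble::tibble(
    gene = c("ok", "bad"),
    cds_a = c("ATGGAAAAA", "ATGTAAAAA"),
    cds_b = c("ATGGAGAAG", "ATGGAAAAA")
  )
  expect_warning(out <- align_codon_pairs(pairs, method = "direct"),
                 "internal stop")
  expect_equal(out$gene, "ok")
})
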