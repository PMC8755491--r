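# Independent oracles used to check the package's implementations. These are
# deliberately written as direct, brute-force formulations of each definition
# and share no code with the package internals.

STANDARD_CODE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  setNames(aas, codons)
})

oracle_translate <- function(codon) STANDARD_CODE[[codon]]

# quadratic-space affine-gap global alignment score (Gotoh); a gap of length
# L costs open + L * ext
oracle_affine_nw_score <- function(a, b, mat, open, ext) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force NG86 site counts by enumerating the nine neighbours
oracle_ng86_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  aa <- oracle_translate(codon)
  syn <- 0
  nonsyn <- 0
  for (p in 1:3) {
    for (x in bases) {
      nb <- codon
      substr(nb, p, p) <- x
      if (nb == codon) next
      nb_aa <- oracle_translate(nb)
      if (nb_aa == "*") next
      if (nb_aa == aa) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
    }
  }
  c(nonsyn = nonsyn, syn = syn)
}

# recursive enumeration of minimal substitution paths between two codons;
# paths through stop codons are discarded (all paths if none survive)
oracle_ng86_pair <- function(a, b, allow_stops = FALSE) {
  if (a == b) return(c(nd = 0, sd = 0))
  walk <- function(cur) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(b, "")[[1]])
    if (length(pos) == 0) return(list(c(0, 0)))
    paths <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (!allow_stops && oracle_translate(nxt) == "*" && nxt != b) next
      step <- if (oracle_translate(cur) == oracle_translate(nxt)) c(0, 1) else c(1, 0)
      for (tailpath in walk(nxt)) {
        paths[[length(paths) + 1]] <- step + tailpath
      }
    }
    paths
  }
  paths <- walk(a)
  if (length(paths) == 0) return(oracle_ng86_pair(a, b, allow_stops = TRUE))
  m <- colMeans(do.call(rbind, paths))
  c(nd = m[1], sd = m[2])
}

# NG86 totals for a pairwise alignment, straight from the definition
oracle_ng86_alignment <- function(cds_a, cds_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(cds_a)
  cb <- split3(cds_b)
  N <- S <- Nd <- Sd <- 0
  used <- 0
  for (k in seq_along(ca)) {
    if (grepl("[^TCAG]", ca[k]) || grepl("[^TCAG]", cb[k])) next
    if (oracle_translate(ca[k]) == "*" || oracle_translate(cb[k]) == "*") next
    sa <- oracle_ng86_sites(ca[k])
    sb <- oracle_ng86_sites(cb[k])
    N <- N + (sa["nonsyn"] + sb["nonsyn"]) / 2
    S <- S + (sa["syn"] + sb["syn"]) / 2
    d <- oracle_ng86_pair(ca[k], cb[k])
    Nd <- Nd + d["nd"]
    Sd <- Sd + d["sd"]
    used <- used + 1
  }
  list(N = unname(N), S = unname(S), Nd = unname(Nd), Sd = unname(Sd),
       used = used)
}

# matrix exponential by scaled Taylor summation
oracle_expm_taylor <- function(q, t, terms = 60) {
  n <- nrow(q)
  k <- max(0, ceiling(log2(max(1, max(abs(q)) * t))))
  a <- q * (t / 2^k)
  p <- diag(n)
  term <- diag(n)
  for (i in 1:terms) {
    term <- term %*% a / i
    p <- p + term
  }
  for (i in seq_len(k)) p <- p %*% p
  p
}

# Spearman's coefficient as Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random sense-codon CDS strings
random_cds <- function(n_codons) {
  paste(sample_codons_fixture(n_codons), collapse = "")
}

sample_codons_fixture <- function(n_codons) {
  sense <- names(STANDARD_CODE)[STANDARD_CODE != "*"]
  sample(sense, n_codons, replace = TRUE)
}

# a small end-to-end analysis used by several tests: cohort -> alignment ->
# partition -> NG86 rates -> filtered rates + correlations + comparisons
analyse_cohort <- function(cohort, engine = "ng86",
                           ds_filter = "per-domain") {
  al <- align_codon_pairs(cohort$genes[, c("gene", "cds_a", "cds_b")],
                          method = "direct")
  part <- partition_cohort(al, cohort$topology_a, cohort$topology_b)
  rates <- estimate_domain_rates(part$subalignments, engine = engine)
  filt <- apply_ds_filter(rates, scope = ds_filter)
  cors <- domain_correlations(filt, cohort$genes[, c("gene", "abundance")])
  list(alignments = al, partition = part, rates = rates, filtered = filt,
       correlations = cors, tests = compare_domain_correlations(cors))
}
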