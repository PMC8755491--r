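# Mapping per-residue membrane topology onto codon-alignment columns and
# extracting the intracellular / transmembrane / extracellular subalignments.

#' Project a protein's topology onto its gapped alignment row
#'
#' The k-th non-gap column receives the k-th residue's label (`inside` -> `i`,
#' `TMhelix` -> `M`, `outside` -> `o`); gap columns receive `"-"`.
#'
#' @param topology Segment tibble for one gene (or a per-residue `i`/`M`/`o`
#'   string).
#' @param protein_row Gapped amino-acid string (one alignment row).
#' @return Character vector of per-column labels (`"i"`, `"M"`, `"o"`, `"-"`).
#' @export
project_topology <- function(topology, protein_row) {
  labels <- if (is.character(topology) && length(topology) == 1L) {
    strsplit(topology, "")[[1]]
  } else {
    strsplit(unname(topology_to_string(topology)), "")[[1]]
  }
  cols <- strsplit(protein_row, "")[[1]]
  is_res <- cols != "-"
  if (sum(is_res) != length(labels)) {
    abort(paste0("topology length (", length(labels),
                 ") does not match ungapped row length (", sum(is_res), ")"))
  }
  out <- rep("-", length(cols))
  out[is_res] <- labels
  out
}

#' Classify codon-alignment columns into domain classes
#'
#' Under the default `"concordant"` policy a column is intracellular when both
#' species label it `i`, transmembrane when both label it `M`, extracellular
#' when both label it `o`; columns where the species disagree, or where either
#' row is a gap, belong to no class. The `"reference"` policy uses the
#' species-A label wherever A is not a gap (sensitivity analysis).
#'
#' @param labels_a,labels_b Per-column label vectors from
#'   [project_topology()].
#' @param policy `"concordant"` (default) or `"reference"`.
#' @return List of class `"domain_partition"` with 0-based codon-column index
#'   vectors `cols_i`, `cols_t`, `cols_e` and the label matrix.
#' @export
classify_columns <- function(labels_a, labels_b,
                             policy = c("concordant", "reference")) {
  policy <- match.arg(policy)
  if (length(labels_a) != length(labels_b)) {
    abort("label vectors must have equal length")
  }
  idx <- seq_along(labels_a) - 1L
  if (policy == "concordant") {
    agree <- labels_a == labels_b
    cols_i <- idx[agree & labels_a == "i"]
    cols_t <- idx[agree & labels_a == "M"]
    cols_e <- idx[agree & labels_a == "o"]
  } else {
    usable <- labels_a != "-" & labels_b != "-"
    cols_i <- idx[usable & labels_a == "i"]
    cols_t <- idx[usable & labels_a == "M"]
    cols_e <- idx[usable & labels_a == "o"]
  }
  structure(
    list(cols_i = cols_i, cols_t = cols_t, cols_e = cols_e,
         labels = rbind(a = labels_a, b = labels_b), policy = policy),
    class = "domain_partition"
  )
}

#' Which domain kinds does a topology contain?
#'
#' @param topology Segment tibble for one gene or per-residue string.
#' @return List with logicals `has_inside`, `has_outside`, `has_membrane`.
#' @export
domain_presence <- function(topology) {
  s <- if (is.character(topology) && length(topology) == 1L) topology else
    unname(topology_to_string(topology))
  list(
    has_inside = grepl("i", s, fixed = TRUE),
    has_outside = grepl("o", s, fixed = TRUE),
    has_membrane = grepl("M", s, fixed = TRUE)
  )
}

#' Retention rule: both domain kinds in both species
#'
#' A gene is kept only when an intracellular and an extracellular segment are
#' both present in both species' topologies.
#'
#' @param presence_a,presence_b [domain_presence()] results.
#' @return Logical scalar.
#' @export
retain_gene <- function(presence_a, presence_b) {
  presence_a$has_inside && presence_a$has_outside &&
    presence_b$has_inside && presence_b$has_outside
}

#' Extract the subalignment at a set of codon columns
#'
#' @param codon_a,codon_b Gap-aligned CDS strings of equal length divisible
#'   by 3.
#' @param column_set 0-based codon-column indices.
#' @return List with `codon_a`, `codon_b`, `n_codons`, `valid` (`FALSE` for an
#'   empty column set, in which case downstream omega is undefined).
#' @export
extract_subalignment <- function(codon_a, codon_b, column_set) {
  n_cols <- nchar(codon_a) / 3L
  if (nchar(codon_a) != nchar(codon_b) || nchar(codon_a) %% 3L != 0L) {
    abort("codon alignment rows must have equal length divisible by 3")
  }
  if (length(column_set) > 0 &&
      (min(column_set) < 0L || max(column_set) >= n_cols)) {
    abort("column_set outside the alignment")
  }
  cs <- sort(unique(as.integer(column_set)))
  if (length(cs) == 0L) {
    return(list(codon_a = "", codon_b = "", n_codons = 0L, valid = FALSE))
  }
  pick <- function(s) {
    paste(substring(s, 3L * cs + 1L, 3L * cs + 3L), collapse = "")
  }
  list(codon_a = pick(codon_a), codon_b = pick(codon_b),
       n_codons = length(cs), valid = TRUE)
}

# gapped codon row -> gapped protein row ("---" codon -> "-")
codon_row_to_protein_row <- function(codon_row) {
  codons <- split_codons(codon_row)
  res <- translate_codons(codons)
  res[codons == "---"] <- "-"
  paste(res, collapse = "")
}

#' Partition an aligned ortholog cohort into domain subalignments
#'
#' Applies projection, column classification and the retention rule to every
#' aligned gene. Genes failing the retention rule (or whose topology length
#' mismatches a protein) are reported but excluded from the subalignments.
#'
#' @param alignments Tibble with `gene`, `codon_a`, `codon_b`.
#' @param topology_a,topology_b Segment tibbles covering the genes.
#' @param policy Column-classification policy (see [classify_columns()]).
#' @return List with `subalignments` (tibble: `gene`, `domain`, `codon_a`,
#'   `codon_b`, `n_codons`) and `report` (tibble: `gene`, `retained`,
#'   `reason`).
#' @export
partition_cohort <- function(alignments, topology_a, topology_b,
                             policy = "concordant") {
  topo_a <- topology_to_string(topology_a)
  topo_b <- topology_to_string(topology_b)
  n <- nrow(alignments)
  doms <- c("i", "t", "e")
  sub_gene <- character(3L * n)
  sub_domain <- character(3L * n)
  sub_a <- character(3L * n)
  sub_b <- character(3L * n)
  sub_n <- integer(3L * n)
  n_sub <- 0L
  retained <- logical(n)
  reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    g <- alignments$gene[k]
    if (is.na(topo_a[g]) || is.na(topo_b[g])) {
      reason[k] <- "no topology"
      next
    }
    if (!retain_gene(domain_presence(topo_a[[g]]), domain_presence(topo_b[[g]]))) {
      reason[k] <- "missing domain kind in a species"
      next
    }
    la <- project_topology(topo_a[[g]], codon_row_to_protein_row(alignments$codon_a[k]))
    lb <- project_topology(topo_b[[g]], codon_row_to_protein_row(alignments$codon_b[k]))
    part <- classify_columns(la, lb, policy)
    for (d in doms) {
      sub <- extract_subalignment(alignments$codon_a[k], alignments$codon_b[k],
                                  part[[paste0("cols_", d)]])
      n_sub <- n_sub + 1L
      sub_gene[n_sub] <- g
      sub_domain[n_sub] <- d
      sub_a[n_sub] <- sub$codon_a
      sub_b[n_sub] <- sub$codon_b
      sub_n[n_sub] <- sub$n_codons
    }
    retained[k] <- TRUE
  }
  keep <- seq_len(n_sub)
  list(
    subalignments = tibble(gene = sub_gene[keep], domain = sub_domain[keep],
                           codon_a = sub_a[keep], codon_b = sub_b[keep],
                           n_codons = sub_n[keep]),
    report = tibble(gene = alignments$gene, retained = retained,
                    reason = reason)
  )
}
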