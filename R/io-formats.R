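# External representations: FASTA sequences, TMHMM-style topology segments,
# abundance tables, and the two result TSVs.

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased; ambiguity characters are preserved. Identifiers
#' are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Tibble with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA identifier(s): ", paste(dup, collapse = ", ")))
  }
  tibble(id = ids, seq = unname(toupper(as.character(set))))
}

#' Write a tibble of sequences as FASTA
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Trim a terminal stop codon from CDS records
#'
#' Ensembl-style CDS sequences end in a stop codon that the protein sequence
#' lacks; this removes it when present. Errors if any resulting CDS length is
#' not a multiple of 3.
#'
#' @param records Tibble with `id`, `seq` (nucleotides).
#' @return The tibble with trimmed sequences.
#' @export
trim_terminal_stop <- function(records) {
  out <- records
  out$seq <- vapply(records$seq, function(s) {
    n <- nchar(s)
    if (n >= 3L && n %% 3L == 0L) {
      last <- substr(s, n - 2L, n)
      if (!is.na(genetic_code()[last]) && genetic_code()[last] == "*") {
        s <- substr(s, 1L, n - 3L)
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
  bad <- out$id[nchar(out$seq) %% 3L != 0L]
  if (length(bad) > 0) {
    abort(paste0("CDS length not a multiple of 3 for: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out
}

TOPOLOGY_LABELS <- c("inside", "TMhelix", "outside")

#' Read membrane-topology segments
#'
#' Accepts two dialects interchangeably: the canonical four-column
#' tab-separated segment form `id<TAB>label<TAB>start<TAB>end` (labels
#' `inside`/`TMhelix`/`outside`, 1-based inclusive coordinates, mirroring
#' TMHMM long-format data lines), or a two-column per-residue string form
#' `id<TAB>iiiMMMooo`. Segments must tile each protein contiguously from
#' position 1 with no gaps or overlaps.
#'
#' @param path Topology file.
#' @return Tibble with columns `gene`, `label`, `start`, `end`, grouped per
#'   gene and sorted by `start`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty topology file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (all(ncols == 2L)) {
    out <- bind_rows(lapply(fields, function(f) {
      topology_from_string(f[1], f[2])
    }))
  } else if (all(ncols == 4L)) {
    out <- tibble(
      gene = vapply(fields, `[`, "", 1L),
      label = vapply(fields, `[`, "", 2L),
      start = as.integer(vapply(fields, `[`, "", 3L)),
      end = as.integer(vapply(fields, `[`, "", 4L))
    )
  } else {
    abort("topology lines must have 4 fields (segments) or 2 fields (residue string)")
  }
  bad <- setdiff(unique(out$label), TOPOLOGY_LABELS)
  if (length(bad) > 0) {
    abort(paste0("unknown topology label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(out$start) || anyNA(out$end)) abort("non-numeric topology coordinates")
  out <- out |> arrange(match(.data$gene, unique(.data$gene)), .data$start)
  validate_topology(out)
  out
}

validate_topology <- function(topology) {
  by_gene <- split(topology, topology$gene)
  for (tg in by_gene) {
    if (tg$start[1] != 1L) {
      abort(paste0("topology for ", tg$gene[1], " does not start at position 1"))
    }
    if (any(tg$end < tg$start)) {
      abort(paste0("topology segment with end < start for ", tg$gene[1]))
    }
    if (nrow(tg) > 1) {
      gaps <- tg$start[-1] != tg$end[-nrow(tg)] + 1L
      if (any(gaps)) {
        abort(paste0("topology segments for ", tg$gene[1],
                     " are not contiguous (gap or overlap after position ",
                     tg$end[which(gaps)[1]], ")"))
      }
    }
  }
  invisible(topology)
}

topology_from_string <- function(gene, string) {
  ch <- strsplit(string, "")[[1]]
  map <- c(i = "inside", M = "TMhelix", o = "outside")
  if (!all(ch %in% names(map))) {
    abort(paste0("unknown topology label(s): ",
                 paste(setdiff(unique(ch), names(map)), collapse = ", ")))
  }
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  tibble(
    gene = gene, label = unname(map[r$values]),
    start = as.integer(c(1L, head(ends, -1) + 1L)), end = as.integer(ends)
  )
}

#' Expand topology segments to a per-residue label string
#'
#' @param topology Segment tibble for one or more genes.
#' @return Named character vector of strings over `i`/`M`/`o`, one per gene.
#' @export
topology_to_string <- function(topology) {
  map <- c(inside = "i", TMhelix = "M", outside = "o")
  vapply(split(topology, topology$gene), function(tg) {
    tg <- tg[order(tg$start), ]
    paste(rep(map[tg$label], tg$end - tg$start + 1L), collapse = "")
  }, character(1))
}

#' Write topology segments in the canonical four-column form
#' @param topology Segment tibble (`gene`, `label`, `start`, `end`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  readr::write_tsv(topology[, c("gene", "label", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read an abundance table into long form
#'
#' Expects a TSV whose first (header-named) column holds gene identifiers and
#' whose remaining columns are abundance contexts (tissues, or a single
#' integrated column). Missing cells are dropped, not zero-filled.
#'
#' @param path Abundance TSV with a header row.
#' @return Tibble with columns `gene`, `context`, `abundance`.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(wide) < 2) abort("abundance table needs a gene column and >= 1 context column")
  names(wide)[1] <- "gene"
  long <- tidyr::pivot_longer(wide, -"gene", names_to = "context",
                              values_to = "abundance") |>
    filter(!is.na(.data$abundance))
  if (any(long$abundance < 0)) abort("negative abundance value")
  dup <- long |> count(.data$gene, .data$context) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (gene, context) pair(s), e.g. ", dup$gene[1],
                 " / ", dup$context[1]))
  }
  long
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write the per-gene rates table and the correlation-comparison table
#'
#' Two TSVs with fixed column order; floating-point values at six significant
#' digits, missing values as literal `NA`.
#'
#' @param rates Per-gene/per-domain rate tibble (long form as produced by
#'   [estimate_domain_rates()]).
#' @param tests Comparison tibble as produced by [fisher_r_to_z()] rows.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_results <- function(rates, tests, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rates_path <- file.path(dir, "rates.tsv")
  tests_path <- file.path(dir, "tests.tsv")
  readr::write_tsv(format_rates_tbl(rates), rates_path, progress = FALSE,
                   na = "NA")
  readr::write_tsv(format_tests_tbl(tests), tests_path, progress = FALSE,
                   na = "NA")
  invisible(c(rates_path, tests_path))
}

format_rates_tbl <- function(rates) {
  rate_cols <- c("gene", "domain", "n_codons", "dN", "dS", "omega", "valid",
                 "engine")
  extra <- intersect(c("kappa", "t", "lnL"), names(rates))
  r <- rates[, c(rate_cols, extra), drop = FALSE]
  for (cc in c("dN", "dS", "omega", extra)) r[[cc]] <- fmt6(r[[cc]])
  r
}

format_tests_tbl <- function(tests) {
  test_cols <- c("comparison", "rho_1", "n_1", "rho_2", "n_2", "Z",
                 "p_one_tailed", "p_two_tailed")
  tt <- tests[, intersect(test_cols, names(tests)), drop = FALSE]
  for (cc in intersect(c("rho_1", "rho_2", "Z", "p_one_tailed", "p_two_tailed"),
                       names(tt))) {
    tt[[cc]] <- fmt6(tt[[cc]])
  }
  tt
}
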