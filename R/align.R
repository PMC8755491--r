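# Ortholog pairing and protein-guided codon alignment: reciprocal best hits
# over exhaustive global alignment scores, then back-translation of the
# protein alignment onto the CDS pair.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62 <- function() {
  if (is.null(the$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    the$blosum62 <- env$BLOSUM62
  }
  the$blosum62
}

#' Keep the longest sequence per gene
#'
#' For genes with several transcripts, retains the longest record; ties go to
#' the lexicographically smallest identifier.
#'
#' @param records Tibble with columns `gene`, `id`, `seq`.
#' @return One row per gene.
#' @export
select_longest <- function(records) {
  records |>
    mutate(.len = nchar(.data$seq)) |>
    group_by(.data$gene) |>
    arrange(desc(.data$.len), .data$id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".len")
}

#' Global protein alignment with affine gap costs
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap penalties
#' (a gap of length L costs `gap_open + L * gap_extend`). This deterministic
#' aligner stands in for probabilistic consistency aligners at desk scale;
#' closely related orthologs are insensitive to the choice.
#'
#' @param protein_a,protein_b Amino-acid strings (standard 20-letter
#'   alphabet).
#' @param substitution_matrix Scoring matrix (default BLOSUM62).
#' @param gap_open,gap_extend Gap opening and per-residue extension costs
#'   (positive numbers; subtracted from the score).
#' @return List with `aligned_a`, `aligned_b` (equal-length gapped strings)
#'   and `score`.
#' @export
global_align <- function(protein_a, protein_b,
                         substitution_matrix = blosum62(),
                         gap_open = 11, gap_extend = 1) {
  for (s in c(protein_a, protein_b)) {
    if (nchar(s) == 0) abort("cannot align an empty sequence")
    bad <- setdiff(unique(strsplit(s, "")[[1]]), AA_ALPHABET)
    if (length(bad) > 0) {
      abort(paste0("non-amino-acid character(s) in protein: ",
                   paste(bad, collapse = ", ")))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

# all-vs-all global alignment scores; rows = proteome A, cols = proteome B
alignment_score_matrix <- function(proteome_a, proteome_b,
                                   substitution_matrix = blosum62(),
                                   gap_open = 11, gap_extend = 1) {
  seqs_a <- Biostrings::AAStringSet(setNames(proteome_a$seq, proteome_a$id))
  scores <- matrix(NA_real_, nrow(proteome_a), nrow(proteome_b),
                   dimnames = list(proteome_a$id, proteome_b$id))
  for (j in seq_len(nrow(proteome_b))) {
    scores[, j] <- Biostrings::pairwiseAlignment(
      seqs_a, Biostrings::AAString(proteome_b$seq[j]), type = "global",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
  }
  scores
}

#' Reciprocal-best-hit ortholog pairs
#'
#' Scores every cross-proteome pair by global alignment and keeps (x, y) when
#' y is x's unique best-scoring partner and x is y's unique best-scoring
#' partner. Ties for best score exclude the pair. Pairs scoring below
#' `min_score` are discarded (screening stand-in for an E-value cutoff, which
#' is database-size dependent and not reproducible at desk scale).
#'
#' @param proteome_a,proteome_b Tibbles with columns `id`, `seq`.
#' @param min_score Minimum alignment score for a hit to count.
#' @inheritParams global_align
#' @return Tibble with columns `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, min_score = 50,
                                 substitution_matrix = blosum62(),
                                 gap_open = 11, gap_extend = 1) {
  if (nrow(proteome_a) == 0 || nrow(proteome_b) == 0) {
    abort("both proteomes must be non-empty")
  }
  scores <- alignment_score_matrix(proteome_a, proteome_b,
                                   substitution_matrix, gap_open, gap_extend)
  scores[scores < min_score] <- -Inf
  pairs <- list()
  for (i in seq_len(nrow(scores))) {
    best <- max(scores[i, ])
    if (!is.finite(best)) next
    js <- which(scores[i, ] == best)
    if (length(js) != 1L) next
    j <- js
    best_j <- max(scores[, j])
    is_ <- which(scores[, j] == best_j)
    if (length(is_) != 1L || is_ != i) next
    pairs[[length(pairs) + 1L]] <- tibble(
      id_a = rownames(scores)[i], id_b = colnames(scores)[j], score = best
    )
  }
  if (length(pairs) == 0) {
    return(tibble(id_a = character(), id_b = character(), score = numeric()))
  }
  bind_rows(pairs)
}

#' Back-translate a protein alignment onto the CDS pair
#'
#' Maps every residue gap to a whole-codon gap `"---"` so column k of the
#' protein alignment corresponds to codon column k of the result. Every codon
#' must translate to its aligned residue under the standard genetic code.
#'
#' @param protein_alignment A [global_align()] result (or any list with
#'   `aligned_a`, `aligned_b`).
#' @param cds_a,cds_b Ungapped CDS strings, lengths 3x the ungapped protein
#'   lengths.
#' @return List with `codon_a`, `codon_b`: gap-aligned CDS strings of equal
#'   length divisible by 3.
#' @export
backtranslate <- function(protein_alignment, cds_a, cds_b) {
  row_to_codons <- function(aligned, cds, which) {
    res <- strsplit(aligned, "")[[1]]
    ungapped <- res[res != "-"]
    if (nchar(cds) != 3L * length(ungapped)) {
      abort(paste0("CDS ", which, " length is not 3x the ungapped protein length"))
    }
    codons <- split_codons(cds)
    aa <- translate_codons(codons)
    mismatch <- which(aa != ungapped)
    if (length(mismatch) > 0) {
      abort(paste0("CDS ", which, " does not translate to the aligned protein at residue ",
                   mismatch[1], " (", codons[mismatch[1]], " -> ",
                   aa[mismatch[1]], ", expected ", ungapped[mismatch[1]], ")"))
    }
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    paste(out, collapse = "")
  }
  list(
    codon_a = row_to_codons(protein_alignment$aligned_a, cds_a, "a"),
    codon_b = row_to_codons(protein_alignment$aligned_b, cds_b, "b")
  )
}

#' Align ortholog CDS pairs via their proteins
#'
#' Convenience wrapper: translates each CDS (dropping genes whose CDS contains
#' an internal stop, with a warning), aligns the proteins and back-translates.
#' For indel-free equal-length pairs `method = "direct"` skips the aligner and
#' pairs codons positionally.
#'
#' @param pairs Tibble with columns `gene`, `cds_a`, `cds_b`.
#' @param method `"nw"` (global protein alignment) or `"direct"`.
#' @return Tibble with columns `gene`, `codon_a`, `codon_b` (gap-aligned CDS
#'   strings).
#' @export
align_codon_pairs <- function(pairs, method = c("nw", "direct")) {
  method <- match.arg(method)
  has_stop <- function(cds) {
    vapply(cds, function(s) {
      code <- genetic_code()[split_codons(s)]
      any(!is.na(code) & code == "*")
    }, logical(1), USE.NAMES = FALSE)
  }
  drop <- has_stop(pairs$cds_a) | has_stop(pairs$cds_b)
  for (g in pairs$gene[drop]) {
    warn(paste0("dropping ", g, ": internal stop codon in CDS"))
  }
  pairs <- pairs[!drop, , drop = FALSE]
  if (method == "direct") {
    bad <- nchar(pairs$cds_a) != nchar(pairs$cds_b)
    if (any(bad)) {
      abort(paste0("direct pairing requires equal CDS lengths (",
                   pairs$gene[which(bad)[1]], ")"))
    }
    return(tibble(gene = pairs$gene, codon_a = pairs$cds_a,
                  codon_b = pairs$cds_b))
  }
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    al <- global_align(translate_cds(pairs$cds_a[k]),
                       translate_cds(pairs$cds_b[k]))
    bt <- backtranslate(al, pairs$cds_a[k], pairs$cds_b[k])
    out[[k]] <- tibble(gene = pairs$gene[k], codon_a = bt$codon_a,
                       codon_b = bt$codon_b)
  }
  bind_rows(out)
}
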