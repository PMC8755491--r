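# Standard genetic code machinery shared by the simulator and both dN/dS
# engines. All tables are built once and cached in the package environment.

NUC <- c("T", "C", "A", "G")

#' Standard genetic code lookup
#'
#' @return Named character vector mapping all 64 codons to one-letter amino
#'   acids, with `"*"` for the three stop codons (standard code).
#' @keywords internal
genetic_code <- function() {
  if (is.null(the$code)) {
    code <- Biostrings::GENETIC_CODE
    the$code <- setNames(as.character(code), names(code))
  }
  the$code
}

#' The 61 sense codons of the standard genetic code
#'
#' @return Character vector of sense codons in fixed (T, C, A, G) order.
#' @export
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

is_stop_codon <- function(codon) {
  genetic_code()[codon] == "*"
}

translate_codons <- function(codons) {
  aa <- genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Translate a CDS string under the standard genetic code
#'
#' Codons containing ambiguity characters or gaps translate to `"X"`.
#'
#' @param cds Nucleotide string with length a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    abort("CDS length must be a multiple of 3")
  }
  paste(translate_codons(split_codons(cds)), collapse = "")
}

#' Split a (possibly gapped) CDS string into codon triplets
#' @keywords internal
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

is_transition_pair <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Pairwise structure over the 61 sense codons: for each ordered pair that
# differs at exactly one nucleotide, whether the change is a transition and
# whether it is nonsynonymous. Cached; used by the GY94 generator and NG86.
codon_pair_masks <- function() {
  if (!is.null(the$pair_masks)) return(the$pair_masks)
  sc <- sense_codons()
  n <- length(sc)
  mat <- do.call(rbind, strsplit(sc, ""))
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(mat[, p], mat[, p], "!=")
  single <- ndiff == 1L
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    ts <- ts | (single & outer(mat[, p], mat[, p], is_transition_pair))
  }
  aa <- translate_codons(sc)
  nonsyn <- outer(aa, aa, "!=")
  the$pair_masks <- list(
    codons = sc, ndiff = ndiff, single = single,
    transition = ts, nonsyn = nonsyn
  )
  the$pair_masks
}

#' F3x4 codon equilibrium frequencies
#'
#' Computes codon frequencies from the observed nucleotide frequencies at each
#' codon position, jointly over the supplied sequences, normalised over the 61
#' sense codons (the PAML F3x4 convention). Gap and ambiguity characters are
#' ignored. A small floor keeps all frequencies positive so the substitution
#' model stays irreducible even when a nucleotide is unobserved at a position.
#'
#' @param cds Character vector of (possibly gapped) CDS strings.
#' @param floor Minimum per-codon frequency before renormalisation.
#' @return Named numeric vector over [sense_codons()], summing to 1.
#' @export
f3x4_frequencies <- function(cds, floor = 1e-6) {
  chars <- strsplit(paste(cds, collapse = ""), "")[[1]]
  if (length(chars) %% 3L != 0L) abort("total CDS length must be a multiple of 3")
  pos <- rep_len(1:3, length(chars))
  freq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, NUC))
  for (p in 1:3) {
    tab <- table(factor(chars[pos == p], levels = NUC))
    if (sum(tab) == 0) abort("no unambiguous nucleotides at a codon position")
    freq[p, ] <- as.numeric(tab) / sum(tab)
  }
  sc <- sense_codons()
  mat <- do.call(rbind, strsplit(sc, ""))
  pi <- freq[1, mat[, 1]] * freq[2, mat[, 2]] * freq[3, mat[, 3]]
  pi <- pmax(pi, floor)
  setNames(pi / sum(pi), sc)
}

#' Uniform codon frequencies over the sense codons
#' @return Named numeric vector, each entry 1/61.
#' @export
uniform_codon_frequencies <- function() {
  sc <- sense_codons()
  setNames(rep(1 / length(sc), length(sc)), sc)
}
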