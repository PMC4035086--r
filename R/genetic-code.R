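# Genetic-code bookkeeping shared by the divergence and Ka/Ks modules.
# The standard code is taken from Biostrings::GENETIC_CODE; degeneracy
# classes and transition/transversion relations are precomputed once.

NUCS <- c("A", "C", "G", "T")

# transition partner of each nucleotide (A<->G, C<->T)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Split an in-frame CDS string into codons
#' @param cds character scalar, length divisible by 3
#' @return character vector of 3-mers
#' @keywords internal
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    od_input_error("CDS length is not divisible by 3 (frame violation)")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

.codon_env <- new.env(parent = emptyenv())

# All 64 codons in a fixed order, their amino acids, and a 64 x 3 matrix of
# degeneracy classes ("nondegenerate", "twofold", "threefold", "fourfold";
# NA for stop codons). Variants that would create a stop codon are excluded
# from the enumeration (NG86-style convention).
.codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  deg <- matrix(NA_character_, nrow = 64L, ncol = 3L,
                dimnames = list(codons, NULL))
  is_ts <- matrix(FALSE, nrow = 64L, ncol = 3L, dimnames = list(codons, NULL))
  for (i in seq_along(codons)) {
    if (aa[i] == "*") next
    for (pos in 1:3) {
      base <- substr(codons[i], pos, pos)
      others <- setdiff(NUCS, base)
      variants <- vapply(others, function(b) {
        v <- codons[i]; substr(v, pos, pos) <- b; v
      }, character(1))
      vaa <- code[variants]
      keep <- vaa != "*"
      n_syn <- sum(vaa[keep] == aa[i])
      deg[i, pos] <- c("nondegenerate", "twofold", "threefold",
                       "fourfold")[n_syn + 1L]
    }
  }
  .codon_env$tab <- list(codons = codons, aa = setNames(aa, codons), deg = deg)
  .codon_env$tab
}

#' Classify the degeneracy of a codon position
#'
#' A position is *nondegenerate* when every single-nucleotide change (stop
#' codons excluded from the enumeration) alters the encoded amino acid,
#' *fourfold* when none does, and *twofold*/*threefold* when one or two of
#' the non-stop variants are synonymous.
#'
#' @param codon character vector of sense codons (3-mers over A/C/G/T).
#' @param position integer vector in 1..3 (1-based codon position),
#'   recycled against `codon`.
#' @return character vector of classes among `"nondegenerate"`, `"twofold"`,
#'   `"threefold"`, `"fourfold"`.
#' @examples
#' classify_degeneracy("GCT", 3)  # fourfold: GCA/GCC/GCG are all Ala
#' classify_degeneracy("ATG", 1:3)  # Met is a one-codon family
#' @export
classify_degeneracy <- function(codon, position) {
  tab <- .codon_tables()
  codon <- toupper(codon)
  n <- max(length(codon), length(position))
  codon <- rep_len(codon, n)
  position <- rep_len(as.integer(position), n)
  if (any(!codon %in% tab$codons))
    od_input_error("invalid codon (must be a 3-mer over A/C/G/T)")
  if (any(tab$aa[codon] == "*"))
    od_input_error("stop codon has no degeneracy class")
  if (any(position < 1L | position > 3L))
    od_input_error("codon position must be 1, 2 or 3")
  tab$deg[cbind(match(codon, tab$codons), position)]
}

#' Translate codons to amino acids (standard code)
#' @keywords internal
#' @noRd
codon_aa <- function(codons) {
  tab <- .codon_tables()
  unname(tab$aa[codons])
}

#' Is the single-nucleotide change between two bases a transition?
#' @keywords internal
#' @noRd
is_transition <- function(from, to) {
  unname(TRANSITION[from] == to)
}
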