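# Pairwise global alignment at desk scale.  Stands in for a database
# search: candidate hits are screened by shared k-mer content, scored by
# exact affine-gap Needleman-Wunsch (Biostrings), and thresholded on score
# and identity rather than a database E-value.

#' Affine-gap scoring scheme
#'
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< match).
#' @param gap_open,gap_extend positive gap penalties.
#' @return list of class `"align_scoring"`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = 2,
                          gap_extend = 1) {
  if (gap_open < 0 || gap_extend < 0)
    od_config_error("gap penalties must be nonnegative")
  if (mismatch >= match)
    od_config_error("mismatch score must be below match score")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.subst_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

.aln_stats <- function(qa, sa) {
  q <- charToRaw(qa)
  s <- charToRaw(sa)
  gap <- charToRaw("-")[1]
  both <- q != gap & s != gap
  overlap <- sum(both)
  matches <- sum(q[both] == s[both])
  list(overlap_bp = overlap,
       identity = if (overlap > 0) matches / overlap else NA_real_)
}

#' Global pairwise alignment of two nucleotide sequences
#'
#' Optimal global (Needleman-Wunsch) alignment under an affine gap scheme.
#' Identity is computed over non-gap columns; `overlap_bp` counts columns
#' where both sequences have a base.
#'
#' @param seq_a,seq_b nucleotide strings over A/C/G/T/N (non-empty).
#' @param scoring an [align_scoring()] scheme.
#' @param id_a,id_b optional sequence labels.
#' @return list of class `"pairwise_alignment"` with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `identity`,
#'   `overlap_bp`.
#' @examples
#' align_pair("ACGT", "ACGA")$score  # 2: three matches, one mismatch
#' @export
align_pair <- function(seq_a, seq_b, scoring = align_scoring(),
                       id_a = "a", id_b = "b") {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    od_input_error("sequences must be non-empty")
  if (grepl("[^ACGTN]", seq_a) || grepl("[^ACGTN]", seq_b))
    od_input_error("sequences must be over A/C/G/T/N")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = .subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  qa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  st <- .aln_stats(qa, sa)
  structure(list(query_id = id_a, subject_id = id_b,
                 aligned_a = unname(qa), aligned_b = unname(sa),
                 score = Biostrings::score(aln),
                 identity = st$identity, overlap_bp = st$overlap_bp),
            class = "pairwise_alignment")
}

# Shared-k-mer candidate screen: cosine similarity of k-mer count profiles.
.kmer_candidates <- function(set_a, set_b, k = 6L, candidates = 5L) {
  fa <- Biostrings::oligonucleotideFrequency(set_a, width = k)
  fb <- Biostrings::oligonucleotideFrequency(set_b, width = k)
  norm <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  sim <- norm(fa) %*% t(norm(fb))
  na <- nrow(sim); nb <- ncol(sim)
  kk <- min(candidates, nb)
  idx_a <- cbind(rep(seq_len(na), each = kk),
                 as.vector(apply(sim, 1L, function(r)
                   order(r, decreasing = TRUE)[seq_len(kk)])))
  kk2 <- min(candidates, na)
  idx_b <- cbind(as.vector(apply(sim, 2L, function(cc)
    order(cc, decreasing = TRUE)[seq_len(kk2)])),
    rep(seq_len(nb), each = kk2))
  unique(rbind(idx_a, idx_b))
}

#' Reciprocal best hits between two transcript sets
#'
#' Every sequence in `set_a` is matched against `set_b` (and vice versa);
#' a pair is retained when each member is the other's unique best-scoring
#' hit, the aligned overlap exceeds `min_overlap` and identity reaches
#' `min_identity`.  Candidate hits are pre-screened by shared k-mer content
#' (top `candidates` per gene, both directions); set `candidates = Inf`
#' for an exhaustive all-vs-all search.
#'
#' @param set_a,set_b named [Biostrings::DNAStringSet]s (or named character
#'   vectors) with unique ids within each set.
#' @param scoring an [align_scoring()] scheme.
#' @param min_overlap retained pairs must have `overlap_bp > min_overlap`
#'   (default 200 bp).
#' @param min_identity minimum alignment identity a retained pair must
#'   reach (stands in for a database E-value cut-off).
#' @param candidates k-mer screen depth per gene.
#' @return data.frame with `gene_A`, `gene_B`, `score`, `identity`,
#'   `overlap_bp`, one row per reciprocal pair.
#' @export
reciprocal_best_hits <- function(set_a, set_b, scoring = align_scoring(),
                                 min_overlap = 200L, min_identity = 0.9,
                                 candidates = 5L) {
  if (!methods::is(set_a, "DNAStringSet")) set_a <- Biostrings::DNAStringSet(set_a)
  if (!methods::is(set_b, "DNAStringSet")) set_b <- Biostrings::DNAStringSet(set_b)
  ids_a <- names(set_a); ids_b <- names(set_b)
  if (is.null(ids_a) || is.null(ids_b) ||
      anyDuplicated(ids_a) || anyDuplicated(ids_b))
    od_input_error("sequence sets must carry unique names")
  if (is.infinite(candidates)) {
    pairs_idx <- as.matrix(expand.grid(seq_along(set_a), seq_along(set_b)))
  } else {
    pairs_idx <- .kmer_candidates(set_a, set_b, candidates = candidates)
  }
  # score candidate pairs (score-only DP), grouped by subject for
  # vectorised calls; full alignments are computed only where needed
  mat <- .subst_matrix(scoring)
  groups <- split(pairs_idx[, 1L], pairs_idx[, 2L])
  res <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    jb <- as.integer(names(groups)[g])
    ia <- groups[[g]]
    sc <- Biostrings::pairwiseAlignment(
      set_a[ia], set_b[[jb]], type = "global",
      substitutionMatrix = mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
    res[[g]] <- data.frame(ia = ia, ib = jb, score = sc)
  }
  cand <- do.call(rbind, res)
  full_stats <- function(r) {
    aln <- align_pair(as.character(set_a[[cand$ia[r]]]),
                      as.character(set_b[[cand$ib[r]]]), scoring)
    c(identity = aln$identity, overlap_bp = aln$overlap_bp)
  }
  # unique best hit by score; score ties are broken by identity (computed
  # on demand); a tie surviving both keys disqualifies the gene
  best_of <- function(rows) {
    top <- rows[cand$score[rows] == max(cand$score[rows])]
    if (length(top) > 1L) {
      idy <- vapply(top, function(r) full_stats(r)[["identity"]], numeric(1))
      top <- top[idy == max(idy)]
      if (length(top) > 1L) return(NA_integer_)
    }
    top
  }
  best_for_a <- vapply(split(seq_len(nrow(cand)), cand$ia), best_of,
                       integer(1))
  best_for_b <- vapply(split(seq_len(nrow(cand)), cand$ib), best_of,
                       integer(1))
  recip <- intersect(best_for_a[!is.na(best_for_a)],
                     best_for_b[!is.na(best_for_b)])
  if (length(recip) == 0L)
    return(data.frame(gene_A = character(0), gene_B = character(0),
                      score = numeric(0), identity = numeric(0),
                      overlap_bp = numeric(0)))
  st <- t(vapply(recip, full_stats, c(identity = 0, overlap_bp = 0)))
  out <- data.frame(gene_A = ids_a[cand$ia[recip]],
                    gene_B = ids_b[cand$ib[recip]],
                    score = cand$score[recip],
                    identity = st[, "identity"],
                    overlap_bp = st[, "overlap_bp"],
                    stringsAsFactors = FALSE)
  out <- out[out$identity >= min_identity & out$overlap_bp > min_overlap, ,
             drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene_A), , drop = FALSE]
}
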