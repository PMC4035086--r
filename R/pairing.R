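# Ortholog pair filter cascade: reciprocal best hit -> shared reference
# protein -> CDS/UTR partition with length and internal-stop filters.

#' Keep only pairs unambiguously mapped to the same reference protein
#'
#' A pair survives when both genes carry exactly one protein label and the
#' labels agree; missing or multiple (semicolon-joined) labels are treated
#' as ambiguous and drop the pair.
#'
#' @param pairs data.frame with `gene_A`, `gene_B` (e.g. from
#'   [reciprocal_best_hits()]).
#' @param anno annotation data.frame with `gene_id`, `protein_label`.
#' @return `pairs` restricted to surviving rows, with a
#'   `shared_protein_label` column appended.
#' @export
same_protein_filter <- function(pairs, anno) {
  lab <- setNames(anno$protein_label, anno$gene_id)
  one_label <- function(ids) {
    l <- lab[ids]
    l[is.na(l) | l == "" | grepl(";", l)] <- NA_character_
    unname(l)
  }
  la <- one_label(pairs$gene_A)
  lb <- one_label(pairs$gene_B)
  keep <- !is.na(la) & !is.na(lb) & la == lb
  out <- pairs[keep, , drop = FALSE]
  out$shared_protein_label <- la[keep]
  rownames(out) <- NULL
  out
}

# label alignment columns by projecting A's CDS interval; gap-in-A columns
# inherit the label of the nearest column on their 5' side
.project_regions <- function(qa, sa, cds_start, cds_end) {
  q <- strsplit(qa, "")[[1]]
  s <- strsplit(sa, "")[[1]]
  apos <- cumsum(q != "-")
  region <- ifelse(apos < cds_start, "utr5",
                   ifelse(apos <= cds_end, "cds", "utr3"))
  # apos == 0 (leading gaps) maps below cds_start -> utr5, as intended
  list(q = q, s = s, apos = apos, region = region)
}

.paste_chars <- function(x) paste(x, collapse = "")

# extract the codon-aligned, gap- and N-free CDS alignment in A's frame,
# dropping A-codons that are incomplete in the alignment and the terminal
# stop codon
.codon_aligned_cds <- function(proj, cds_start, cds_end) {
  in_cds <- proj$region == "cds" & proj$q != "-"
  cols <- which(in_cds)
  if (length(cols) == 0L)
    return(list(a = "", b = ""))
  codon_idx <- (proj$apos[cols] - cds_start) %/% 3L
  ok_codons <- names(which(table(codon_idx) == 3L))
  keep <- codon_idx %in% as.integer(ok_codons) & proj$s[cols] != "-" &
    proj$q[cols] != "N" & proj$s[cols] != "N"
  # a codon must survive whole or not at all
  codon_idx_keep <- codon_idx[keep]
  full <- names(which(table(codon_idx_keep) == 3L))
  keep <- keep & codon_idx %in% as.integer(full)
  cols <- cols[keep]
  a <- .paste_chars(proj$q[cols])
  b <- .paste_chars(proj$s[cols])
  if (nchar(a) >= 3L) {
    ca <- split_codons(a); cb <- split_codons(b)
    n <- length(ca)
    if (codon_aa(ca[n]) == "*" || codon_aa(cb[n]) == "*") {
      ca <- ca[-n]; cb <- cb[-n]
    }
    a <- paste(ca, collapse = ""); b <- paste(cb, collapse = "")
  }
  list(a = a, b = b)
}

# does an in-frame CDS contain a stop codon before its final codon?
.has_internal_stop <- function(cds) {
  cod <- split_codons(cds)
  n <- length(cod)
  if (n <= 1L) return(FALSE)
  any(codon_aa(cod[-n]) == "*")
}

#' Partition ortholog pairs into aligned 5'UTR / CDS / 3'UTR regions
#'
#' Each retained pair is globally re-aligned and its alignment columns are
#' labelled by projecting species A's annotated CDS interval; gap columns
#' inherit the label of the nearest 5'-ward column.  Pairs whose gap-free
#' aligned CDS is shorter than `min_cds` bp, or whose CDS contains an
#' internal in-frame stop codon in either species, are rejected with a
#' reason code.
#'
#' @param pairs data.frame with `gene_A`, `gene_B` (and optionally
#'   `shared_protein_label`) surviving the earlier filters.
#' @param seqs_a,seqs_b named sequence sets for the two species.
#' @param anno annotation data.frame with `gene_id`, `cds_start`, `cds_end`
#'   (1-based inclusive; the CDS includes its stop codon).
#' @param min_cds minimum gap-free aligned CDS length in bp (default 75).
#' @param scoring an [align_scoring()] scheme.
#' @return list with `pairs` (list of `"ortholog_pair"` objects), `table`
#'   (one summary row per retained pair) and `rejected` (data.frame of
#'   `gene_A`, `gene_B`, `reason`).
#' @export
partition_regions <- function(pairs, seqs_a, seqs_b, anno, min_cds = 75L,
                              scoring = align_scoring()) {
  cs <- setNames(anno$cds_start, anno$gene_id)
  ce <- setNames(anno$cds_end, anno$gene_id)
  get_seq <- function(set, id) {
    if (!id %in% names(set))
      od_input_error(sprintf("sequence %s not found", id))
    as.character(set[[match(id, names(set))]])
  }
  kept <- list()
  rej <- list()
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    ga <- pairs$gene_A[r]; gb <- pairs$gene_B[r]
    a <- get_seq(seqs_a, ga); b <- get_seq(seqs_b, gb)
    if (is.na(cs[ga]) || !ga %in% names(cs)) {
      rej[[length(rej) + 1L]] <- data.frame(gene_A = ga, gene_B = gb,
                                            reason = "missing_cds")
      next
    }
    if (cs[[ga]] < 1L || ce[[ga]] > nchar(a))
      od_input_error(sprintf("CDS coordinates outside sequence for %s", ga))
    aln <- align_pair(a, b, scoring, id_a = ga, id_b = gb)
    proj <- .project_regions(aln$aligned_a, aln$aligned_b, cs[[ga]], ce[[ga]])
    gapfree_cds <- sum(proj$region == "cds" & proj$q != "-" & proj$s != "-")
    if (gapfree_cds < min_cds) {
      rej[[length(rej) + 1L]] <- data.frame(gene_A = ga, gene_B = gb,
                                            reason = "cds_too_short")
      next
    }
    cds_a_raw <- substr(a, cs[[ga]], ce[[ga]])
    cds_b_raw <- if (gb %in% names(cs) && !is.na(cs[gb]))
      substr(b, cs[[gb]], ce[[gb]]) else NULL
    cod <- .codon_aligned_cds(proj, cs[[ga]], ce[[ga]])
    stop_hit <- .has_internal_stop(cds_a_raw) ||
      (!is.null(cds_b_raw) && .has_internal_stop(cds_b_raw)) ||
      (nchar(cod$b) >= 3L && any(codon_aa(split_codons(cod$b)) == "*"))
    if (stop_hit) {
      rej[[length(rej) + 1L]] <- data.frame(gene_A = ga, gene_B = gb,
                                            reason = "internal_stop")
      next
    }
    regions <- lapply(c(utr5 = "utr5", cds = "cds", utr3 = "utr3"),
                      function(rg) {
                        cols <- proj$region == rg
                        list(a = .paste_chars(proj$q[cols]),
                             b = .paste_chars(proj$s[cols]))
                      })
    pid <- sprintf("pair_%s", sub("^A_", "", ga))
    obj <- structure(list(
      pair_id = pid, gene_A = ga, gene_B = gb,
      shared_protein_label = pairs$shared_protein_label[r] %||% NA_character_,
      score = pairs$score[r] %||% aln$score,
      identity = aln$identity, overlap_bp = aln$overlap_bp,
      regions = regions, codon_cds = cod),
      class = "ortholog_pair")
    kept[[length(kept) + 1L]] <- obj
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = pid, gene_A = ga, gene_B = gb,
      overlap_bp = aln$overlap_bp, identity = aln$identity,
      shared_protein_label = obj$shared_protein_label,
      utr5_bp = nchar(regions$utr5$a), cds_bp = nchar(regions$cds$a),
      utr3_bp = nchar(regions$utr3$a), stringsAsFactors = FALSE)
  }
  empty_rej <- data.frame(gene_A = character(0), gene_B = character(0),
                          reason = character(0))
  list(pairs = kept,
       table = if (length(rows)) do.call(rbind, rows) else NULL,
       rejected = if (length(rej)) do.call(rbind, rej) else empty_rej)
}

#' Run the full ortholog-pairing cascade
#'
#' Reciprocal best hits, the same-reference-protein filter and the
#' CDS/UTR partition with its length and stop-codon filters, in order.
#'
#' @inheritParams reciprocal_best_hits
#' @inheritParams partition_regions
#' @param anno annotation table covering both species' gene ids.
#' @return as [partition_regions()], plus the intermediate `rbh` table.
#' @export
find_orthologs <- function(set_a, set_b, anno, scoring = align_scoring(),
                           min_overlap = 200L, min_identity = 0.9,
                           min_cds = 75L, candidates = 5L) {
  rbh <- reciprocal_best_hits(set_a, set_b, scoring, min_overlap,
                              min_identity, candidates)
  flt <- same_protein_filter(rbh, anno)
  out <- partition_regions(flt, set_a, set_b, anno, min_cds, scoring)
  out$rbh <- rbh
  out
}

#' Orthogroups between a tissue and a whole-body set, and tissue-specific
#' genes
#'
#' Putative orthologous relationships between the tissue and whole-body
#' sets are identified as reciprocal best similarity pairs and grouped by
#' single linkage; tissue genes falling in no group are reported as
#' tissue-specific, together with their proportion of the tissue set.
#'
#' @param tissue_set,body_set named sequence sets.
#' @inheritParams reciprocal_best_hits
#' @return list with `groups` (data.frame `group_id`, `tissue_gene`,
#'   `body_gene`), `specific` (character vector of tissue-specific gene
#'   ids) and `proportion` (fraction of the tissue set that is specific).
#' @export
orthogroups_and_specific_genes <- function(tissue_set, body_set,
                                           scoring = align_scoring(),
                                           min_overlap = 200L,
                                           min_identity = 0.9,
                                           candidates = 5L) {
  rbh <- reciprocal_best_hits(tissue_set, body_set, scoring, min_overlap,
                              min_identity, candidates)
  groups <- if (nrow(rbh))
    data.frame(group_id = sprintf("og%04d", seq_len(nrow(rbh))),
               tissue_gene = rbh$gene_A, body_gene = rbh$gene_B,
               stringsAsFactors = FALSE)
  else
    data.frame(group_id = character(0), tissue_gene = character(0),
               body_gene = character(0))
  tissue_ids <- names(tissue_set)
  specific <- setdiff(tissue_ids, groups$tissue_gene)
  list(groups = groups, specific = specific,
       proportion = length(specific) / length(tissue_ids))
}
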