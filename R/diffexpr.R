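# Count-based differential expression between two libraries: RPKM
# normalisation, log2 fold change, the Audic-Claverie exact test on the
# two counts, Benjamini-Hochberg FDR, and threshold calls.

#' Reads per kilobase per million mapped reads
#'
#' @param count read count(s).
#' @param gene_length_bp transcript length(s) in bp (> 0).
#' @param total_mapped_reads library size (> 0).
#' @return `count * 1e9 / (gene_length_bp * total_mapped_reads)`.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0) || any(total_mapped_reads <= 0))
    od_input_error("gene length and total mapped reads must be positive")
  if (any(count < 0)) od_input_error("counts must be nonnegative")
  count * 1e9 / (gene_length_bp * total_mapped_reads)
}

#' log2 expression ratio of two RPKM values
#'
#' With the default `pseudo = 0`, a zero RPKM on one side yields a signed
#' infinite ratio (flagged by downstream consumers and excluded from
#' ranged summaries); zero on both sides yields `NaN`.
#'
#' @param rpkm_a,rpkm_b nonnegative RPKM values.
#' @param pseudo pseudocount added to both values.
#' @return `log2((rpkm_a + pseudo) / (rpkm_b + pseudo))`.
#' @export
log2_ratio <- function(rpkm_a, rpkm_b, pseudo = 0) {
  if (any(rpkm_a < 0) || any(rpkm_b < 0))
    od_input_error("RPKM values must be nonnegative")
  log2((rpkm_a + pseudo) / (rpkm_b + pseudo))
}

#' Audic-Claverie two-sided significance of a count difference
#'
#' Conditions on the count `x` observed in a library of `N1` reads and
#' asks how surprising the count `y` from a library of `N2` reads is under
#' equal relative expression:
#' `p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`,
#' i.e. `Y | x` is negative binomial with size `x + 1` and success
#' probability `N1/(N1+N2)`.  The two-sided p-value doubles the smaller of
#' the cumulative probability `P(Y <= y | x)` and its complement
#' `P(Y > y | x)`, capped at 1.  With this convention the two tails
#' partition the distribution and the p-value is exactly invariant under
#' exchanging the two libraries.
#'
#' @param x,y nonnegative integer counts.
#' @param N1,N2 positive library sizes.
#' @return two-sided p-value(s), vectorised.
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  k <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, k); y <- rep_len(y, k)
  N1 <- rep_len(N1, k); N2 <- rep_len(N2, k)
  if (any(x < 0) || any(y < 0))
    od_input_error("counts must be nonnegative")
  if (any(N1 <= 0) || any(N2 <= 0))
    od_input_error("library sizes must be positive")
  prob <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- pnbinom(y, size = x + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; the output preserves
#' the input order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    od_input_error("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Differential-expression calls at effect-size and FDR thresholds
#'
#' @param results data.frame with `log2_ratio` and `fdr` columns (e.g.
#'   from [diff_expression()]).
#' @param log2_threshold absolute log2 ratio a call must exceed (default 1).
#' @param fdr_threshold FDR a call must fall below (default 1.0e-3).
#' @return `results` with a `call` column (`up_in_A`, `down_in_A`, `ns`)
#'   and a `histogram` attribute binning the called genes' finite log2
#'   ratios into unit intervals.
#' @export
call_de <- function(results, log2_threshold = 1, fdr_threshold = 1e-3) {
  sig <- !is.na(results$fdr) & results$fdr < fdr_threshold
  call <- rep("ns", nrow(results))
  call[sig & results$log2_ratio > log2_threshold] <- "up_in_A"
  call[sig & results$log2_ratio < -log2_threshold] <- "down_in_A"
  results$call <- call
  de_l2 <- results$log2_ratio[call != "ns"]
  de_l2 <- de_l2[is.finite(de_l2)]
  if (length(de_l2)) {
    lo <- floor(min(de_l2)); hi <- ceiling(max(de_l2))
    h <- table(cut(de_l2, breaks = lo:hi, right = FALSE))
  } else h <- table(numeric(0))
  attr(results, "histogram") <- h
  results
}

#' Differential expression between two count libraries
#'
#' RPKM for each side, log2 ratio (A over B), the Audic-Claverie test on
#' the raw counts, BH FDR across genes, and calls at the thresholds.
#'
#' @param counts data.frame with `gene_id`, `count_A`, `count_B`.
#' @param gene_lengths named vector of transcript lengths in bp (may be a
#'   single shared length per gene; when per-species lengths differ,
#'   supply the species-A lengths in `gene_lengths` and B's in
#'   `gene_lengths_b`).
#' @param gene_lengths_b optional named vector of species-B lengths.
#' @param lib_size_a,lib_size_b library sizes; default to the column sums.
#' @param log2_threshold,fdr_threshold call thresholds (defaults 1 and
#'   1.0e-3).
#' @return data.frame with `gene_id`, counts, `rpkm_A`, `rpkm_B`,
#'   `log2_ratio`, `p`, `fdr`, `call`, plus the histogram attribute from
#'   [call_de()].
#' @export
diff_expression <- function(counts, gene_lengths, gene_lengths_b = NULL,
                            lib_size_a = NULL, lib_size_b = NULL,
                            log2_threshold = 1, fdr_threshold = 1e-3) {
  need <- c("gene_id", "count_A", "count_B")
  if (!all(need %in% names(counts)))
    od_input_error("counts must have gene_id, count_A, count_B columns")
  la <- gene_lengths[counts$gene_id]
  lb <- (gene_lengths_b %||% gene_lengths)[counts$gene_id]
  if (any(is.na(la)) || any(is.na(lb)))
    od_input_error("every gene needs a length")
  Na <- lib_size_a %||% sum(counts$count_A)
  Nb <- lib_size_b %||% sum(counts$count_B)
  ra <- rpkm(counts$count_A, la, Na)
  rb <- rpkm(counts$count_B, lb, Nb)
  l2 <- log2_ratio(ra, rb)
  p <- audic_claverie_p(counts$count_A, counts$count_B, Na, Nb)
  out <- data.frame(gene_id = counts$gene_id,
                    count_A = counts$count_A, count_B = counts$count_B,
                    rpkm_A = ra, rpkm_B = rb, log2_ratio = l2,
                    p = p, fdr = bh_fdr(p), stringsAsFactors = FALSE)
  call_de(out, log2_threshold, fdr_threshold)
}
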