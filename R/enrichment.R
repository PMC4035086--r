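# Hypergeometric pathway enrichment of a tissue gene set against a
# whole-body background.  N and n count background and subset genes that
# carry any pathway annotation; M and m count those annotated to a given
# pathway.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= m)` for `X ~ Hypergeometric(N, M, n)`: the probability of
#' observing at least `m` pathway members in a subset of `n` genes drawn
#' from a background of `N` genes of which `M` are in the pathway.
#'
#' @param N background size (annotated genes).
#' @param M pathway members in the background.
#' @param n subset size (annotated genes).
#' @param m pathway members observed in the subset.
#' @return the upper-tail probability (vectorised over its arguments).
#' @examples
#' hypergeom_upper_tail(20, 5, 10, 5)  # 3003/184756
#' @export
hypergeom_upper_tail <- function(N, M, n, m) {
  k <- max(length(N), length(M), length(n), length(m))
  N <- rep_len(N, k); M <- rep_len(M, k)
  n <- rep_len(n, k); m <- rep_len(m, k)
  if (any(M > N) || any(n > N) || any(m > M) || any(m > n) ||
      any(c(N, M, n, m) < 0))
    od_input_error("require 0 <= m <= min(n, M), M <= N, n <= N")
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Pathway enrichment of a gene subset against a background
#'
#' One upper-tail hypergeometric test per pathway with at least one
#' background member, after removing excluded pathways (e.g. disease
#' pathways irrelevant to the tissue).  Genes without any pathway
#' annotation do not count towards the totals.  No multiple-testing
#' correction is applied to the enriched flag (a raw threshold is the
#' convention for this analysis); a BH-adjusted column is provided for
#' reference.
#'
#' @param subset_genes character vector of subset (tissue) gene ids; must
#'   be contained in `background_genes`.
#' @param background_genes character vector of background (whole-body)
#'   gene ids.
#' @param catalog data.frame with `pathway_id`, `gene_id` (one row per
#'   membership), or a named list of gene-id vectors.
#' @param alpha enrichment threshold on the raw p-value (default 5.0e-3).
#' @param exclude character vector of pathway ids to drop before testing.
#' @return data.frame sorted by ascending p with columns `pathway_id`,
#'   `N`, `n`, `M`, `m`, `p`, `bh`, `enriched`.
#' @export
enrich_pathways <- function(subset_genes, background_genes, catalog,
                            alpha = 5e-3, exclude = character(0)) {
  if (!all(subset_genes %in% background_genes))
    od_input_error("subset genes must all be present in the background")
  if (is.list(catalog) && !is.data.frame(catalog))
    catalog <- data.frame(pathway_id = rep(names(catalog), lengths(catalog)),
                          gene_id = unlist(catalog, use.names = FALSE),
                          stringsAsFactors = FALSE)
  catalog <- catalog[catalog$gene_id %in% background_genes, , drop = FALSE]
  catalog <- catalog[!catalog$pathway_id %in% exclude, , drop = FALSE]
  annotated <- unique(catalog$gene_id)
  N <- sum(background_genes %in% annotated)
  n <- sum(subset_genes %in% annotated)
  sets <- split(catalog$gene_id, catalog$pathway_id)
  sets <- sets[lengths(sets) >= 1L]
  if (length(sets) == 0L)
    return(data.frame(pathway_id = character(0), N = integer(0),
                      n = integer(0), M = integer(0), m = integer(0),
                      p = numeric(0), bh = numeric(0),
                      enriched = logical(0)))
  M <- vapply(sets, function(g) length(unique(g)), integer(1))
  m <- vapply(sets, function(g) length(intersect(unique(g), subset_genes)),
              integer(1))
  p <- hypergeom_upper_tail(N, M, n, m)
  out <- data.frame(pathway_id = names(sets), N = N, n = n, M = M, m = m,
                    p = p, bh = p.adjust(p, method = "BH"),
                    enriched = p < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
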