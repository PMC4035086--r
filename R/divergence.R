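# Region-wise and degeneracy-class divergence between aligned orthologs.
# Divergence is the number of substitutions divided by the number of base
# pairs compared; columns with a gap or N in either sequence never count.

#' Divergence of one aligned region
#'
#' @param a,b equal-length (possibly gapped) aligned strings.
#' @return list with `compared_bp`, `substitutions`, `divergence`
#'   (`substitutions / compared_bp`; `NA` when nothing is compared) and
#'   `gc` (GC fraction over both sequences' included bases).
#' @examples
#' region_divergence("AC-GT", "ACAGA")  # 4 compared, 1 substitution
#' @export
region_divergence <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    od_input_error("aligned segments must have equal length")
  if (nchar(a) == 0L)
    return(list(compared_bp = 0L, substitutions = 0L,
                divergence = NA_real_, gc = NA_real_))
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  ok <- x %in% NUCS & y %in% NUCS
  compared <- sum(ok)
  subs <- sum(x[ok] != y[ok])
  bases <- c(x[ok], y[ok])
  list(compared_bp = compared, substitutions = subs,
       divergence = if (compared > 0) subs / compared else NA_real_,
       gc = if (compared > 0) mean(bases %in% c("G", "C")) else NA_real_)
}

#' Divergence restricted to nondegenerate and fourfold-degenerate sites
#'
#' Operates on a gap-free, in-frame, codon-aligned CDS pair.  A codon
#' position contributes to a class only when both species' codons assign it
#' that class (discordant positions are excluded from both tallies, so the
#' result does not depend on which species is taken as reference).  Codons
#' that are stop codons in either sequence are skipped.
#'
#' @param cds_a,cds_b equal-length gap-free CDS strings, length divisible
#'   by 3.
#' @return data.frame with rows `nd` and `fourfold` and columns
#'   `compared_bp`, `substitutions`, `divergence`.
#' @export
site_class_divergence <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    od_input_error("CDS alignment must have equal lengths")
  if (grepl("-", cds_a, fixed = TRUE) || grepl("-", cds_b, fixed = TRUE))
    od_input_error("CDS alignment must be gap-free")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  tab <- .codon_tables()
  valid <- ca %in% tab$codons & cb %in% tab$codons
  valid <- valid & !is.na(codon_aa(ifelse(valid, ca, "AAA"))) &
    codon_aa(ifelse(valid, ca, "AAA")) != "*" &
    codon_aa(ifelse(valid, cb, "AAA")) != "*"
  ca <- ca[valid]; cb <- cb[valid]
  out <- data.frame(class = c("nd", "fourfold"), compared_bp = 0L,
                    substitutions = 0L, divergence = NA_real_)
  if (length(ca) == 0L) return(out)
  cls_a <- matrix(tab$deg[ca, , drop = FALSE], ncol = 3L)
  cls_b <- matrix(tab$deg[cb, , drop = FALSE], ncol = 3L)
  same_cls <- cls_a == cls_b
  diff_nt <- matrix(unlist(strsplit(ca, "")) != unlist(strsplit(cb, "")),
                    ncol = 3L, byrow = TRUE)
  for (i in 1:2) {
    want <- c("nondegenerate", "fourfold")[i]
    sel <- same_cls & cls_a == want
    out$compared_bp[i] <- sum(sel)
    out$substitutions[i] <- sum(diff_nt[sel])
    out$divergence[i] <- if (out$compared_bp[i] > 0)
      out$substitutions[i] / out$compared_bp[i] else NA_real_
  }
  out
}

#' Per-pair divergence across all regions and site classes
#'
#' @param pair an `"ortholog_pair"` from [partition_regions()].
#' @return data.frame with one row per region (`utr5`, `cds`, `nd`,
#'   `fourfold`, `utr3`) and columns `pair_id`, `region`, `compared_bp`,
#'   `substitutions`, `divergence`, `gc`.
#' @export
pair_divergence <- function(pair) {
  stopifnot(inherits(pair, "ortholog_pair"))
  rows <- list()
  for (rg in c("utr5", "cds", "utr3")) {
    d <- region_divergence(pair$regions[[rg]]$a, pair$regions[[rg]]$b)
    rows[[rg]] <- data.frame(region = rg, compared_bp = d$compared_bp,
                             substitutions = d$substitutions,
                             divergence = d$divergence, gc = d$gc)
  }
  if (nchar(pair$codon_cds$a) >= 3L) {
    sc <- site_class_divergence(pair$codon_cds$a, pair$codon_cds$b)
    gc_cds <- rows$cds$gc
    rows$nd <- data.frame(region = "nd", compared_bp = sc$compared_bp[1],
                          substitutions = sc$substitutions[1],
                          divergence = sc$divergence[1], gc = gc_cds)
    rows$fourfold <- data.frame(region = "fourfold",
                                compared_bp = sc$compared_bp[2],
                                substitutions = sc$substitutions[2],
                                divergence = sc$divergence[2], gc = gc_cds)
  }
  out <- do.call(rbind, rows[c("utr5", "cds", "nd", "fourfold", "utr3")])
  out <- out[!vapply(out$region, is.null, logical(1)), , drop = FALSE]
  cbind(pair_id = pair$pair_id, out, stringsAsFactors = FALSE)
}

#' Summarise per-pair divergences into a five-row table
#'
#' One row per region/site class (5'UTR, CDS, nondegenerate sites,
#' fourfold-degenerate sites, 3'UTR) with the number of contributing loci,
#' the unweighted mean and standard error of per-pair divergences, the
#' pooled (substitution-weighted) divergence, total compared kb and pooled
#' GC.  Pairs contribute to a row only when they have compared base pairs
#' there.
#'
#' @param per_pair data.frame rbind of [pair_divergence()] results (or a
#'   list of `"ortholog_pair"` objects, which are summarised first).
#' @return data.frame with columns `region`, `loci`, `mean_divergence`,
#'   `se`, `pooled_divergence`, `compared_kb`, `gc`, `single_locus`.
#' @export
summarize_divergence <- function(per_pair) {
  if (is.list(per_pair) && !is.data.frame(per_pair)) {
    if (length(per_pair) == 0L) od_input_error("no pairs to summarise")
    per_pair <- do.call(rbind, lapply(per_pair, pair_divergence))
  }
  if (is.null(per_pair) || nrow(per_pair) == 0L)
    od_input_error("no pairs to summarise")
  regions <- c("utr5", "cds", "nd", "fourfold", "utr3")
  rows <- lapply(regions, function(rg) {
    d <- per_pair[per_pair$region == rg & per_pair$compared_bp > 0, ,
                  drop = FALSE]
    n <- nrow(d)
    if (n == 0L)
      return(data.frame(region = rg, loci = 0L, mean_divergence = NA_real_,
                        se = NA_real_, pooled_divergence = NA_real_,
                        compared_kb = 0, gc = NA_real_,
                        single_locus = FALSE))
    data.frame(region = rg, loci = n,
               mean_divergence = mean(d$divergence),
               se = if (n > 1L) sd(d$divergence) / sqrt(n) else 0,
               pooled_divergence = sum(d$substitutions) / sum(d$compared_bp),
               compared_kb = sum(d$compared_bp) / 1000,
               gc = sum(d$gc * d$compared_bp) / sum(d$compared_bp),
               single_locus = n == 1L)
  })
  do.call(rbind, rows)
}

#' Divergence table for a set of ortholog pairs
#'
#' Convenience wrapper: [pair_divergence()] for every pair, then
#' [summarize_divergence()].
#'
#' @param pairs list of `"ortholog_pair"` objects.
#' @return the five-row summary data.frame.
#' @export
divergence_table <- function(pairs) {
  summarize_divergence(pairs)
}
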