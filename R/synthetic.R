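# Synthetic two-species orthologous transcriptomes with known ground truth.
#
# The generator draws an ancestral transcriptome (5'UTR + CDS + 3'UTR per
# gene), then derives a second species by a per-site proposal/acceptance
# mutation process: UTR sites mutate neutrally, CDS proposals are accepted
# with probability 1 when synonymous, omega when nonsynonymous, and 0 when
# they would create a stop codon.  No indels are simulated, so orthologs
# stay column-aligned by construction and divergence arithmetic (counting
# substitutions over compared base pairs) is exactly defined.

#' Evolution parameters for the ortholog simulator
#'
#' Defaults emulate a pair of recently diverged cryptic species of the
#' whitefly complex: neutral (fourfold-degenerate) CDS divergence near 2.5%,
#' UTR divergence near 1.65%, and strong purifying selection (omega = 0.07)
#' suppressing nondegenerate-site divergence roughly 14-fold below the
#' neutral level.
#'
#' @param omega nonnegative acceptance probability for nonsynonymous
#'   proposals (the simulated Ka/Ks).
#' @param kappa positive transition/transversion rate ratio used when
#'   proposing mutations.
#' @param t_cds expected proposed substitutions per CDS site (before
#'   selection filtering).
#' @param t_utr expected substitutions per UTR site.
#' @param seed optional integer seed applied by [evolve_transcriptome()].
#' @return a list of class `"evolution_params"`.
#' @export
evolution_params <- function(omega = 0.07, kappa = 2, t_cds = 0.0248,
                             t_utr = 0.0166, seed = NULL) {
  if (!is.numeric(omega) || length(omega) < 1L || any(omega < 0) ||
      any(!is.finite(omega)))
    od_config_error("omega must be finite and nonnegative")
  if (!is.numeric(kappa) || any(kappa <= 0) || any(!is.finite(kappa)))
    od_config_error("kappa must be finite and positive")
  if (!is.numeric(t_cds) || any(t_cds < 0) || any(!is.finite(t_cds)))
    od_config_error("t_cds must be finite and >= 0")
  if (!is.numeric(t_utr) || any(t_utr < 0) || any(!is.finite(t_utr)))
    od_config_error("t_utr must be finite and >= 0")
  structure(list(omega = omega, kappa = kappa, t_cds = t_cds,
                 t_utr = t_utr, seed = seed),
            class = "evolution_params")
}

# draw n sequences of iid nucleotides at a given GC fraction
.draw_nucs <- function(n, gc) {
  sample(NUCS, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# draw n_codons sense (non-stop) codons at a given GC fraction
.draw_sense_codons <- function(n_codons, gc) {
  if (n_codons == 0L) return(character(0))
  stops <- c("TAA", "TAG", "TGA")
  cod <- paste0(.draw_nucs(n_codons, gc), .draw_nucs(n_codons, gc),
                .draw_nucs(n_codons, gc))
  bad <- cod %in% stops
  while (any(bad)) {
    nb <- sum(bad)
    cod[bad] <- paste0(.draw_nucs(nb, gc), .draw_nucs(nb, gc),
                       .draw_nucs(nb, gc))
    bad <- cod %in% stops
  }
  cod
}

#' Generate an ancestral transcriptome
#'
#' Each gene is a 5'UTR + CDS + 3'UTR nucleotide sequence.  The CDS starts
#' with ATG, ends with a stop codon and contains no internal in-frame stop.
#' Genes carry a unique reference-protein label and 1-3 pathway labels.
#'
#' @param n_genes number of genes.
#' @param utr5_len,cds_len,utr3_len either a fixed length (scalar) or a
#'   function of `n` returning `n` lengths.  `cds_len` draws must be
#'   multiples of 3 and at least 75 (start + at least 23 internal codons +
#'   stop).  Defaults draw negative-binomial lengths with means ~90 / ~675 /
#'   ~180 bp, matching transcript proportions typical of assembled insect
#'   gut transcriptomes.
#' @param gc target GC fraction in (0, 1).
#' @param n_pathways number of pathway labels to distribute over genes.
#' @param seed integer seed (the generator is deterministic given the seed).
#' @return an object of class `"ancestral_transcriptome"`: a list with
#'   `seqs` (named [Biostrings::DNAStringSet]) and `anno` (data.frame with
#'   `gene_id`, `cds_start`, `cds_end` (1-based, inclusive), `protein_label`,
#'   `pathway_ids` (semicolon-joined)).
#' @export
generate_ancestral_transcriptome <- function(n_genes,
                                             utr5_len = NULL,
                                             cds_len = NULL,
                                             utr3_len = NULL,
                                             gc = 0.42,
                                             n_pathways = 30L,
                                             seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1)
    od_config_error("n_genes must be a positive count")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    od_config_error("gc must lie in (0, 1)")
  if (!is.numeric(n_pathways) || n_pathways < 1)
    od_config_error("n_pathways must be a positive count")
  n_genes <- as.integer(n_genes)
  set.seed(as.integer(seed))

  utr5_len <- utr5_len %||% function(n) 20L + rnbinom(n, mu = 70, size = 4)
  cds_len  <- cds_len  %||% function(n) 3L * (25L + rnbinom(n, mu = 200, size = 8))
  utr3_len <- utr3_len %||% function(n) 30L + rnbinom(n, mu = 150, size = 4)
  as_sampler <- function(x) if (is.function(x)) x else function(n) rep_len(as.integer(x), n)
  l5 <- as.integer(as_sampler(utr5_len)(n_genes))
  lc <- as.integer(as_sampler(cds_len)(n_genes))
  l3 <- as.integer(as_sampler(utr3_len)(n_genes))
  if (any(l5 < 0) || any(l3 < 0))
    od_config_error("UTR lengths must be nonnegative")
  if (any(lc %% 3L != 0L) || any(lc < 75L))
    od_config_error("cds_len draws must be multiples of 3 and >= 75")

  ids <- sprintf("g%04d", seq_len(n_genes))
  pw_pool <- sprintf("pw%03d", seq_len(as.integer(n_pathways)))
  seqs <- character(n_genes)
  pw <- character(n_genes)
  for (i in seq_len(n_genes)) {
    n_internal <- lc[i] / 3L - 2L
    cds <- paste0("ATG",
                  paste(.draw_sense_codons(n_internal, gc), collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    seqs[i] <- paste0(paste(.draw_nucs(l5[i], gc), collapse = ""),
                      cds,
                      paste(.draw_nucs(l3[i], gc), collapse = ""))
    pw[i] <- paste(sample(pw_pool, sample(1:3, 1L)), collapse = ";")
  }
  anno <- data.frame(gene_id = ids,
                     cds_start = l5 + 1L,
                     cds_end = l5 + lc,
                     protein_label = sprintf("P%04d", seq_len(n_genes)),
                     pathway_ids = pw,
                     stringsAsFactors = FALSE)
  structure(list(seqs = Biostrings::DNAStringSet(setNames(seqs, ids)),
                 anno = anno),
            class = "ancestral_transcriptome")
}

# propose a replacement for base b with transition bias kappa
.mutate_base <- function(b, kappa) {
  ts <- TRANSITION[[b]]
  tv <- setdiff(NUCS, c(b, ts))
  sample(c(ts, tv), 1L, prob = c(kappa, 1, 1))
}

#' Evolve one ortholog from an ancestral gene
#'
#' UTR sites receive a Poisson(`t_utr`) number of substitutions each, with
#' transition bias `kappa`.  CDS sites (terminal stop codon excluded, which
#' stays fixed) receive Poisson(`t_cds`) proposed mutations; a proposal is
#' accepted with probability 1 if synonymous, `omega` if nonsynonymous, and
#' rejected outright if it would create a stop codon.
#'
#' @param seq ancestral nucleotide sequence (character scalar).
#' @param cds_start,cds_end 1-based inclusive CDS bounds (the CDS ends with
#'   its stop codon).
#' @param params an [evolution_params()] object; if `params$seed` is not
#'   `NULL` the RNG is seeded here.
#' @return list with `seq` (derived ortholog, same length) and `truth`, a
#'   one-row data.frame of realized differing-site counts per region
#'   (`utr5_sub`, `cds_sub`, `utr3_sub`) and per ancestral degeneracy class
#'   (`nd_sub`, `twofold_sub`, `threefold_sub`, `fourfold_sub`), ancestral
#'   site totals per class (`nd_sites`, ..., `fourfold_sites`), and event
#'   tallies (`syn_events`, `nonsyn_events`, `proposals`, `stop_rejections`).
#' @export
evolve_ortholog <- function(seq, cds_start, cds_end, params = evolution_params()) {
  if (!is.null(params$seed)) set.seed(as.integer(params$seed))
  x <- strsplit(toupper(seq), "")[[1]]
  L <- length(x)
  if (cds_start < 1L || cds_end > L || (cds_end - cds_start + 1L) %% 3L != 0L)
    od_input_error("invalid CDS interval")
  anc <- x
  tab <- .codon_tables()

  # --- UTRs: neutral, kappa-biased
  utr_pos <- c(seq_len(cds_start - 1L),
               if (cds_end < L) (cds_end + 1L):L else integer(0))
  if (length(utr_pos) && params$t_utr > 0) {
    nev <- rpois(length(utr_pos), params$t_utr)
    for (i in which(nev > 0L)) {
      p <- utr_pos[i]
      for (k in seq_len(nev[i])) x[p] <- .mutate_base(x[p], params$kappa)
    }
  }

  # --- CDS: proposal + selection; terminal stop codon frozen
  cds_pos <- if (cds_end - 2L > cds_start) cds_start:(cds_end - 3L) else integer(0)
  syn_ev <- 0L; nonsyn_ev <- 0L; stop_rej <- 0L; nprop <- 0L
  if (length(cds_pos) && params$t_cds > 0) {
    nprop <- rpois(1L, params$t_cds * length(cds_pos))
    if (nprop > 0L) {
      props <- sample(cds_pos, nprop, replace = TRUE)
      for (p in props) {
        ci <- (p - cds_start) %/% 3L
        cst <- cds_start + 3L * ci
        codon <- paste0(x[cst], x[cst + 1L], x[cst + 2L])
        newb <- .mutate_base(x[p], params$kappa)
        newcodon <- codon
        substr(newcodon, p - cst + 1L, p - cst + 1L) <- newb
        aa_old <- tab$aa[[codon]]
        aa_new <- tab$aa[[newcodon]]
        if (aa_new == "*") { stop_rej <- stop_rej + 1L; next }
        if (aa_new == aa_old) {
          x[p] <- newb; syn_ev <- syn_ev + 1L
        } else if (runif(1L) < params$omega) {
          x[p] <- newb; nonsyn_ev <- nonsyn_ev + 1L
        }
      }
    }
  }

  # --- truth: end-state differing sites, classified on the ancestral codons
  diff <- x != anc
  utr5_sub <- sum(diff[seq_len(cds_start - 1L)])
  utr3_sub <- if (cds_end < L) sum(diff[(cds_end + 1L):L]) else 0L
  cds_idx <- cds_start:cds_end
  cds_sub <- sum(diff[cds_idx])
  anc_codons <- split_codons(paste(anc[cds_idx], collapse = ""))
  n_cod <- length(anc_codons)
  # drop the terminal stop codon from classification
  sense <- anc_codons[-n_cod]
  cls <- matrix(tab$deg[sense, , drop = FALSE], ncol = 3L)
  site_tot <- table(factor(cls, levels = c("nondegenerate", "twofold",
                                           "threefold", "fourfold")))
  diff_cds <- matrix(diff[cds_idx][seq_len(3L * (n_cod - 1L))],
                     ncol = 3L, byrow = TRUE)
  sub_by_cls <- vapply(c("nondegenerate", "twofold", "threefold", "fourfold"),
                       function(cl) sum(diff_cds[cls == cl]), numeric(1))
  truth <- data.frame(
    omega = params$omega, kappa = params$kappa,
    t_cds = params$t_cds, t_utr = params$t_utr,
    utr5_sub = utr5_sub, cds_sub = cds_sub, utr3_sub = utr3_sub,
    nd_sub = sub_by_cls[["nondegenerate"]],
    twofold_sub = sub_by_cls[["twofold"]],
    threefold_sub = sub_by_cls[["threefold"]],
    fourfold_sub = sub_by_cls[["fourfold"]],
    nd_sites = as.integer(site_tot[["nondegenerate"]]),
    twofold_sites = as.integer(site_tot[["twofold"]]),
    threefold_sites = as.integer(site_tot[["threefold"]]),
    fourfold_sites = as.integer(site_tot[["fourfold"]]),
    syn_events = syn_ev, nonsyn_events = nonsyn_ev,
    proposals = nprop, stop_rejections = stop_rej)
  list(seq = paste(x, collapse = ""), truth = truth)
}

#' Evolve a whole ortholog cohort from an ancestral transcriptome
#'
#' Species A keeps the ancestral sequences; species B is derived by
#' [evolve_ortholog()] applied gene by gene.  `omega` (and the other rates)
#' may be vectors, recycled over genes, to simulate per-pair selection
#' regimes.
#'
#' @param ancestral an `"ancestral_transcriptome"`.
#' @param params an [evolution_params()]; `params$seed` seeds the whole pass.
#' @return an object of class `"ortholog_cohort"`: list with `seqs_a`,
#'   `seqs_b` (DNAStringSets named `A_<id>` / `B_<id>`), `anno` (per-species
#'   annotation rows), and `truth` (per-gene data.frame).
#' @export
evolve_transcriptome <- function(ancestral, params = evolution_params()) {
  stopifnot(inherits(ancestral, "ancestral_transcriptome"))
  if (!is.null(params$seed)) set.seed(as.integer(params$seed))
  n <- length(ancestral$seqs)
  omega <- rep_len(params$omega, n)
  kappa <- rep_len(params$kappa, n)
  t_cds <- rep_len(params$t_cds, n)
  t_utr <- rep_len(params$t_utr, n)
  anno <- ancestral$anno
  derived <- character(n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- structure(list(omega = omega[i], kappa = kappa[i], t_cds = t_cds[i],
                         t_utr = t_utr[i], seed = NULL),
                    class = "evolution_params")
    ev <- evolve_ortholog(as.character(ancestral$seqs[[i]]),
                          anno$cds_start[i], anno$cds_end[i], pi)
    derived[i] <- ev$seq
    truths[[i]] <- cbind(gene_id = anno$gene_id[i], ev$truth)
  }
  truth <- do.call(rbind, truths)
  anno_a <- transform(anno, gene_id = paste0("A_", gene_id), species = "A")
  anno_b <- transform(anno, gene_id = paste0("B_", gene_id), species = "B")
  anno2 <- rbind(anno_a, anno_b)
  anno2 <- anno2[, c("gene_id", "species", "cds_start", "cds_end",
                     "protein_label", "pathway_ids")]
  structure(list(
    seqs_a = setNames(ancestral$seqs, paste0("A_", anno$gene_id)),
    seqs_b = Biostrings::DNAStringSet(setNames(derived,
                                               paste0("B_", anno$gene_id))),
    anno = anno2,
    truth = truth),
    class = "ortholog_cohort")
}

#' Plant fold changes for a differential-expression simulation
#'
#' By default ~7.8% of genes are up-regulated and ~1.6% down-regulated in
#' species A (the proportions observed among orthologous gut gene pairs in
#' the two-species comparison this package emulates).  Planted |log2 fold|
#' magnitudes are `log2_min` plus an exponential tail with rate
#' `tail_rate`, capped at `log2_max`: with the defaults the majority of DE
#' genes fall between 1 and 2 and ~13.5% exceed 2, matching the published
#' log2-ratio distribution (41 of 304 up-regulated pairs above 2, extreme
#' values near 6.6).
#'
#' @param gene_ids character vector of gene ids.
#' @param frac_up,frac_down fractions of genes up/down-regulated in A.
#' @param log2_min minimum planted |log2 fold change|.
#' @param tail_rate rate of the exponential magnitude tail.
#' @param log2_max cap on the planted |log2 fold change|.
#' @param seed optional integer seed.
#' @return named numeric vector of fold changes (A relative to B).
#' @export
plant_fold_changes <- function(gene_ids, frac_up = 304 / 3910,
                               frac_down = 64 / 3910,
                               log2_min = 1, tail_rate = 2,
                               log2_max = 6.6, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(gene_ids)
  fold <- rep(1, n)
  n_up <- round(frac_up * n)
  n_dn <- round(frac_down * n)
  pick <- sample(n, n_up + n_dn)
  up <- pick[seq_len(n_up)]
  dn <- setdiff(pick, up)
  mag <- function(k) pmin(log2_min + stats::rexp(k, rate = tail_rate),
                          log2_max)
  fold[up] <- 2 ^ mag(n_up)
  fold[dn] <- 2 ^ -mag(n_dn)
  setNames(fold, gene_ids)
}

#' Simulate read counts for two libraries
#'
#' Counts are negative binomial (Poisson when `dispersion = 0`) with mean
#' proportional to library size x gene length x relative expression; fold
#' changes multiply species A's expression.
#'
#' @param gene_lengths named vector of transcript lengths (bp).
#' @param lib_size_a,lib_size_b total reads per library (> 0).
#' @param fold_changes named positive vector (default all 1); fold > 1
#'   means higher expression in library A.
#' @param dispersion nonnegative negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param expr_log_sd standard deviation of log-normal relative expression.
#' @param seed optional integer seed.
#' @return list with `counts` (data.frame `gene_id`, `count_A`, `count_B`)
#'   and `truth` (`gene_id`, `fold`, `log2_fold`, `de`, `mu_a`, `mu_b`).
#' @export
simulate_counts <- function(gene_lengths, lib_size_a, lib_size_b,
                            fold_changes = NULL, dispersion = 0,
                            expr_log_sd = 1, seed = NULL) {
  if (!is.numeric(lib_size_a) || !is.numeric(lib_size_b) ||
      lib_size_a <= 0 || lib_size_b <= 0)
    od_config_error("library sizes must be positive")
  if (dispersion < 0) od_config_error("dispersion must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- names(gene_lengths)
  if (is.null(ids)) od_input_error("gene_lengths must be named")
  n <- length(gene_lengths)
  fold <- rep(1, n); names(fold) <- ids
  if (!is.null(fold_changes)) {
    if (any(fold_changes <= 0)) od_config_error("fold changes must be positive")
    fold[names(fold_changes)] <- fold_changes
  }
  e <- rlnorm(n, meanlog = 0, sdlog = expr_log_sd)
  wa <- gene_lengths * e * fold
  wb <- gene_lengths * e
  mu_a <- lib_size_a * wa / sum(wa)
  mu_b <- lib_size_b * wb / sum(wb)
  draw <- function(mu) {
    if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  counts <- data.frame(gene_id = ids, count_A = draw(mu_a), count_B = draw(mu_b),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, fold = unname(fold),
                      log2_fold = unname(log2(fold)),
                      de = unname(abs(log2(fold)) >= 1),
                      mu_a = unname(mu_a), mu_b = unname(mu_b),
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Plant a tissue gene subset with one enriched pathway
#'
#' Draws a subset of genes in which members of `enriched_pathway` are
#' oversampled at the given odds ratio, emulating a tissue transcriptome
#' whose pathway usage differs from the whole-body background.
#'
#' @param anno annotation data.frame with `gene_id` and semicolon-joined
#'   `pathway_ids`.
#' @param subset_size number of genes in the tissue subset.
#' @param enriched_pathway pathway label to enrich.
#' @param odds_ratio sampling odds of pathway members relative to others.
#' @param seed optional integer seed.
#' @return character vector of subset gene ids.
#' @export
plant_tissue_subset <- function(anno, subset_size, enriched_pathway,
                                odds_ratio = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (odds_ratio <= 0) od_config_error("odds_ratio must be positive")
  in_pw <- vapply(strsplit(anno$pathway_ids, ";"),
                  function(p) enriched_pathway %in% p, logical(1))
  w <- ifelse(in_pw, odds_ratio, 1)
  sample(anno$gene_id, subset_size, prob = w)
}

#' Expand a semicolon-joined annotation into a pathway catalog
#' @param anno annotation data.frame with `gene_id` and `pathway_ids`.
#' @return data.frame with `pathway_id`, `gene_id`.
#' @export
pathway_catalog <- function(anno) {
  pw <- strsplit(anno$pathway_ids, ";")
  data.frame(pathway_id = unlist(pw),
             gene_id = rep(anno$gene_id, lengths(pw)),
             stringsAsFactors = FALSE)
}
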