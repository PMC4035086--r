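# Stage orchestration: simulate -> pair -> diverge -> kaks -> enrich -> de.
# Every stage reads/writes plain-text artifacts in config$outdir, logs to
# stderr, and records seeds and input checksums in a run manifest.

#' Pipeline configuration
#'
#' Holds every path, threshold and seed the pipeline uses.  Thresholds
#' default to the analysis' published cut-offs: best-hit pairs must overlap
#' more than 200 bp, coding regions shorter than 75 bp are removed,
#' pathways are enriched below p = 5.0e-3, and differential-expression
#' calls require |log2 ratio| > 1 at FDR < 1.0e-3.
#'
#' @param outdir output directory for all artifacts.
#' @param n_genes cohort size for the simulate stage.
#' @param params an [evolution_params()] object.
#' @param gc,n_pathways generator settings (see
#'   [generate_ancestral_transcriptome()]).
#' @param lib_size_a,lib_size_b simulated library sizes.
#' @param dispersion count overdispersion (see [simulate_counts()]).
#' @param min_overlap,min_identity,min_cds pairing thresholds.
#' @param enrich_alpha enrichment p-value threshold.
#' @param log2_threshold,fdr_threshold differential-expression thresholds.
#' @param excluded_pathways pathway ids dropped before enrichment.
#' @param subset_frac fraction of genes in the simulated tissue subset.
#' @param enriched_pathway,odds_ratio planted enrichment (see
#'   [plant_tissue_subset()]).
#' @param kaks_method `"YN00"` or `"NG86"`.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param candidates k-mer screen depth for the pairing stage.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir = "orthodiverge_out",
                            n_genes = 500L,
                            params = evolution_params(),
                            gc = 0.42, n_pathways = 30L,
                            lib_size_a = 4e5, lib_size_b = 4e5,
                            dispersion = 0.02,
                            min_overlap = 200L, min_identity = 0.9,
                            min_cds = 75L,
                            enrich_alpha = 5e-3,
                            log2_threshold = 1, fdr_threshold = 1e-3,
                            excluded_pathways = character(0),
                            subset_frac = 0.4,
                            enriched_pathway = "pw001", odds_ratio = 3,
                            kaks_method = "YN00",
                            seed = 1L, candidates = 5L) {
  cfg <- list(outdir = outdir, n_genes = as.integer(n_genes),
              params = params, gc = gc, n_pathways = as.integer(n_pathways),
              lib_size_a = lib_size_a, lib_size_b = lib_size_b,
              dispersion = dispersion,
              min_overlap = min_overlap, min_identity = min_identity,
              min_cds = min_cds, enrich_alpha = enrich_alpha,
              log2_threshold = log2_threshold, fdr_threshold = fdr_threshold,
              excluded_pathways = excluded_pathways,
              subset_frac = subset_frac,
              enriched_pathway = enriched_pathway, odds_ratio = odds_ratio,
              kaks_method = kaks_method,
              seed = as.integer(seed), candidates = candidates)
  pos <- c("n_genes", "lib_size_a", "lib_size_b", "min_overlap", "min_cds",
           "enrich_alpha", "log2_threshold", "fdr_threshold")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    od_config_error(sprintf("config field %s must be positive", f))
  if (cfg$min_identity < 0 || cfg$min_identity > 1)
    od_config_error("min_identity must lie in [0, 1]")
  if (!cfg$kaks_method %in% c("YN00", "NG86"))
    od_config_error("kaks_method must be YN00 or NG86")
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as plain key=value text
#' @param config a `"pipeline_config"`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- c(config[setdiff(names(config), c("params", "excluded_pathways"))],
            list(omega = config$params$omega, kappa = config$params$kappa,
                 t_cds = config$params$t_cds, t_utr = config$params$t_utr,
                 excluded_pathways = paste(config$excluded_pathways,
                                           collapse = ";")))
  writeLines(sprintf("%s=%s", names(flat),
                     vapply(flat, function(v) paste(format(v, digits = 15),
                                                    collapse = ";"),
                            character(1))),
             path)
  invisible(path)
}

#' Read a plain key=value pipeline configuration
#' @param path file written by [write_pipeline_config()].
#' @return a `"pipeline_config"` (unknown keys raise a config error).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    od_input_error(sprintf("required input file is missing: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  known <- c(names(formals(pipeline_config)), "omega", "kappa", "t_cds",
             "t_utr")
  bad <- setdiff(keys, c(known, "params"))
  if (length(bad))
    od_config_error(sprintf("unknown config keys: %s",
                            paste(bad, collapse = ", ")))
  vv <- setNames(as.list(vals), keys)
  num <- function(k, d) if (k %in% keys) as.numeric(vv[[k]]) else d
  chr <- function(k, d) if (k %in% keys) vv[[k]] else d
  excl <- chr("excluded_pathways", "")
  pipeline_config(
    outdir = chr("outdir", "orthodiverge_out"),
    n_genes = num("n_genes", 500), gc = num("gc", 0.42),
    n_pathways = num("n_pathways", 30),
    params = evolution_params(omega = num("omega", 0.07),
                              kappa = num("kappa", 2),
                              t_cds = num("t_cds", 0.0248),
                              t_utr = num("t_utr", 0.0166)),
    lib_size_a = num("lib_size_a", 4e5), lib_size_b = num("lib_size_b", 4e5),
    dispersion = num("dispersion", 0.02),
    min_overlap = num("min_overlap", 200),
    min_identity = num("min_identity", 0.9), min_cds = num("min_cds", 75),
    enrich_alpha = num("enrich_alpha", 5e-3),
    log2_threshold = num("log2_threshold", 1),
    fdr_threshold = num("fdr_threshold", 1e-3),
    excluded_pathways = if (nzchar(excl)) strsplit(excl, ";")[[1]]
                        else character(0),
    subset_frac = num("subset_frac", 0.4),
    enriched_pathway = chr("enriched_pathway", "pw001"),
    odds_ratio = num("odds_ratio", 3),
    kaks_method = chr("kaks_method", "YN00"),
    seed = num("seed", 1), candidates = num("candidates", 5))
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

.update_manifest <- function(cfg, stage, outputs) {
  path <- file.path(cfg$outdir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else list()
  manifest[[stage]] <- list(
    package_version = as.character(utils::packageVersion("orthodiverge")),
    seed = cfg$seed,
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(cfg$outdir, outputs))), outputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
}

.need <- function(cfg, files, stage) {
  for (f in files) {
    p <- file.path(cfg$outdir, f)
    if (!file.exists(p))
      od_input_error(sprintf(
        "stage '%s' needs %s; run the upstream stage first", stage, p))
  }
}

.rebuild_pairs <- function(cfg) {
  seqs_a <- read_transcripts(file.path(cfg$outdir, "speciesA.fasta"))
  seqs_b <- read_transcripts(file.path(cfg$outdir, "speciesB.fasta"))
  anno <- read_annotations(file.path(cfg$outdir, "annotations.tsv"))
  tab <- .read_tsv(file.path(cfg$outdir, "pairs.tsv"))
  partition_regions(tab, seqs_a, seqs_b, anno, cfg$min_cds)$pairs
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` writes the synthetic fixtures; `pair` runs the
#' ortholog cascade and writes `pairs.tsv` / `rejected.tsv`; `diverge`
#' writes the five-row `divergence.tsv`; `kaks` writes `kaks.tsv`;
#' `enrich` writes `enrichment.tsv`; `de` writes `de.tsv`; `all` chains
#' them.  Reruns with the same config and seeds produce byte-identical
#' artifacts.
#'
#' @param stage one of `"simulate"`, `"pair"`, `"diverge"`, `"kaks"`,
#'   `"enrich"`, `"de"`, `"all"`.
#' @param config a [pipeline_config()].
#' @return invisibly, a character vector of the artifact paths written.
#' @export
run_stage <- function(stage = c("all", "simulate", "pair", "diverge",
                                "kaks", "enrich", "de"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- c(run_stage("simulate", config), run_stage("pair", config),
             run_stage("diverge", config), run_stage("kaks", config),
             run_stage("enrich", config), run_stage("de", config))
    return(invisible(out))
  }
  t0 <- proc.time()[["elapsed"]]
  written <- switch(stage,
    simulate = {
      anc <- generate_ancestral_transcriptome(config$n_genes, gc = config$gc,
                                              n_pathways = config$n_pathways,
                                              seed = config$seed)
      prm <- config$params
      prm$seed <- config$seed + 1L
      cohort <- evolve_transcriptome(anc, prm)
      lens <- setNames(Biostrings::width(anc$seqs), anc$anno$gene_id)
      fold <- plant_fold_changes(anc$anno$gene_id, seed = config$seed + 2L)
      counts <- simulate_counts(lens, config$lib_size_a, config$lib_size_b,
                                fold, dispersion = config$dispersion,
                                seed = config$seed + 3L)
      subset <- plant_tissue_subset(anc$anno,
                                    round(config$subset_frac * config$n_genes),
                                    config$enriched_pathway,
                                    config$odds_ratio,
                                    seed = config$seed + 4L)
      write_fixtures(cohort, config$outdir, counts = counts,
                     catalog = pathway_catalog(anc$anno),
                     tissue_subset = sort(subset))
      c("speciesA.fasta", "speciesB.fasta", "annotations.tsv", "truth.tsv",
        "counts.tsv", "counts_truth.tsv", "catalog.tsv", "tissue_subset.tsv")
    },
    pair = {
      .need(config, c("speciesA.fasta", "speciesB.fasta", "annotations.tsv"),
            "pair")
      seqs_a <- read_transcripts(file.path(config$outdir, "speciesA.fasta"))
      seqs_b <- read_transcripts(file.path(config$outdir, "speciesB.fasta"))
      anno <- read_annotations(file.path(config$outdir, "annotations.tsv"))
      orth <- find_orthologs(seqs_a, seqs_b, anno,
                             min_overlap = config$min_overlap,
                             min_identity = config$min_identity,
                             min_cds = config$min_cds,
                             candidates = config$candidates)
      .write_tsv(orth$table, file.path(config$outdir, "pairs.tsv"),
                 "retained ortholog pairs; region widths in alignment columns")
      .write_tsv(orth$rejected, file.path(config$outdir, "rejected.tsv"),
                 "pairs dropped by the filter cascade, with reason codes")
      c("pairs.tsv", "rejected.tsv")
    },
    diverge = {
      .need(config, c("pairs.tsv"), "diverge")
      pairs <- .rebuild_pairs(config)
      div <- divergence_table(pairs)
      .write_tsv(div, file.path(config$outdir, "divergence.tsv"),
                 "divergence per region/site class; fractions, not percent")
      "divergence.tsv"
    },
    kaks = {
      .need(config, c("pairs.tsv"), "kaks")
      pairs <- .rebuild_pairs(config)
      res <- kaks(pairs, method = config$kaks_method)
      .write_tsv(kaks_table(res), file.path(config$outdir, "kaks.tsv"))
      "kaks.tsv"
    },
    enrich = {
      .need(config, c("catalog.tsv", "tissue_subset.tsv", "annotations.tsv"),
            "enrich")
      catalog <- read_catalog(file.path(config$outdir, "catalog.tsv"))
      subset <- .read_tsv(file.path(config$outdir, "tissue_subset.tsv"))$gene_id
      anno <- read_annotations(file.path(config$outdir, "annotations.tsv"))
      background <- unique(sub("^[AB]_", "", anno$gene_id))
      enr <- enrich_pathways(subset, background, catalog,
                             alpha = config$enrich_alpha,
                             exclude = config$excluded_pathways)
      .write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
      "enrichment.tsv"
    },
    de = {
      .need(config, c("counts.tsv", "pairs.tsv", "annotations.tsv"), "de")
      counts <- read_counts(file.path(config$outdir, "counts.tsv"))
      tab <- .read_tsv(file.path(config$outdir, "pairs.tsv"))
      seqs_a <- read_transcripts(file.path(config$outdir, "speciesA.fasta"))
      seqs_b <- read_transcripts(file.path(config$outdir, "speciesB.fasta"))
      core <- sub("^A_", "", tab$gene_A)
      counts <- counts[counts$gene_id %in% core, , drop = FALSE]
      la <- setNames(Biostrings::width(seqs_a), sub("^A_", "", names(seqs_a)))
      lb <- setNames(Biostrings::width(seqs_b), sub("^B_", "", names(seqs_b)))
      de <- diff_expression(counts, la, lb,
                            log2_threshold = config$log2_threshold,
                            fdr_threshold = config$fdr_threshold)
      .write_tsv(de, file.path(config$outdir, "de.tsv"),
                 "orthologous genes only; log2_ratio is A over B")
      "de.tsv"
    })
  .update_manifest(config, stage, written)
  .stage_log(stage, sprintf("wrote %s (%.1fs)",
                            paste(written, collapse = ", "),
                            proc.time()[["elapsed"]] - t0))
  invisible(file.path(config$outdir, written))
}
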