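# Plain-text readers and writers for the pipeline's FASTA/TSV dialect.
# All coordinate columns are 1-based and inclusive; TSV files say so in a
# leading comment line and are read back with comment.char = "#".

.write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path))
    od_input_error(sprintf("required input file is missing: %s", path))
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a transcript set from FASTA
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path))
    od_input_error(sprintf("required input file is missing: %s", path))
  Biostrings::readDNAStringSet(path)
}

#' Read an annotation table (gene_id, species, cds_start, cds_end,
#' protein_label, pathway_ids)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotations <- function(path) .read_tsv(path)

#' Read a per-gene count table (gene_id, count_A, count_B)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_counts <- function(path) .read_tsv(path)

#' Read a pathway catalog (pathway_id, gene_id)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_catalog <- function(path) .read_tsv(path)

#' Write synthetic fixtures to a directory
#'
#' Writes `speciesA.fasta`, `speciesB.fasta` (60-column wrap),
#' `annotations.tsv`, `truth.tsv`, and optionally `counts.tsv`,
#' `counts_truth.tsv`, `catalog.tsv` and `tissue_subset.tsv`.  Outputs are
#' byte-identical under identical seeds.
#'
#' @param cohort an `"ortholog_cohort"` from [evolve_transcriptome()].
#' @param dir output directory (created if absent).
#' @param counts optional result of [simulate_counts()].
#' @param catalog optional pathway catalog data.frame.
#' @param tissue_subset optional character vector of subset gene ids.
#' @return invisibly, the directory.
#' @export
write_fixtures <- function(cohort, dir, counts = NULL, catalog = NULL,
                           tissue_subset = NULL) {
  stopifnot(inherits(cohort, "ortholog_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(cohort$seqs_a, file.path(dir, "speciesA.fasta"),
                              width = 60L)
  Biostrings::writeXStringSet(cohort$seqs_b, file.path(dir, "speciesB.fasta"),
                              width = 60L)
  .write_tsv(cohort$anno, file.path(dir, "annotations.tsv"),
             "cds_start/cds_end are 1-based, inclusive")
  .write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
             "generator ground truth: realized differing sites per region/class")
  if (!is.null(counts)) {
    .write_tsv(counts$counts, file.path(dir, "counts.tsv"),
               "per-gene read counts for libraries A and B")
    .write_tsv(counts$truth, file.path(dir, "counts_truth.tsv"),
               "planted fold changes; de = |log2 fold| >= 1")
  }
  if (!is.null(catalog))
    .write_tsv(catalog, file.path(dir, "catalog.tsv"),
               "pathway membership: one row per (pathway_id, gene_id)")
  if (!is.null(tissue_subset))
    .write_tsv(data.frame(gene_id = tissue_subset),
               file.path(dir, "tissue_subset.tsv"),
               "tissue gene subset for enrichment against the full background")
  invisible(dir)
}
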