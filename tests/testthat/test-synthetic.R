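# The simulator is first-class code: its invariants (CDS structure, GC
# calibration, determinism, selection behaviour) are what downstream
# recovery tests lean on.

test_that("ancestral genes have valid structure and forced lengths", {
  anc <- generate_ancestral_transcriptome(1, utr5_len = 100, cds_len = 300,
                                          utr3_len = 100, seed = 7)
  expect_equal(Biostrings::width(anc$seqs), 500)
  expect_equal(anc$anno$cds_start, 101)
  expect_equal(anc$anno$cds_end, 400)

  anc2 <- generate_ancestral_transcriptome(25, seed = 3)
  for (i in seq_len(25)) {
    s <- as.character(anc2$seqs[[i]])
    cds <- substr(s, anc2$anno$cds_start[i], anc2$anno$cds_end[i])
    cod <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(cod[length(cod)] %in% c("TAA", "TAG", "TGA"))
    internal_aa <- vapply(cod[-length(cod)], oracle_translate, character(1))
    expect_false(any(internal_aa == "*"))
    n_pw <- length(strsplit(anc2$anno$pathway_ids[i], ";")[[1]])
    expect_true(n_pw >= 1 && n_pw <= 3)
  }
})

test_that("generated GC tracks the requested fraction", {
  anc <- generate_ancestral_transcriptome(200, gc = 0.43, seed = 1)
  s <- paste(as.character(anc$seqs), collapse = "")
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.43), 0.02)
})

test_that("identical seeds give byte-identical fixtures", {
  build <- function(dir) {
    anc <- generate_ancestral_transcriptome(15, seed = 11)
    coh <- evolve_transcriptome(anc, evolution_params(seed = 12))
    lens <- setNames(Biostrings::width(anc$seqs), anc$anno$gene_id)
    cts <- simulate_counts(lens, 1e4, 1e4,
                           plant_fold_changes(anc$anno$gene_id, seed = 13),
                           dispersion = 0.02, seed = 14)
    write_fixtures(coh, dir, counts = cts,
                   catalog = pathway_catalog(anc$anno))
    dir
  }
  d1 <- build(withr::local_tempdir())
  d2 <- build(withr::local_tempdir())
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("zero rates leave the ortholog identical; omega 0 preserves the protein", {
  anc <- generate_ancestral_transcriptome(5, seed = 21)
  zero <- evolution_params(t_cds = 0, t_utr = 0, seed = 22)
  for (i in 1:5) {
    ev <- evolve_ortholog(as.character(anc$seqs[[i]]),
                          anc$anno$cds_start[i], anc$anno$cds_end[i], zero)
    expect_identical(ev$seq, as.character(anc$seqs[[i]]))
    expect_equal(ev$truth$cds_sub + ev$truth$utr5_sub + ev$truth$utr3_sub, 0)
  }
  strong <- evolution_params(omega = 0, t_cds = 0.5, t_utr = 0, seed = 23)
  for (i in 1:5) {
    ev <- evolve_ortholog(as.character(anc$seqs[[i]]),
                          anc$anno$cds_start[i], anc$anno$cds_end[i], strong)
    cds_a <- substr(as.character(anc$seqs[[i]]), anc$anno$cds_start[i],
                    anc$anno$cds_end[i])
    cds_b <- substr(ev$seq, anc$anno$cds_start[i], anc$anno$cds_end[i])
    aa <- function(s) paste(vapply(
      substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3)),
      oracle_translate, character(1)), collapse = "")
    expect_identical(aa(cds_a), aa(cds_b))
    expect_equal(ev$truth$nonsyn_events, 0)
  }
})

test_that("nd-site divergence is monotone in omega and neutral at omega=1, kappa=1", {
  sub_rates <- vapply(c(0, 0.25, 1), function(om) {
    tc <- test_cohort(80, seed = 31,
                      evolution_params(omega = om, kappa = 2, t_cds = 0.05,
                                       t_utr = 0))
    tr <- tc$cohort$truth
    sum(tr$nd_sub) / sum(tr$nd_sites)
  }, numeric(1))
  expect_true(all(diff(sub_rates) > 0))
  expect_equal(sub_rates[1], 0)

  tc <- test_cohort(80, seed = 33,
                    evolution_params(omega = 1, kappa = 1, t_cds = 0.05,
                                     t_utr = 0))
  tr <- tc$cohort$truth
  p_nd <- sum(tr$nd_sub) / sum(tr$nd_sites)
  p_4d <- sum(tr$fourfold_sub) / sum(tr$fourfold_sites)
  ci <- stats::prop.test(c(sum(tr$nd_sub), sum(tr$fourfold_sub)),
                         c(sum(tr$nd_sites), sum(tr$fourfold_sites)))
  expect_gt(ci$p.value, 0.01)
  expect_lt(abs(p_nd - p_4d) / p_4d, 0.2)
})

test_that("fourfold-site divergence dominates nd divergence under purifying selection", {
  tc <- test_cohort(120, seed = 41,
                    evolution_params(omega = 0.07, kappa = 2, t_cds = 0.0248,
                                     t_utr = 0.0166))
  tr <- tc$cohort$truth
  fold <- (sum(tr$fourfold_sub) / sum(tr$fourfold_sites)) /
    (sum(tr$nd_sub) / sum(tr$nd_sites))
  expect_gt(fold, 5)
})

test_that("simulated counts respect fold changes and error on bad input", {
  lens <- setNames(rep(1000L, 400), sprintf("g%03d", 1:400))
  fold <- setNames(rep(1, 400), names(lens))
  fold["g007"] <- 4
  sim <- simulate_counts(lens, 5e5, 5e5, fold, dispersion = 0, seed = 51)
  r <- rpkm(sim$counts$count_A, 1000, 5e5) /
    rpkm(sim$counts$count_B, 1000, 5e5)
  expect_lt(abs(log2(r[sim$counts$gene_id == "g007"]) - 2), 0.35)
  expect_true(sim$truth$de[sim$truth$gene_id == "g007"])
  expect_equal(sum(sim$truth$de), 1)
  expect_error(simulate_counts(lens, 0, 1e5), class = "od_config_error")
})

test_that("planted tissue subsets oversample the enriched pathway", {
  anc <- generate_ancestral_transcriptome(400, seed = 61)
  sub <- plant_tissue_subset(anc$anno, 150, "pw001", odds_ratio = 3,
                             seed = 62)
  expect_length(sub, 150)
  in_pw <- vapply(strsplit(anc$anno$pathway_ids, ";"),
                  function(p) "pw001" %in% p, logical(1))
  frac_sub <- mean(sub %in% anc$anno$gene_id[in_pw])
  frac_bg <- mean(in_pw)
  expect_gt(frac_sub, frac_bg)
})
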