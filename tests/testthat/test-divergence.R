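test_that("degeneracy classification matches exhaustive enumeration", {
  # spot checks from first principles
  expect_equal(classify_degeneracy("GCT", 3), "fourfold")
  expect_equal(classify_degeneracy("ATG", 1:3),
               rep("nondegenerate", 3))
  expect_false(classify_degeneracy("CTA", 1) == "nondegenerate")
  expect_error(classify_degeneracy("TAA", 1), class = "od_input_error")

  # all 61 sense codons x 3 positions against the seqinr-based oracle
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (cod in sense) {
    for (pos in 1:3) {
      expect_equal(classify_degeneracy(cod, pos), oracle_degeneracy(cod, pos),
                   label = paste(cod, pos))
    }
  }
})

test_that("region divergence counts substitutions over compared columns", {
  d <- region_divergence(strrep("A", 100), strrep("A", 100))
  expect_equal(d$divergence, 0)

  a200 <- paste(rep("ACGT", 50), collapse = "")
  b200 <- a200
  substr(b200, 1, 1) <- "G"; substr(b200, 50, 50) <- "A"
  substr(b200, 120, 120) <- "C"
  d2 <- region_divergence(a200, b200)
  expect_equal(d2$substitutions, 3)
  expect_equal(d2$divergence, 0.015)

  # gap and N columns are excluded from the comparison
  d3 <- region_divergence("AC-GT", "ACAGA")
  expect_equal(d3$compared_bp, 4)
  expect_equal(d3$substitutions, 1)
  expect_equal(d3$divergence, 0.25)
  d4 <- region_divergence("ANCG", "AACG")
  expect_equal(d4$compared_bp, 3)
  expect_equal(d4$substitutions, 0)

  expect_error(region_divergence("ACG", "AC"), class = "od_input_error")
})

test_that("divergence is symmetric and permutation-invariant", {
  set.seed(23)
  a <- paste(sample(c("A", "C", "G", "T", "-"), 300, TRUE,
                    prob = c(rep(0.24, 4), 0.04)), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T", "-"), 300, TRUE,
                    prob = c(rep(0.24, 4), 0.04)), collapse = "")
  d_ab <- region_divergence(a, b)
  d_ba <- region_divergence(b, a)
  expect_equal(d_ab$divergence, d_ba$divergence)
  expect_equal(d_ab$compared_bp, d_ba$compared_bp)

  perm <- sample(300)
  pa <- paste(strsplit(a, "")[[1]][perm], collapse = "")
  pb <- paste(strsplit(b, "")[[1]][perm], collapse = "")
  d_p <- region_divergence(pa, pb)
  expect_equal(d_p$substitutions, d_ab$substitutions)
  expect_equal(d_p$compared_bp, d_ab$compared_bp)
})

test_that("site-class divergence matches the hand-enumerated GCN case", {
  a <- strrep("GCT", 10)
  b <- paste0(strrep("GCT", 9), "GCC")
  sc <- site_class_divergence(a, b)
  expect_equal(sc$compared_bp[sc$class == "fourfold"], 10)
  expect_equal(sc$substitutions[sc$class == "fourfold"], 1)
  expect_equal(sc$divergence[sc$class == "fourfold"], 0.10)
  expect_equal(sc$compared_bp[sc$class == "nd"], 20)
  expect_equal(sc$substitutions[sc$class == "nd"], 0)

  idn <- site_class_divergence(a, a)
  expect_equal(idn$substitutions, c(0, 0))
  expect_lte(sum(idn$compared_bp), nchar(a))

  expect_error(site_class_divergence("GCTA", "GCTA"),
               class = "od_input_error")
})

test_that("simulated cohorts recover the planted nd/4d divergence ratio", {
  tc <- test_cohort(120, seed = 41,
                    evolution_params(omega = 0.07, kappa = 2, t_cds = 0.0248,
                                     t_utr = 0.0166))
  coh <- tc$cohort
  tr <- coh$truth
  measured <- vapply(seq_along(coh$seqs_a), function(i) {
    cs <- coh$anno$cds_start[i]; ce <- coh$anno$cds_end[i]
    a <- substr(as.character(coh$seqs_a[[i]]), cs, ce - 3)
    b <- substr(as.character(coh$seqs_b[[i]]), cs, ce - 3)
    sc <- site_class_divergence(a, b)
    c(sc$substitutions, sc$compared_bp)
  }, numeric(4))
  ratio_meas <- (sum(measured[2, ]) / sum(measured[4, ])) /
    (sum(measured[1, ]) / sum(measured[3, ]))
  ratio_true <- (sum(tr$fourfold_sub) / sum(tr$fourfold_sites)) /
    (sum(tr$nd_sub) / sum(tr$nd_sites))
  expect_lt(abs(ratio_meas - ratio_true) / ratio_true, 0.30)
})

test_that("summaries average per-pair divergences and pool counts", {
  pp <- data.frame(pair_id = c("p1", "p2"), region = "cds",
                   compared_bp = c(100, 100), substitutions = c(1, 2),
                   divergence = c(0.01, 0.02), gc = c(0.4, 0.5))
  sm <- summarize_divergence(pp)
  cds <- sm[sm$region == "cds", ]
  expect_equal(cds$mean_divergence, 0.015)
  expect_equal(cds$se, 0.005)
  expect_equal(cds$pooled_divergence, 3 / 200)
  expect_equal(cds$compared_kb, 0.2)

  # pooled divergence equals the compared-bp-weighted mean (conservation)
  expect_equal(cds$pooled_divergence,
               weighted.mean(pp$divergence, pp$compared_bp))

  one <- summarize_divergence(pp[1, ])
  expect_equal(one$se[one$region == "cds"], 0)
  expect_true(one$single_locus[one$region == "cds"])

  expect_error(summarize_divergence(list()), class = "od_input_error")
})

test_that("UTR divergence sits between nd and fourfold levels in the default cohort", {
  tc <- test_cohort(120, seed = 41,
                    evolution_params(omega = 0.07, kappa = 2, t_cds = 0.0248,
                                     t_utr = 0.0166))
  coh <- tc$cohort
  orth <- find_orthologs(coh$seqs_a, coh$seqs_b, coh$anno)
  div <- divergence_table(orth$pairs)
  g <- function(r) div$mean_divergence[div$region == r]
  expect_gt(g("utr5"), g("nd"))
  expect_gt(g("utr3"), g("nd"))
  expect_gt(g("fourfold"), g("utr5"))
  expect_gt(g("cds"), g("nd"))
  expect_lt(g("cds"), g("fourfold"))
})
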