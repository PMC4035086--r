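# helpers to build tiny annotated transcript sets by hand
.mk_anno <- function(ids, cds_start, cds_end, protein) {
  data.frame(gene_id = ids, cds_start = cds_start, cds_end = cds_end,
             protein_label = protein, stringsAsFactors = FALSE)
}

test_that("same-protein filter keeps equal labels and drops ambiguity", {
  pairs <- data.frame(gene_A = c("a1", "a2", "a3", "a4"),
                      gene_B = c("b1", "b2", "b3", "b4"))
  anno <- .mk_anno(c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
                   1, 3,
                   c("P1", "P1", "P1", "P2;P3", "P1", "P2", NA, "P2"))
  out <- same_protein_filter(pairs, anno)
  expect_equal(out$gene_A, "a1")           # (P1,P1) kept
  expect_equal(out$shared_protein_label, "P1")
  # (P1,P2) mismatch, (P1,NA) missing, (multi,P2) ambiguous: all dropped
})

test_that("regions partition by projected CDS with correct widths", {
  # transcript of 1000 nt, CDS occupying positions 101..700 (600 nt)
  set.seed(11)
  cds <- random_cds(199, seed = 12)            # 597 nt sense + stop below
  cds <- paste0(cds, "TAA")
  u5 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  u3 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  s <- paste0(u5, cds, u3)
  anno <- .mk_anno(c("a", "b"), 101, 700, "P1")
  pr <- partition_regions(data.frame(gene_A = "a", gene_B = "b"),
                          c(a = s), c(b = s), anno)
  expect_length(pr$pairs, 1)
  rg <- pr$pairs[[1]]$regions
  expect_equal(nchar(rg$utr5$a), 100)
  expect_equal(nchar(rg$cds$a), 600)
  expect_equal(nchar(rg$utr3$a), 300)
  # gap-free: region lengths sum to overlap
  expect_equal(sum(nchar(c(rg$utr5$a, rg$cds$a, rg$utr3$a))),
               pr$pairs[[1]]$overlap_bp)
  # codon-aligned CDS drops the terminal stop
  expect_equal(nchar(pr$pairs[[1]]$codon_cds$a), 597)

  # CDS coordinates outside the sequence are an input error
  bad <- .mk_anno(c("a", "b"), 101, 1200, "P1")
  expect_error(partition_regions(data.frame(gene_A = "a", gene_B = "b"),
                                 c(a = s), c(b = s), bad),
               class = "od_input_error")
})

test_that("short and stop-containing CDSs are rejected with reason codes", {
  set.seed(13)
  # 60 bp CDS (20 codons incl. start/stop) -> below the 75 bp floor
  cds60 <- paste0("ATG", paste(rep("GCT", 17), collapse = ""), "TAA")
  flank <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  s1 <- paste0(flank, cds60, flank)
  anno1 <- .mk_anno(c("a", "b"), 201, 260, "P1")
  pr1 <- partition_regions(data.frame(gene_A = "a", gene_B = "b"),
                           c(a = s1), c(b = s1), anno1)
  expect_length(pr1$pairs, 0)
  expect_equal(pr1$rejected$reason, "cds_too_short")

  # a planted in-frame TAA inside species B's CDS
  cds_ok <- paste0("ATG", paste(rep(c("GCT", "AAA", "CCG"), 40), collapse = ""),
                   "TAA")
  s2 <- paste0(flank, cds_ok, flank)
  s2b <- s2
  substr(s2b, 201 + 33, 201 + 35) <- "TAA"   # codon 12 of the CDS
  anno2 <- .mk_anno(c("a", "b"), 201, 200 + nchar(cds_ok), "P1")
  pr2 <- partition_regions(data.frame(gene_A = "a", gene_B = "b"),
                           c(a = s2), c(b = s2b), anno2)
  expect_length(pr2$pairs, 0)
  expect_equal(pr2$rejected$reason, "internal_stop")
})

test_that("the filter cascade is order-independent in its final pair set", {
  tc <- test_cohort(40, seed = 81)
  coh <- tc$cohort
  rbh <- reciprocal_best_hits(coh$seqs_a, coh$seqs_b, min_overlap = 0,
                              min_identity = 0)
  run <- function(order) {
    p <- rbh
    for (step in order) {
      p <- switch(step,
        overlap = p[p$overlap_bp > 200, , drop = FALSE],
        protein = same_protein_filter(p, coh$anno),
        cds = {
          kept <- partition_regions(p, coh$seqs_a, coh$seqs_b, coh$anno)
          p[p$gene_A %in% vapply(kept$pairs, `[[`, character(1), "gene_A"), ,
            drop = FALSE]
        })
    }
    sort(paste(p$gene_A, p$gene_B))
  }
  o1 <- run(c("overlap", "protein", "cds"))
  o2 <- run(c("protein", "cds", "overlap"))
  o3 <- run(c("cds", "overlap", "protein"))
  expect_identical(o1, o2)
  expect_identical(o1, o3)
  expect_gt(length(o1), 0)
})

test_that("tissue-specific genes are those without reciprocal partners", {
  set.seed(17)
  shared1 <- random_cds(150, seed = 91)
  shared2 <- random_cds(150, seed = 92)
  lonely <- random_cds(150, seed = 93)
  body_extra <- random_cds(150, seed = 94)
  tissue <- c(t1 = shared1, t2 = shared2, t3 = lonely)
  body <- c(w1 = shared1, w2 = shared2, w4 = body_extra)
  og <- orthogroups_and_specific_genes(tissue, body, candidates = Inf)
  expect_setequal(og$groups$tissue_gene, c("t1", "t2"))
  expect_equal(og$specific, "t3")
  expect_equal(og$proportion, 1 / 3)
})

test_that("pairing recovers planted orthologs on a small cohort", {
  tc <- test_cohort(40, seed = 81)
  coh <- tc$cohort
  orth <- find_orthologs(coh$seqs_a, coh$seqs_b, coh$anno)
  got <- sub("^A_", "", orth$table$gene_A)
  expect_true(all(sub("^B_", "", orth$table$gene_B) == got))  # no false pairs
  expect_gte(length(got), 39)
})
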