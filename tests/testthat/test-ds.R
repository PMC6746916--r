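.design1 <- data.frame(sample = c("Rp_1", "FRp_1"),
                       condition = factor(c("Rp", "FRp"),
                                          levels = c("Rp", "FRp")))

test_that("PSI follows its defining ratio", {
  expect_equal(compute_psi(10, 10), 50)
  expect_equal(compute_psi(7, 0), 100)
  expect_equal(compute_psi(30, 10), 75)
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 5))
})

test_that("PIR follows its defining ratio", {
  expect_equal(compute_pir(10, 10, 5), 100 * 20 / 30)
  expect_equal(compute_pir(4, 3, 0), 100)
  expect_equal(compute_pir(0, 0, 12), 0)
  expect_true(is.na(compute_pir(0, 0, 0)))
})

test_that("PIR is monotone in retention and exclusion support", {
  base <- compute_pir(10, 10, 5)
  expect_gte(compute_pir(11, 10, 5), base)
  expect_gte(compute_pir(10, 12, 5), base)
  expect_lte(compute_pir(10, 10, 6), base)
  # across a random grid
  for (i in 1:20) {
    e1 <- sample(0:50, 1); e2 <- sample(0:50, 1); j <- sample(1:50, 1)
    expect_gte(compute_pir(e1 + 1, e2, j), compute_pir(e1, e2, j))
    expect_lte(compute_pir(e1, e2, j + 1), compute_pir(e1, e2, j))
  }
})

test_that("DS calls respect the strict FDR and delta thresholds", {
  expect_true(call_ds(0.14, 0.6))
  expect_false(call_ds(0.10, 0.4))
  expect_false(call_ds(0.15, 20))         # fdr == 0.15 fails strict <
  expect_false(call_ds(0.14, 0.5))        # delta == 0.5 fails strict >
  expect_true(call_ds(NA, 12, "novel_junction"))
  expect_false(call_ds(NA, 10, "novel_junction"))  # 10 fails strict >
  expect_false(call_ds(0.01, NA))         # untestable: never flagged
})

test_that("bin filter enforces the gene gate and bin thresholds", {
  bins <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 101, 201), c(100, 200, 300)),
    bin_id = c("b1", "b2", "b3"), gene_id = c("gA", "gA", "gB"),
    kind = "exon", as_class = "none")
  gene_counts <- matrix(c(100, 100,   # gA: expressed everywhere
                          100, 8),    # gB: fails FRp -> gate closes
                        2, 2, byrow = TRUE,
                        dimnames = list(c("gA", "gB"), .design1$sample))
  gcm <- structure(list(counts = gene_counts,
                        rd = gene_counts / c(200, 100),
                        width = c(gA = 200, gB = 100)),
                   class = "count_matrix")
  bin_counts <- matrix(c(6, 6,     # b1: 6 > 5, ratio (6/100)/(100/200) ok
                         100, 100, # b2: reads fine but width 10k -> ratio low
                         50, 1),   # b3: parent gene gated out
                       3, 2, byrow = TRUE,
                       dimnames = list(c("b1", "b2", "b3"), .design1$sample))
  bcm <- structure(list(counts = bin_counts,
                        rd = bin_counts / c(100, 10000, 100),
                        width = c(b1 = 100, b2 = 10000, b3 = 100)),
                   class = "count_matrix")
  keep <- filter_bins(bcm, gcm, bins, .design1)
  expect_identical(unname(keep), c(TRUE, FALSE, FALSE))
})

test_that("usage test ignores expression changes but sees usage changes", {
  design <- data.frame(sample = paste0(c("Rp_", "Rp_", "Rp_", "FRp_", "FRp_",
                                         "FRp_"), c(1:3, 1:3)),
                       condition = factor(rep(c("Rp", "FRp"), each = 3),
                                          levels = c("Rp", "FRp")))
  bins <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
    bin_id = "b1", gene_id = "gA", kind = "exon", as_class = "none")
  mk <- function(bin, gene) {
    bcm <- structure(list(counts = matrix(bin, 1, 6,
                            dimnames = list("b1", design$sample)),
                          rd = NULL, width = c(b1 = 100)),
                     class = "count_matrix")
    gcm <- structure(list(counts = matrix(gene, 1, 6,
                            dimnames = list("gA", design$sample)),
                          rd = NULL, width = c(gA = 500)),
                     class = "count_matrix")
    test_bins_normalized(bcm, gcm, bins, design)
  }
  # gene doubles, bin doubles with it: usage unchanged
  quiet <- mk(c(100, 110, 95, 200, 210, 205), c(500, 530, 480, 1000, 1040, 1010))
  expect_gt(quiet$pvalue, 0.2)
  expect_lt(abs(quiet$logFC), 0.2)
  # gene doubles, bin constant: usage halves, detectable at high counts
  loud <- mk(c(500, 520, 490, 500, 490, 515), c(1000, 1050, 980, 2000, 2080, 2010))
  expect_lt(loud$pvalue, 0.05)
})

test_that("novel junction PSI uses competing junctions sharing a splice site", {
  design <- .design1
  mk_jt <- function(novel_counts, comp_counts) {
    j <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(101, 101), c(200, 250)))
    counts <- rbind(comp_counts, novel_counts)
    dimnames(counts) <- list(c("chr1:101-200", "chr1:101-250"),
                             design$sample)
    structure(list(junctions = j, counts = counts,
                   annotated = c(TRUE, FALSE)), class = "junction_table")
  }
  jt <- mk_jt(c(20, 20), c(20, 20))
  res <- psi_for_novel_junctions(jt, design)
  expect_equal(res$psi_Rp, 50)
  expect_equal(res$psi_FRp, 50)
  expect_false(res$low_confidence)
  # condition swap 30/10 vs 10/30: delta 50 points
  jt2 <- mk_jt(c(30, 10), c(10, 30))
  res2 <- psi_for_novel_junctions(jt2, design)
  expect_equal(res2$psi_Rp, 75)
  expect_equal(res2$psi_FRp, 25)
  expect_equal(res2$delta, -50)
  # no competitor: PSI 100, low confidence
  j3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 400))
  jt3 <- structure(list(junctions = j3,
                        counts = matrix(c(9, 9), 1, 2,
                          dimnames = list("chr1:301-400", design$sample)),
                        annotated = FALSE), class = "junction_table")
  res3 <- psi_for_novel_junctions(jt3, design)
  expect_equal(res3$psi_Rp, 100)
  expect_true(res3$low_confidence)
})

test_that("DE/DS overlap is an exact set decomposition", {
  expect_identical(overlap_de_ds(c("a", "b"), c("b", "c")),
                   list(de_only = 1L, both = 1L, ds_only = 1L))
  expect_identical(overlap_de_ds(c("a"), c("b"))$both, 0L)
  expect_identical(overlap_de_ds(character(0), character(0)),
                   list(de_only = 0L, both = 0L, ds_only = 0L))
})

test_that("simulated DS genes surface through ds_analysis, nulls stay quiet", {
  cfg <- sim_config(n_genes = 120, library_size = 120000, frac_de_genes = 0,
                    frac_ds_genes = 0.15, delta_inclusion = 40, seed = 99)
  d <- sim_dataset(cfg)
  aln <- lapply(d$alignments, alignments_from_records)
  bins <- build_bins(d$gms)
  gcm <- count_genes(aln, d$gms)
  bcm <- count_features(aln, bins)
  jt <- extract_junctions(aln, gene_introns(d$gms))
  il <- bins[bins$kind == "intron" | bins$as_class == "IR"]
  bc <- count_boundaries(aln, il, jt)
  res <- ds_analysis(bcm, gcm, bins, jt, bc, d$design, d$gms)
  true_ds <- d$truth$gene_id[d$truth$ds]
  expect_gt(mean(true_ds %in% res$ds_genes), 0.8)
  null_genes <- setdiff(d$truth$gene_id, true_ds)
  expect_lt(mean(null_genes %in% res$ds_genes), 0.05)
})
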