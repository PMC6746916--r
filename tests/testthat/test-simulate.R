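test_that("simulator output is byte-identical under the same seed", {
  cfg <- sim_config(n_genes = 15, seed = 9)
  d1 <- sim_dataset(cfg)
  d2 <- sim_dataset(cfg)
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(d1$gms, f1); write_gtf(d2$gms, f2)
  expect_identical(readLines(f1), readLines(f2))
  s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
  write_sam(d1$alignments[[1]], s1, sim_seq_lengths(d1$gms))
  write_sam(d2$alignments[[1]], s2, sim_seq_lengths(d2$gms))
  expect_identical(readLines(s1), readLines(s2))
  expect_identical(d1$truth, d2$truth)
})

test_that("an IR gene has two transcripts identical except the retained intron", {
  cfg <- sim_config(n_genes = 1, frac_ds_genes = 1, event_classes = "IR",
                    seed = 3)
  ann <- make_toy_annotation(cfg)
  ex <- ann$gms$exons
  txs <- split(ex, ex$transcript_id)
  expect_length(txs, 2L)
  red <- lapply(txs, GenomicRanges::reduce)
  # same overall span, retained intron only in the inclusion isoform
  expect_identical(range(red[[1]]), range(red[[2]]))
  tr <- ann$truth
  expect_identical(tr$event_class, "IR")
  iv <- IRanges::IRanges(tr$event_start, tr$event_end)
  in1 <- sum(IRanges::width(IRanges::intersect(IRanges::ranges(red[[1]]), iv)))
  in2 <- sum(IRanges::width(IRanges::intersect(IRanges::ranges(red[[2]]), iv)))
  expect_setequal(c(in1, in2), c(IRanges::width(iv), 0L))
})

test_that("configured DS fraction yields exactly that many flagged genes", {
  cfg <- sim_config(n_genes = 50, frac_ds_genes = 0.2, seed = 5)
  ann <- make_toy_annotation(cfg)
  expect_identical(sum(ann$truth$ds), 10L)
  expect_identical(sum(!is.na(ann$truth$event_class)), 10L)
  # a zero inclusion shift means no gene is truly DS, events or not
  cfg0 <- sim_config(n_genes = 50, frac_ds_genes = 0.2, delta_inclusion = 0,
                     seed = 5)
  ann0 <- make_toy_annotation(cfg0)
  expect_identical(sum(ann0$truth$ds), 0L)
  expect_identical(sum(!is.na(ann0$truth$event_class)), 10L)
})

test_that("an empty annotation request errors", {
  expect_error(make_toy_annotation(sim_config(n_genes = 0, seed = 1)),
               "empty")
})

test_that("every read's blocks lie within exons of its source gene", {
  cfg <- sim_config(n_genes = 10, library_size = 2000, seed = 21)
  d <- sim_dataset(cfg)
  ex <- d$gms$exons
  ex_by_tx <- split(IRanges::IRanges(GenomicRanges::start(ex),
                                     GenomicRanges::end(ex)),
                    ex$transcript_id)
  rec <- d$alignments[[1]]
  ok <- vapply(seq_len(nrow(rec)), function(i) {
    w <- ora_walk_cigar(rec$pos[i], rec$cigar[i])
    # all blocks inside the exons of at least one transcript
    any(vapply(ex_by_tx, function(tx)
      all(apply(w$blocks, 1L, function(b)
        any(IRanges::start(tx) <= b[1] & IRanges::end(tx) >= b[2]))),
      logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("fully retained introns leave no spliced junction support", {
  cfg <- sim_config(n_genes = 1, frac_ds_genes = 1, event_classes = "IR",
                    delta_inclusion = 100, library_size = 3000, seed = 8)
  d <- sim_dataset(cfg)
  tr <- d$truth
  key <- paste0(tr$event_start, "-", tr$event_end)
  # in the condition with 100% inclusion no read supports the excising
  # junction; in the 0% condition no read lies inside the intron
  full_cond <- if (tr$incl_cond1 == 100) "Rp" else "FRp"
  for (s in seq_len(nrow(d$design))) {
    j <- ora_junctions(d$alignments[[s]])
    if (d$design$condition[s] == full_cond) {
      expect_false(key %in% names(j))
    } else {
      expect_identical(ora_count_feature(d$alignments[[s]],
                                         tr$event_start + 1L,
                                         tr$event_end - 1L), 0L)
    }
  }
})

test_that("empirical inclusion converges to truth at deep coverage", {
  # ES gene at PSI 50 in both conditions, ~10,000 reads per gene
  cfg <- sim_config(n_genes = 2, frac_ds_genes = 1, event_classes = "ES",
                    delta_inclusion = 0, library_size = 20000,
                    nb_dispersion = 0, seed = 13)
  d <- sim_dataset(cfg)
  ann <- d$truth
  bins <- build_bins(d$gms)
  ev <- bins[bins$as_class == "ES"]
  aln <- lapply(d$alignments, alignments_from_records)
  jt <- extract_junctions(aln, gene_introns(d$gms))
  bc <- count_boundaries(aln, ev, jt)
  met <- bin_splice_metrics(ev, jt, bc, d$design)
  expect_true(all(abs(met$metric_Rp - 50) < 2))
  expect_true(all(abs(met$metric_FRp - 50) < 2))
})

test_that("zero-dispersion gene counts are Poisson-like across replicates", {
  cfg <- sim_config(n_genes = 60, n_replicates = 25, library_size = 6000,
                    nb_dispersion = 0, frac_de_genes = 0, frac_ds_genes = 0,
                    seed = 31)
  d <- sim_dataset(cfg)
  aln <- lapply(d$alignments, alignments_from_records)
  gcm <- count_genes(aln, d$gms)
  rp <- gcm$counts[, d$design$condition == "Rp"]
  m <- rowMeans(rp); v <- apply(rp, 1L, var)
  idx <- m > 20
  expect_gt(sum(idx), 10)
  # dispersion index ~ 1 under Poisson sampling
  expect_lt(abs(median(v[idx] / m[idx]) - 1), 0.3)
  # and clearly overdispersed when phi > 0
  cfg2 <- sim_config(n_genes = 60, n_replicates = 25, library_size = 60000,
                     nb_dispersion = 0.2, frac_de_genes = 0,
                     frac_ds_genes = 0, seed = 32)
  d2 <- sim_dataset(cfg2)
  g2 <- count_genes(lapply(d2$alignments, alignments_from_records), d2$gms)
  rp2 <- g2$counts[, d2$design$condition == "Rp"]
  m2 <- rowMeans(rp2); v2 <- apply(rp2, 1L, var)
  expect_gt(median(v2[m2 > 100] / m2[m2 > 100]), 2)
})

test_that("genes shorter than the read length are rejected with a diagnostic", {
  cfg <- sim_config(n_genes = 3, read_length = 100, seed = 2)
  ann <- make_toy_annotation(cfg)
  # shrink one gene's exons below the read length
  ex <- ann$gms$exons
  g1 <- ex$gene_id == "g0001"
  IRanges::width(ex[g1]) <- 30L
  gms2 <- gene_model_set(ex)
  expect_warning(aln <- simulate_alignments(gms2, ann$truth, cfg),
                 "rejecting")
})
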