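# three-bin fixture: exon [1-100], intron [101-200], exon [201-300]
.fixture_gms <- function() {
  ora_gms(list(list(gene_id = "gF", strand = "+",
    txs = list(data.frame(start = c(1, 201), end = c(100, 300))))))
}

test_that("reads count toward every bin an aligned block touches", {
  gms <- .fixture_gms()
  bins <- build_bins(gms)
  # one read inside the first exon
  aln <- alignments_from_records(ora_records(11, "50M"))
  cm <- count_features(aln, bins)
  expect_identical(as.integer(cm$counts), c(1L, 0L, 0L))
  gcm <- count_genes(aln, gms)
  expect_identical(as.integer(gcm$counts), 1L)
  # a gapped read spanning the junction: both exon bins, not the intron
  aln2 <- alignments_from_records(ora_records(81, "20M100N30M"))
  cm2 <- count_features(aln2, bins)
  expect_identical(as.integer(cm2$counts), c(1L, 0L, 1L))
  # a contiguous read across the exon-intron boundary: exon and intron
  aln3 <- alignments_from_records(ora_records(91, "40M"))
  cm3 <- count_features(aln3, bins)
  expect_identical(as.integer(cm3$counts), c(1L, 1L, 0L))
})

test_that("an empty alignment set gives an all-zero matrix with full index", {
  gms <- .fixture_gms()
  bins <- build_bins(gms)
  aln <- alignments_from_records(ora_records(integer(0), character(0)))
  cm <- count_features(aln, bins)
  expect_identical(dim(cm$counts), c(3L, 1L))
  expect_true(all(cm$counts == 0L))
  expect_identical(rownames(cm$counts), bins$bin_id)
})

test_that("read densities scale exactly with counts", {
  gms <- .fixture_gms()
  bins <- build_bins(gms)
  aln1 <- alignments_from_records(ora_records(c(11, 21), c("50M", "50M")))
  aln2 <- alignments_from_records(
    ora_records(c(11, 21, 11, 21), rep(c("50M", "50M"), 2)))
  cm1 <- count_features(aln1, bins)
  cm2 <- count_features(aln2, bins)
  expect_equal(cm2$rd, 2 * cm1$rd)
})

test_that("junctions below five reads in every sample are discarded", {
  gms <- .fixture_gms()
  introns <- gene_introns(gms)
  gap4 <- ora_records(rep(81, 4), rep("20M100N30M", 4))
  gap5 <- ora_records(rep(81, 5), rep("20M100N30M", 5))
  jt4 <- extract_junctions(list(s1 = alignments_from_records(gap4),
                                s2 = alignments_from_records(gap4)), introns)
  expect_length(jt4$junctions, 0L)
  jt5 <- extract_junctions(list(s1 = alignments_from_records(gap5),
                                s2 = alignments_from_records(gap4)), introns)
  expect_length(jt5$junctions, 1L)
  expect_identical(as.integer(jt5$counts), c(5L, 4L))
  expect_true(jt5$annotated)
})

test_that("junctions not matching an annotated intron are flagged novel", {
  gms <- .fixture_gms()
  rec <- ora_records(rep(61, 5), rep("20M110N30M", 5))  # gap [81, 190]
  jt <- extract_junctions(alignments_from_records(rec), gene_introns(gms))
  expect_length(jt$junctions, 1L)
  expect_false(jt$annotated)
})

test_that("boundary counts separate retention from exclusion support", {
  gms <- .fixture_gms()
  bins <- build_bins(gms)
  intron <- bins[bins$kind == "intron"]
  # 10 reads across each boundary, 5 spliced over the intron
  rec <- ora_records(
    c(rep(91, 10), rep(181, 10), rep(81, 5)),
    c(rep("20M", 10), rep("40M", 10), rep("20M100N30M", 5)))
  aln <- alignments_from_records(rec)
  jt <- extract_junctions(aln, gene_introns(gms))
  bc <- count_boundaries(aln, intron, jt)
  expect_identical(as.integer(bc$E1I), 10L)
  expect_identical(as.integer(bc$IE2), 10L)
  expect_identical(as.integer(bc$J), 5L)
  # agrees with the brute-force walker
  ora <- ora_boundary(rec, 101L, 200L)
  expect_identical(unname(c(bc$E1I[1, 1], bc$IE2[1, 1], bc$J[1, 1])),
                   unname(as.integer(ora)))
  # a spliced read never counts toward E1I/IE2
  spliced <- alignments_from_records(ora_records(81, "20M100N30M"))
  jt2 <- extract_junctions(spliced, gene_introns(gms), min_reads = 1)
  bc2 <- count_boundaries(spliced, intron, jt2)
  expect_identical(as.integer(bc2$E1I), 0L)
  expect_identical(as.integer(bc2$IE2), 0L)
  expect_identical(as.integer(bc2$J), 1L)
})

test_that("boundary windows respect the anchor width", {
  gms <- .fixture_gms()
  intron <- build_bins(gms)[2]
  # block [96, 105]: covers the 5' boundary with 5 nt on each side
  rec <- ora_records(96, "10M")
  aln <- alignments_from_records(rec)
  jt <- extract_junctions(aln, NULL, min_reads = 99)
  expect_identical(as.integer(count_boundaries(aln, intron, jt,
                                               min_anchor = 5)$E1I), 1L)
  expect_identical(as.integer(count_boundaries(aln, intron, jt,
                                               min_anchor = 6)$E1I), 0L)
})

test_that("gene counts conserve simulated reads", {
  cfg <- sim_config(n_genes = 25, library_size = 5000, seed = 41)
  d <- sim_dataset(cfg)
  aln <- lapply(d$alignments, alignments_from_records)
  gcm <- count_genes(aln, d$gms)
  # non-overlapping genes, every sampled base exonic in some transcript:
  # each read hits exactly one gene
  for (s in seq_along(aln))
    expect_identical(sum(gcm$counts[, s]), nrow(d$alignments[[s]]))
})

test_that("package junction extraction matches the brute-force CIGAR walker", {
  cfg <- sim_config(n_genes = 20, library_size = 4000, seed = 43)
  d <- sim_dataset(cfg)
  for (s in c(1L, 4L)) {
    rec <- d$alignments[[s]]
    jt <- extract_junctions(alignments_from_records(rec), min_reads = 1)
    got <- stats::setNames(as.integer(jt$counts),
                           paste0(GenomicRanges::start(jt$junctions), "-",
                                  GenomicRanges::end(jt$junctions)))
    ora <- ora_junctions(rec)
    expect_setequal(names(got), names(ora))
    expect_identical(got[names(ora)], ora[names(ora)])
  }
})

test_that("SAM files round-trip through the reader", {
  cfg <- sim_config(n_genes = 8, library_size = 1500, seed = 47)
  d <- sim_dataset(cfg)
  path <- tempfile(fileext = ".sam")
  write_sam(d$alignments[[1]], path, sim_seq_lengths(d$gms))
  from_file <- read_alignments(path)
  in_mem <- alignments_from_records(d$alignments[[1]])
  expect_identical(length(from_file), length(in_mem))
  bins <- build_bins(d$gms)
  expect_identical(count_features(from_file, bins)$counts,
                   count_features(in_mem, bins)$counts)
})
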