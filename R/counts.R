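#' Count reads over a set of features
#'
#' A read counts toward a feature when any of its aligned blocks overlaps the
#' feature by at least one nucleotide; a gapped read spanning several bins
#' counts toward each bin it touches, never toward the bins inside its N
#' gaps. Counting is integer (one per overlapped feature) and strand-unaware.
#'
#' @param alignments Named list of `GAlignments` (one per sample), or a
#'   single `GAlignments`.
#' @param features `GRanges` of features; metadata column `bin_id` or names
#'   are used as feature ids when present.
#' @param width Effective widths (nt) used for read density; defaults to the
#'   feature widths.
#' @return list of class `count_matrix`: integer `counts` and numeric `rd`
#'   (reads per nt) matrices, features x samples, plus `width`.
#' @export
count_features <- function(alignments, features, width = NULL) {
  if (is(alignments, "GAlignments")) alignments <- list(sample = alignments)
  ids <- if (!is.null(features$bin_id)) features$bin_id
         else if (!is.null(names(features))) names(features)
         else as.character(seq_along(features))
  if (is.null(width)) width <- GenomicRanges::width(features)
  counts <- vapply(alignments, function(aln) {
    blocks <- GenomicAlignments::grglist(aln)
    hits <- GenomicRanges::findOverlaps(blocks, features, ignore.strand = TRUE)
    tabulate(S4Vectors::subjectHits(hits), nbins = length(features))
  }, integer(length(features)))
  counts <- matrix(counts, nrow = length(features),
                   dimnames = list(ids, names(alignments)))
  structure(list(counts = counts, rd = counts / width,
                 width = stats::setNames(as.numeric(width), ids)),
            class = "count_matrix")
}

#' Gene-level counts over exonic bases
#'
#' A read counts toward a gene when any aligned block overlaps any exonic
#' base of the gene; read density divides by the gene's effective width
#' (union of its exons).
#'
#' @param alignments Named list of `GAlignments`.
#' @param gms A [gene_model_set].
#' @return A `count_matrix` (genes x samples).
#' @export
count_genes <- function(alignments, gms) {
  red <- GenomicRanges::reduce(
    S4Vectors::split(gms$exons, S4Vectors::mcols(gms$exons)$gene_id))
  red <- red[gms$genes$gene_id]
  if (is(alignments, "GAlignments")) alignments <- list(sample = alignments)
  counts <- vapply(alignments, function(aln) {
    blocks <- GenomicAlignments::grglist(aln)
    hits <- GenomicRanges::findOverlaps(blocks, red, ignore.strand = TRUE)
    tabulate(S4Vectors::subjectHits(hits), nbins = length(red))
  }, integer(length(red)))
  counts <- matrix(counts, nrow = length(red),
                   dimnames = list(gms$genes$gene_id, names(alignments)))
  w <- stats::setNames(gms$genes$effective_width, gms$genes$gene_id)
  structure(list(counts = counts, rd = counts / w, width = w),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Extract splice junctions from gapped alignments
#'
#' Every N gap of an aligned read yields one junction (the gapped interval,
#' i.e. the excised intron). Junctions whose maximum count over all samples
#' is below `min_reads` are discarded; survivors are flagged `annotated` when
#' they exactly match an annotated intron.
#'
#' @param alignments Named list of `GAlignments`.
#' @param introns `GRanges` of annotated introns (see [gene_introns()]), used
#'   for the `annotated` flag; may be `NULL`.
#' @param min_reads Minimum max-over-samples read support (junctions with
#'   fewer than this many reads are discarded; default 5).
#' @return list of class `junction_table`: `junctions` (`GRanges`), integer
#'   `counts` (junctions x samples), logical `annotated`.
#' @export
extract_junctions <- function(alignments, introns = NULL, min_reads = 5) {
  if (is(alignments, "GAlignments")) alignments <- list(sample = alignments)
  per_sample <- lapply(alignments, function(aln)
    unlist(GenomicAlignments::junctions(aln), use.names = FALSE))
  all_j <- unique(unlist(GenomicRanges::GRangesList(lapply(per_sample, function(g) {
    GenomicRanges::strand(g) <- "*"
    unique(g)
  }))))
  all_j <- sort(all_j)
  if (length(all_j) == 0L)
    return(structure(list(junctions = all_j,
                          counts = matrix(integer(0), 0, length(alignments),
                                          dimnames = list(NULL, names(alignments))),
                          annotated = logical(0)),
                     class = "junction_table"))
  counts <- vapply(per_sample, function(g) {
    GenomicRanges::strand(g) <- "*"
    S4Vectors::countMatches(all_j, g)
  }, integer(length(all_j)))
  counts <- matrix(counts, nrow = length(all_j),
                   dimnames = list(.junction_key(all_j), names(alignments)))
  keep <- apply(counts, 1L, max) >= min_reads
  all_j <- all_j[keep]
  counts <- counts[keep, , drop = FALSE]
  annotated <- if (is.null(introns) || length(introns) == 0L)
    rep(FALSE, length(all_j))
  else {
    intr <- introns
    GenomicRanges::strand(intr) <- "*"
    S4Vectors::countMatches(all_j, unique(intr)) > 0L
  }
  structure(list(junctions = all_j, counts = counts, annotated = annotated),
            class = "junction_table")
}

.junction_key <- function(gr) {
  paste0(GenomicRanges::seqnames(gr), ":", GenomicRanges::start(gr), "-",
         GenomicRanges::end(gr))
}

#' @export
print.junction_table <- function(x, ...) {
  cat("junction_table:", length(x$junctions), "junctions (",
      sum(x$annotated), "annotated ) x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Intron boundary and exclusion-junction counts
#'
#' For each intron bin, counts per sample the reads supporting retention at
#' each boundary and the reads supporting exclusion: `E1I` is the number of
#' reads with a contiguous aligned block covering the exon1-intron boundary
#' with at least `min_anchor` nt on each side, `IE2` the same at the
#' intron-exon2 boundary, and `J` the count of the junction exactly excising
#' the intron. Spliced reads over the intron never count toward E1I/IE2.
#'
#' @param alignments Named list of `GAlignments`.
#' @param intron_bins `GRanges` of intron (or IR) bins, with `bin_id`.
#' @param junctions A `junction_table` from [extract_junctions()] (already
#'   filtered; junctions below the read filter contribute J = 0).
#' @param min_anchor Minimum nt a block must extend on each side of the
#'   boundary (default 1).
#' @return list of class `boundary_counts` with integer matrices `E1I`,
#'   `IE2`, `J` (intron bins x samples).
#' @export
count_boundaries <- function(alignments, intron_bins, junctions,
                             min_anchor = 1L) {
  if (is(alignments, "GAlignments")) alignments <- list(sample = alignments)
  ids <- intron_bins$bin_id
  a <- as.integer(min_anchor)
  w5 <- GenomicRanges::GRanges(GenomicRanges::seqnames(intron_bins),
    IRanges::IRanges(GenomicRanges::start(intron_bins) - a,
                     GenomicRanges::start(intron_bins) + a - 1L))
  w3 <- GenomicRanges::GRanges(GenomicRanges::seqnames(intron_bins),
    IRanges::IRanges(GenomicRanges::end(intron_bins) - a + 1L,
                     GenomicRanges::end(intron_bins) + a))
  count_window <- function(aln, win) {
    blocks <- unlist(GenomicAlignments::grglist(aln), use.names = FALSE)
    hits <- GenomicRanges::findOverlaps(win, blocks, type = "within",
                                        ignore.strand = TRUE)
    tabulate(S4Vectors::queryHits(hits), nbins = length(win))
  }
  E1I <- vapply(alignments, count_window, integer(length(w5)), win = w5)
  IE2 <- vapply(alignments, count_window, integer(length(w3)), win = w3)
  E1I <- matrix(E1I, nrow = length(w5), dimnames = list(ids, names(alignments)))
  IE2 <- matrix(IE2, nrow = length(w3), dimnames = list(ids, names(alignments)))
  J <- matrix(0L, length(ids), length(alignments),
              dimnames = list(ids, names(alignments)))
  if (length(junctions$junctions) > 0L) {
    key_bin <- .junction_key(GenomicRanges::granges(intron_bins))
    m <- match(key_bin, .junction_key(junctions$junctions))
    hit <- !is.na(m)
    J[hit, ] <- junctions$counts[m[hit], , drop = FALSE]
  }
  structure(list(E1I = E1I, IE2 = IE2, J = J), class = "boundary_counts")
}
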