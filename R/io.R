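#' Write a gene model set as GTF
#'
#' Emits gene, transcript and exon features, 1-based inclusive coordinates.
#' Output bytes are a deterministic function of the input.
#'
#' @param gms A [gene_model_set].
#' @param path Output path.
#' @export
write_gtf <- function(gms, path) {
  ex <- gms$exons
  mc <- S4Vectors::mcols(ex)
  lines <- character(0)
  for (g in gms$genes$gene_id) {
    grow <- gms$genes[gms$genes$gene_id == g, ]
    lines <- c(lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      grow$seqnames, grow$start, grow$end, grow$strand, g))
    idx <- which(mc$gene_id == g)
    for (tx in sort(unique(mc$transcript_id[idx]))) {
      tix <- idx[mc$transcript_id[idx] == tx]
      tix <- tix[order(GenomicRanges::start(ex)[tix])]
      lines <- c(lines, sprintf(
        "%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        grow$seqnames, min(GenomicRanges::start(ex)[tix]),
        max(GenomicRanges::end(ex)[tix]), grow$strand, g, tx))
      lines <- c(lines, sprintf(
        "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        grow$seqnames, GenomicRanges::start(ex)[tix],
        GenomicRanges::end(ex)[tix], grow$strand, g, tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write simulated alignment records as SAM
#'
#' Coordinate-sorted, header-complete single-end SAM. Sequences and qualities
#' are omitted (`*`), as only positions and CIGARs carry information here.
#'
#' @param records data.frame from [simulate_alignments()] (one sample).
#' @param path Output path.
#' @param seq_lengths Named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @export
write_sam <- function(records, path, seq_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  records$qname, records$flag, records$rname,
                  records$pos, records$mapq, records$cigar)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reference lengths implied by a gene model set
#' @param gms A [gene_model_set].
#' @param pad Extra bases beyond the last exon.
#' @return Named integer vector, one element per reference sequence.
#' @export
sim_seq_lengths <- function(gms, pad = 1000L) {
  tapply(gms$genes$end, gms$genes$seqnames, max) + pad
}

#' Read spliced alignments from a SAM/BAM file
#'
#' SAM files are converted to BAM on the fly; the result is a
#' `GAlignments` whose CIGARs drive all downstream counting.
#'
#' @param path Path to a SAM or BAM file.
#' @return A [GenomicAlignments::GAlignments].
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    path <- bam
  }
  GenomicAlignments::readGAlignments(path)
}

#' In-memory alignment records to GAlignments
#'
#' @param records data.frame with `rname`, `pos`, `cigar` columns.
#' @return A [GenomicAlignments::GAlignments].
#' @export
alignments_from_records <- function(records) {
  GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(records$rname)),
    pos = as.integer(records$pos),
    cigar = as.character(records$cigar),
    strand = S4Vectors::Rle(GenomicRanges::strand(rep("*", nrow(records)))))
}

#' Tab-separated output with '.' for missing values
#'
#' The interchange dialect of the pipeline: header row, tabs, no quoting,
#' missing values written as `.`.
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
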