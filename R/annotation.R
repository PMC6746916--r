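#' Gene model sets
#'
#' A `gene_model_set` bundles the exon structure of an annotation: a
#' [GenomicRanges::GRanges] of exons carrying `gene_id` and `transcript_id`
#' metadata, plus a per-gene summary table. The effective width of a gene is
#' the number of bases in the union of all its exons, the denominator used
#' for read densities.
#'
#' @param exons A `GRanges` of exons with metadata columns `gene_id` and
#'   `transcript_id`.
#' @return An object of class `gene_model_set` with elements `exons` (the
#'   input, sorted) and `genes` (data.frame with `gene_id`, `seqnames`,
#'   `strand`, `start`, `end`, `effective_width`, `n_transcripts`,
#'   `multiexonic`).
#' @export
gene_model_set <- function(exons) {
  stopifnot(is(exons, "GRanges"))
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$gene_id) || is.null(mc$transcript_id))
    stop("exons must carry 'gene_id' and 'transcript_id' metadata columns")
  if (anyNA(mc$transcript_id))
    stop("exon without parent transcript in annotation")
  exons <- exons[order(mc$gene_id, GenomicRanges::start(exons),
                       GenomicRanges::end(exons))]
  by_gene <- S4Vectors::split(exons, S4Vectors::mcols(exons)$gene_id)
  red <- GenomicRanges::reduce(by_gene)
  eff <- sum(GenomicRanges::width(red))
  n_tx <- vapply(S4Vectors::split(S4Vectors::mcols(exons)$transcript_id,
                                  S4Vectors::mcols(exons)$gene_id),
                 function(x) length(unique(x)), integer(1))
  # a gene is multiexonic when at least one transcript has >= 2 exons
  tx_nexon <- table(S4Vectors::mcols(exons)$transcript_id)
  tx2gene <- tapply(S4Vectors::mcols(exons)$gene_id,
                    S4Vectors::mcols(exons)$transcript_id,
                    function(x) x[1])
  multi <- tapply(as.integer(tx_nexon[names(tx2gene)]) >= 2, unlist(tx2gene), any)
  gid <- names(by_gene)
  rng <- unlist(range(by_gene, ignore.strand = TRUE))
  first <- !duplicated(S4Vectors::mcols(exons)$gene_id)
  genes <- data.frame(
    gene_id = gid,
    seqnames = as.character(GenomicRanges::seqnames(rng))[match(gid, names(rng))],
    strand = as.character(GenomicRanges::strand(exons))[first][
      match(gid, S4Vectors::mcols(exons)$gene_id[first])],
    start = GenomicRanges::start(rng)[match(gid, names(rng))],
    end = GenomicRanges::end(rng)[match(gid, names(rng))],
    effective_width = as.numeric(eff[gid]),
    n_transcripts = as.integer(n_tx[gid]),
    multiexonic = as.logical(multi[gid]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(exons = exons, genes = genes), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$genes), "genes,",
      length(unique(S4Vectors::mcols(x$exons)$transcript_id)), "transcripts,",
      sum(x$genes$multiexonic), "multiexonic\n")
  invisible(x)
}

#' Load a GTF annotation into a gene model set
#'
#' Reads a GTF with gene/transcript/exon hierarchy. Only `exon` features are
#' used; `gene_id` and `transcript_id` attributes are required. Monoexonic
#' genes are kept in the set (and flagged) but produce no bins downstream:
#' only multiexonic genes are partitioned.
#'
#' @param path Path to a GTF file.
#' @return A [gene_model_set].
#' @export
load_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("exon without parent transcript_id while parsing ", path)
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(gene_id = ex$gene_id,
                                               transcript_id = ex$transcript_id)
  gene_model_set(ex)
}

#' Exons grouped per transcript of one gene
#' @keywords internal
.tx_exons <- function(gms, gene_id) {
  ex <- gms$exons[S4Vectors::mcols(gms$exons)$gene_id == gene_id]
  lapply(split(ex, S4Vectors::mcols(ex)$transcript_id), function(g)
    IRanges::IRanges(sort(GenomicRanges::start(g)), sort(GenomicRanges::end(g))))
}

#' Annotated introns of a gene model set
#'
#' One range per distinct intron (gap between consecutive exons of a
#' transcript), with the ids of one transcript/gene that uses it.
#'
#' @param gms A [gene_model_set].
#' @return A `GRanges` of introns with `gene_id` metadata.
#' @export
gene_introns <- function(gms) {
  ex <- gms$exons
  keys <- paste(S4Vectors::mcols(ex)$gene_id, S4Vectors::mcols(ex)$transcript_id)
  parts <- split(seq_along(ex), keys)
  out <- lapply(parts, function(idx) {
    e <- ex[idx]
    if (length(e) < 2L) return(NULL)
    s <- sort(GenomicRanges::start(e)); en <- sort(GenomicRanges::end(e))
    data.frame(seqnames = as.character(GenomicRanges::seqnames(e))[1],
               start = en[-length(en)] + 1L, end = s[-1L] - 1L,
               strand = as.character(GenomicRanges::strand(e))[1],
               gene_id = S4Vectors::mcols(e)$gene_id[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(out$seqnames,
                               IRanges::IRanges(out$start, out$end),
                               strand = out$strand, gene_id = out$gene_id)
  unique(gr)
}

# Per-transcript status of a subinterval: "exon" if it lies inside an exon,
# "intron" if inside the transcript span but not exonic, "outside" otherwise.
.subinterval_status <- function(sub_start, sub_end, tx) {
  if (sub_start >= min(IRanges::start(tx)) && sub_end <= max(IRanges::end(tx))) {
    inside <- any(IRanges::start(tx) <= sub_start & IRanges::end(tx) >= sub_end)
    if (inside) "exon" else "intron"
  } else "outside"
}

#' Partition the multiexonic genes of a set into subgenic bins
#'
#' Bin boundaries are the union of all transcripts' exon start/end positions.
#' Each subinterval between consecutive boundaries becomes a bin: an exon bin
#' if it is exonic in every transcript spanning it, an intron bin if intronic
#' in every one, and an AS bin otherwise. Adjacent subintervals with the same
#' kind and identical per-transcript support are merged. AS bins are
#' classified as `ES`, `Alt5SS`, `Alt3SS` or `IR`; runs of adjacent AS bins
#' carrying three or more distinct event classes are relabelled `multiple`,
#' as are geometries that fit none of the four classes.
#'
#' @param gms A [gene_model_set].
#' @return A `GRanges` of bins with metadata `bin_id`, `gene_id`, `kind`
#'   (exon/intron/AS) and `as_class` (ES/Alt5SS/Alt3SS/IR/multiple/none).
#' @export
build_bins <- function(gms) {
  multi <- gms$genes$gene_id[gms$genes$multiexonic]
  # pre-split exon starts/ends once; per-gene GRanges subsetting is too slow
  mc <- S4Vectors::mcols(gms$exons)
  key <- paste0(mc$gene_id, "\r", mc$transcript_id)
  st <- split(GenomicRanges::start(gms$exons), key)
  en <- split(GenomicRanges::end(gms$exons), key)
  tx_gene <- sub("\r.*$", "", names(st))
  txs_by_gene <- split(mapply(function(s, e) {
    o <- order(s)
    IRanges::IRanges(s[o], e[o])
  }, st, en, SIMPLIFY = FALSE), tx_gene)
  res <- lapply(multi, function(g)
    .build_gene_bins(gms, g, txs = txs_by_gene[[g]]))
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(GenomicRanges::GRanges())
  out <- do.call(rbind, res)
  GenomicRanges::GRanges(out$seqnames, IRanges::IRanges(out$start, out$end),
                         strand = out$strand, bin_id = out$bin_id,
                         gene_id = out$gene_id, kind = out$kind,
                         as_class = out$as_class)
}

.build_gene_bins <- function(gms, gene_id, txs = NULL) {
  if (is.null(txs)) txs <- .tx_exons(gms, gene_id)
  grow <- gms$genes[match(gene_id, gms$genes$gene_id), ]
  bounds <- sort(unique(c(
    unlist(lapply(txs, IRanges::start)),
    unlist(lapply(txs, IRanges::end)) + 1L)))
  if (length(bounds) < 2L) return(NULL)
  sub_start <- bounds[-length(bounds)]
  sub_end <- bounds[-1L] - 1L
  status <- vapply(seq_along(sub_start), function(i)
    vapply(txs, function(tx) .subinterval_status(sub_start[i], sub_end[i], tx),
           character(1)),
    character(length(txs)))
  status <- matrix(status, nrow = length(txs))
  kind <- apply(status, 2L, function(st) {
    st <- st[st != "outside"]
    if (length(st) == 0L) "intron"
    else if (all(st == "exon")) "exon"
    else if (all(st == "intron")) "intron"
    else "AS"
  })
  # merge adjacent subintervals with identical kind and support signature
  sig <- paste(kind, apply(status, 2L, paste, collapse = "|"))
  grp <- cumsum(c(TRUE, sig[-1L] != sig[-length(sig)]))
  m_start <- tapply(sub_start, grp, min)
  m_end <- tapply(sub_end, grp, max)
  m_kind <- tapply(kind, grp, function(x) x[1])
  as_class <- rep("none", length(m_start))
  is_as <- m_kind == "AS"
  if (any(is_as)) {
    as_class[is_as] <- vapply(which(is_as), function(i)
      .classify_as_interval(m_start[[i]], m_end[[i]], txs, grow$strand),
      character(1))
    # >= 3 distinct event classes in one run of adjacent AS bins -> multiple
    run <- cumsum(c(TRUE, diff(which(is_as)) != 1L))
    for (r in unique(run)) {
      idx <- which(is_as)[run == r]
      if (length(unique(as_class[idx])) >= 3L) as_class[idx] <- "multiple"
    }
  }
  data.frame(seqnames = grow$seqnames, start = as.integer(m_start),
             end = as.integer(m_end), strand = grow$strand,
             bin_id = sprintf("%s:B%03d", gene_id, seq_along(m_start)),
             gene_id = gene_id, kind = as.character(m_kind),
             as_class = as_class, row.names = NULL, stringsAsFactors = FALSE)
}

# Classify one AS interval against the transcripts of its gene.
.classify_as_interval <- function(bs, be, txs, strand) {
  intr <- lapply(txs, function(tx) {
    if (length(tx) < 2L) return(IRanges::IRanges())
    IRanges::IRanges(IRanges::end(tx)[-length(tx)] + 1L, IRanges::start(tx)[-1L] - 1L)
  })
  # IR: equals a full intron of one transcript, interior of an exon of another
  full_intron <- any(vapply(intr, function(ir)
    any(IRanges::start(ir) == bs & IRanges::end(ir) == be), logical(1)))
  inside_exon <- any(vapply(txs, function(tx)
    any(IRanges::start(tx) < bs & IRanges::end(tx) > be), logical(1)))
  if (full_intron && inside_exon) return("IR")
  # ES: equals a full exon of one transcript, strictly inside an intron of another
  full_exon <- any(vapply(txs, function(tx)
    any(IRanges::start(tx) == bs & IRanges::end(tx) == be), logical(1)))
  inside_intron <- any(vapply(intr, function(ir)
    any(IRanges::start(ir) < bs & IRanges::end(ir) > be), logical(1)))
  if (full_exon && inside_intron) return("ES")
  # Alt5'/Alt3': bin abuts a shared exonic region on exactly one side; the
  # alternative boundary is a donor or acceptor depending on side and strand
  left_shared <- .position_exonic_in_all(bs - 1L, txs)
  right_shared <- .position_exonic_in_all(be + 1L, txs)
  if (xor(isTRUE(left_shared), isTRUE(right_shared))) {
    if (isTRUE(left_shared))
      return(if (strand == "+") "Alt5SS" else "Alt3SS")
    return(if (strand == "+") "Alt3SS" else "Alt5SS")
  }
  warning("unclassifiable AS geometry at [", bs, ",", be, "]; labelled 'multiple'",
          call. = FALSE)
  "multiple"
}

# TRUE when a position is exonic in every transcript whose span covers it,
# and covered by at least one transcript.
.position_exonic_in_all <- function(pos, txs) {
  spans <- vapply(txs, function(tx)
    pos >= min(IRanges::start(tx)) && pos <= max(IRanges::end(tx)), logical(1))
  if (!any(spans)) return(FALSE)
  all(vapply(txs[spans], function(tx)
    any(IRanges::start(tx) <= pos & IRanges::end(tx) >= pos), logical(1)))
}

#' Classify a single AS bin
#'
#' Convenience wrapper over the classifier used by [build_bins()].
#'
#' @param bin A one-range `GRanges` (or anything with start/end) for the bin.
#' @param gms A [gene_model_set].
#' @param gene_id Parent gene of the bin.
#' @return One of `"ES"`, `"Alt5SS"`, `"Alt3SS"`, `"IR"`, `"multiple"`.
#' @export
classify_as_bin <- function(bin, gms, gene_id) {
  txs <- .tx_exons(gms, gene_id)
  strand <- gms$genes$strand[gms$genes$gene_id == gene_id]
  .classify_as_interval(GenomicRanges::start(bin)[1], GenomicRanges::end(bin)[1],
                        txs, strand)
}

#' Export bins as a BED-like table
#'
#' @param bins `GRanges` from [build_bins()].
#' @param path Output TSV path (chrom, start, end, bin_id, kind, as_class, gene).
#' @export
write_bins <- function(bins, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
                   start = GenomicRanges::start(bins),
                   end = GenomicRanges::end(bins),
                   bin_id = bins$bin_id, kind = bins$kind,
                   as_class = bins$as_class, gene = bins$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
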