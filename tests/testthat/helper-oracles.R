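# Independent oracles, deliberately implemented with plain base R (string
# CIGAR walking, loops, direct arithmetic) so they share no code path with
# the package's GenomicRanges/GenomicAlignments machinery.

# Walk one CIGAR: returns reference-space aligned blocks and N gaps.
ora_walk_cigar <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  blocks <- NULL
  gaps <- NULL
  ref <- pos
  bstart <- pos
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      ref <- ref + len[i]
    } else if (op[i] == "N") {
      blocks <- rbind(blocks, c(bstart, ref - 1L))
      gaps <- rbind(gaps, c(ref, ref + len[i] - 1L))
      ref <- ref + len[i]
      bstart <- ref
    }
    # I/S/H/P consume no reference
  }
  blocks <- rbind(blocks, c(bstart, ref - 1L))
  list(blocks = blocks, gaps = gaps)
}

# Walk every record once: matrices of aligned blocks and N gaps with the
# owning read index. Bulk gregexpr keeps this usable on large fixtures.
ora_walk_all <- function(records) {
  n <- nrow(records)
  if (n == 0L) return(list(blocks = matrix(0L, 0, 3), gaps = matrix(0L, 0, 3)))
  ops_all <- regmatches(records$cigar,
                        gregexpr("[0-9]+[MIDNSHP=X]", records$cigar))
  blocks <- vector("list", n)
  gaps <- vector("list", n)
  for (i in seq_len(n)) {
    ops <- ops_all[[i]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    ref <- records$pos[i]
    bstart <- ref
    bl <- NULL; gp <- NULL
    for (j in seq_along(op)) {
      if (op[j] %in% c("M", "=", "X", "D")) {
        ref <- ref + len[j]
      } else if (op[j] == "N") {
        bl <- rbind(bl, c(i, bstart, ref - 1L))
        gp <- rbind(gp, c(i, ref, ref + len[j] - 1L))
        ref <- ref + len[j]
        bstart <- ref
      }
    }
    blocks[[i]] <- rbind(bl, c(i, bstart, ref - 1L))
    gaps[[i]] <- gp
  }
  list(blocks = do.call(rbind, blocks),
       gaps = do.call(rbind, gaps) %||% matrix(0L, 0, 3))
}

# Junction counts from raw records: table keyed "start-end" of every N gap.
ora_junctions <- function(records) {
  w <- ora_walk_all(records)
  if (nrow(w$gaps) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(paste0(w$gaps[, 2], "-", w$gaps[, 3]))
  stats::setNames(as.integer(tab), names(tab))
}

# Boundary support for an intron [s, e] from a pre-walked record set.
ora_boundary_bulk <- function(walk, s, e, a = 1L) {
  b <- walk$blocks; g <- walk$gaps
  E1I <- length(unique(b[b[, 2] <= s - a & b[, 3] >= s + a - 1L, 1]))
  IE2 <- length(unique(b[b[, 2] <= e - a + 1L & b[, 3] >= e + a, 1]))
  J <- length(unique(g[g[, 2] == s & g[, 3] == e, 1]))
  c(E1I = E1I, IE2 = IE2, J = J)
}

# Reads overlapping a feature interval by >= 1 nt with any aligned block.
ora_count_feature <- function(records, start, end) {
  n <- 0L
  for (i in seq_len(nrow(records))) {
    w <- ora_walk_cigar(records$pos[i], records$cigar[i])
    if (any(w$blocks[, 1] <= end & w$blocks[, 2] >= start)) n <- n + 1L
  }
  n
}

# Boundary support for an intron [s, e]: reads with one contiguous block
# covering [s - a, s + a - 1] (E1I) or [e - a + 1, e + a] (IE2), plus reads
# whose gap is exactly [s, e] (J).
ora_boundary <- function(records, s, e, a = 1L) {
  E1I <- 0L; IE2 <- 0L; J <- 0L
  for (i in seq_len(nrow(records))) {
    w <- ora_walk_cigar(records$pos[i], records$cigar[i])
    if (any(w$blocks[, 1] <= s - a & w$blocks[, 2] >= s + a - 1L)) E1I <- E1I + 1L
    if (any(w$blocks[, 1] <= e - a + 1L & w$blocks[, 2] >= e + a)) IE2 <- IE2 + 1L
    if (!is.null(w$gaps) &&
        any(w$gaps[, 1] == s & w$gaps[, 2] == e)) J <- J + 1L
  }
  c(E1I = E1I, IE2 = IE2, J = J)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-rolled SAM record table (one sample) for fixtures.
ora_records <- function(pos, cigar) {
  n <- length(pos)
  data.frame(qname = sprintf("r%03d", seq_len(n)), flag = rep(0L, n),
             rname = rep("chr1", n), pos = as.integer(pos),
             mapq = rep(255L, n), cigar = as.character(cigar),
             stringsAsFactors = FALSE)
}

# Build a gene_model_set from a list of genes; each gene is
# list(gene_id, strand, txs = list of data.frame(start, end)).
ora_gms <- function(genes) {
  rows <- do.call(rbind, lapply(genes, function(g)
    do.call(rbind, lapply(seq_along(g$txs), function(k)
      data.frame(seqnames = "chr1", start = g$txs[[k]]$start,
                 end = g$txs[[k]]$end, strand = g$strand,
                 gene_id = g$gene_id,
                 transcript_id = paste0(g$gene_id, ".", k))))))
  gene_model_set(GenomicRanges::GRanges(
    rows$seqnames, IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand, gene_id = rows$gene_id,
    transcript_id = rows$transcript_id))
}

# Hypergeometric upper-tail by direct lchoose enumeration (enrichment oracle).
ora_hyper_tail <- function(k, K, n, N) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  if (k > hi) return(0)
  x <- max(k, lo):hi
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# Conditional binomial two-sided exact test (Poisson-limit oracle).
ora_cond_binom_p <- function(s1, s2, prob = 0.5) {
  t <- s1 + s2
  if (t == 0) return(1)
  pr <- dbinom(0:t, t, prob)
  obs <- pr[s1 + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}
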