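#' Bin-level testability filter
#'
#' A bin enters the differential splicing test only if (a) its parent gene
#' is expressed above the gene thresholds (strictly more than `gene_reads`
#' reads and gene RD strictly above `gene_rd`) in every experimental
#' condition, and (b) the bin itself has strictly more than `bin_reads`
#' reads and an RD(bin)/RD(gene) ratio strictly above `bin_rd_ratio` in at
#' least one condition. Counts are totalled over replicates per condition.
#'
#' @param bin_cm `count_matrix` over bins (from [count_features()]).
#' @param gene_cm `count_matrix` over genes.
#' @param bins `GRanges` of bins (metadata `bin_id`, `gene_id`).
#' @param design data.frame with `sample`, `condition`.
#' @param gene_reads,gene_rd Gene-level thresholds (defaults 10, 0.05).
#' @param bin_reads,bin_rd_ratio Bin-level thresholds (defaults 5, 0.05).
#' @return Named logical vector over bins.
#' @export
filter_bins <- function(bin_cm, gene_cm, bins, design,
                        gene_reads = 10, gene_rd = 0.05,
                        bin_reads = 5, bin_rd_ratio = 0.05) {
  gene_of <- bins$gene_id[match(rownames(bin_cm$counts), bins$bin_id)]
  gi <- match(gene_of, rownames(gene_cm$counts))
  if (anyNA(gi)) stop("bin without parent gene counts: ",
                      rownames(bin_cm$counts)[which(is.na(gi))[1]])
  gene_ok <- filter_expressed(gene_cm, design, gene_reads, gene_rd,
                              all_conditions = TRUE)[gi]
  conds <- unique(as.character(design$condition))
  bin_ok_by_cond <- vapply(conds, function(cc) {
    sel <- design$condition == cc
    bin_tot <- rowSums(bin_cm$counts[, sel, drop = FALSE])
    gene_tot <- rowSums(gene_cm$counts[, sel, drop = FALSE])[gi]
    bin_rd <- bin_tot / bin_cm$width
    grd <- gene_tot / gene_cm$width[gi]
    ratio <- ifelse(grd > 0, bin_rd / grd, 0)
    bin_tot > bin_reads & ratio > bin_rd_ratio
  }, logical(nrow(bin_cm$counts)))
  out <- gene_ok & apply(bin_ok_by_cond, 1L, any)
  stats::setNames(out, rownames(bin_cm$counts))
}

#' Gene-normalized differential bin usage test
#'
#' Tests each bin's counts relative to its parent gene, so that changes in
#' overall gene expression do not register as splicing changes. Per
#' condition, replicate counts are summed and the bin's reads are compared
#' against the remaining reads of its gene in a 2x2 conditional
#' (hypergeometric) exact test — conditioning on both margins removes the
#' gene-expression variance, which is exactly what normalizing bin counts
#' to gene counts is meant to achieve. The default mid-p correction halves
#' the probability of the observed table, giving null p-values that are
#' uniform rather than conservative; `"exact"` gives the classical
#' conservative Fisher p. FDR is computed jointly across all tested bins.
#'
#' @param bin_cm `count_matrix` over the bins to test (pre-filtered).
#' @param gene_cm `count_matrix` over genes.
#' @param bins `GRanges` of bins.
#' @param design data.frame with `sample`, `condition`.
#' @param p_method `"midp"` (default) or `"exact"`.
#' @return data.frame with `bin_id`, `gene_id`, `logFC` (log2 usage change,
#'   second condition over first), `pvalue`, `fdr`.
#' @export
test_bins_normalized <- function(bin_cm, gene_cm, bins, design,
                                 p_method = c("midp", "exact")) {
  p_method <- match.arg(p_method)
  gene_of <- bins$gene_id[match(rownames(bin_cm$counts), bins$bin_id)]
  gi <- match(gene_of, rownames(gene_cm$counts))
  if (anyNA(gi)) stop("bin without parent gene counts")
  groups <- droplevels(as.factor(design$condition))
  stopifnot(nlevels(groups) == 2L)
  c1 <- groups == levels(groups)[1]
  s1 <- rowSums(bin_cm$counts[, c1, drop = FALSE])
  s2 <- rowSums(bin_cm$counts[, !c1, drop = FALSE])
  G1 <- rowSums(gene_cm$counts[gi, c1, drop = FALSE])
  G2 <- rowSums(gene_cm$counts[gi, !c1, drop = FALSE])
  # intron-bin reads need not overlap exonic bases, so they are not always
  # nested in the gene count; clamp the complement at zero
  o1 <- pmax(G1 - s1, 0)
  o2 <- pmax(G2 - s2, 0)
  pval <- vapply(seq_along(s1), function(i)
    .cond_hyper_p(s1[i], o1[i], s2[i], o2[i], midp = p_method == "midp"),
    numeric(1))
  usage1 <- (s1 + 0.5) / (G1 + 1)
  usage2 <- (s2 + 0.5) / (G2 + 1)
  data.frame(bin_id = rownames(bin_cm$counts), gene_id = gene_of,
             logFC = log2(usage2 / usage1), pvalue = pval,
             fdr = bh_fdr(pval), row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided conditional test of a 2x2 table (bin vs rest-of-gene reads,
# condition 1 vs 2): sums hypergeometric probabilities not exceeding the
# observed one; mid-p counts the observed probability with weight 1/2.
.cond_hyper_p <- function(s1, o1, s2, o2, midp = TRUE) {
  m <- s1 + s2
  n <- o1 + o2
  k <- s1 + o1
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  obs <- stats::dhyper(s1, m, n, k)
  if (midp)
    min(1, sum(pr[pr < obs * (1 - 1e-10)]) +
          0.5 * sum(pr[abs(pr - obs) <= obs * 1e-10]))
  else
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Percent spliced-in
#'
#' `PSI = 100 * inclusion / (inclusion + exclusion)`, the percentage of
#' junction reads supporting bin inclusion relative to all reads supporting
#' inclusion or exclusion. Undefined (NA) when both are zero; such bins are
#' dropped from PSI-based calling.
#'
#' @param inclusion_reads,exclusion_reads Non-negative counts (vectorized).
#' @return PSI in percent.
#' @export
compute_psi <- function(inclusion_reads, exclusion_reads) {
  stopifnot(all(inclusion_reads >= 0, na.rm = TRUE),
            all(exclusion_reads >= 0, na.rm = TRUE))
  tot <- inclusion_reads + exclusion_reads
  ifelse(tot > 0, 100 * inclusion_reads / tot, NA_real_)
}

#' Percent intron retention
#'
#' `PIR = 100 * (E1I + IE2) / (E1I + IE2 + 2 * J)`: reads supporting
#' retention at either intron boundary relative to retention plus twice the
#' exclusion-junction reads. Undefined (NA) when all three are zero.
#'
#' @param E1I Reads spanning the exon1-intron boundary.
#' @param IE2 Reads spanning the intron-exon2 boundary.
#' @param J Reads of the junction excising the intron.
#' @return PIR in percent.
#' @export
compute_pir <- function(E1I, IE2, J) {
  stopifnot(all(E1I >= 0, na.rm = TRUE), all(IE2 >= 0, na.rm = TRUE),
            all(J >= 0, na.rm = TRUE))
  num <- E1I + IE2
  den <- num + 2 * J
  ifelse(den > 0, 100 * num / den, NA_real_)
}

# Junction support for one bin: inclusion = junctions abutting the bin
# (donor or acceptor flush with a bin edge), exclusion = junctions whose gap
# covers the whole bin. A cassette exon has inclusion junctions on both
# sides; their counts are averaged over the sides present in the table so
# that junction PSI converges to the true inclusion fraction (summing
# would double-weight inclusion). Alt5'/Alt3' bins have one abutting
# (bin-proximal) junction against the bin-distal spanning junction.
.bin_junction_support <- function(bins, jt) {
  if (length(jt$junctions) == 0L)
    return(list(inc = integer(0), exc = integer(0)))
  js <- GenomicRanges::start(jt$junctions)
  je <- GenomicRanges::end(jt$junctions)
  jc <- as.character(GenomicRanges::seqnames(jt$junctions))
  bs <- GenomicRanges::start(bins)
  be <- GenomicRanges::end(bins)
  bc <- as.character(GenomicRanges::seqnames(bins))
  n_s <- ncol(jt$counts)
  inc <- matrix(0, length(bins), n_s, dimnames = list(bins$bin_id,
                                                      colnames(jt$counts)))
  exc <- inc
  for (i in seq_along(bins)) {
    same <- jc == bc[i]
    adj_l <- same & je == bs[i] - 1L
    adj_r <- same & js == be[i] + 1L
    spn <- same & js <= bs[i] & je >= be[i]
    n_sides <- any(adj_l) + any(adj_r)
    if (n_sides > 0)
      inc[i, ] <- (colSums(jt$counts[adj_l, , drop = FALSE]) +
                     colSums(jt$counts[adj_r, , drop = FALSE])) / n_sides
    if (any(spn)) exc[i, ] <- colSums(jt$counts[spn, , drop = FALSE])
  }
  list(inc = inc, exc = exc)
}

#' Junction-based PSI/PIR metrics per condition for a set of bins
#'
#' Intron and IR bins get PIR from intron-boundary and exclusion-junction
#' reads; all other bins get PSI from junctions abutting versus spanning the
#' bin. Replicate counts are summed per condition before the ratio is
#' taken, so each condition yields one metric value.
#'
#' @param bins `GRanges` of bins to quantify.
#' @param jt `junction_table` from [extract_junctions()].
#' @param bc `boundary_counts` from [count_boundaries()] covering at least
#'   the intron/IR bins of `bins`.
#' @param design data.frame with `sample`, `condition`.
#' @return data.frame with `bin_id`, `metric` ("PSI"/"PIR"), one column of
#'   metric values per condition, and `delta` (second condition minus
#'   first, percentage points).
#' @export
bin_splice_metrics <- function(bins, jt, bc, design) {
  conds <- unique(as.character(design$condition))
  use_pir <- bins$kind == "intron" | bins$as_class == "IR"
  sup <- .bin_junction_support(bins, jt)
  per_cond <- function(m, cc) {
    if (length(m) == 0L || nrow(m) == 0L) return(rep(0L, length(bins)))
    rowSums(m[, design$condition == cc, drop = FALSE])
  }
  vals <- vapply(conds, function(cc) {
    out <- rep(NA_real_, length(bins))
    if (any(!use_pir)) {
      inc <- per_cond(sup$inc, cc); exc <- per_cond(sup$exc, cc)
      out[!use_pir] <- compute_psi(inc[!use_pir], exc[!use_pir])
    }
    if (any(use_pir)) {
      bi <- match(bins$bin_id[use_pir], rownames(bc$E1I))
      e1 <- per_cond(bc$E1I, cc)[bi]
      e2 <- per_cond(bc$IE2, cc)[bi]
      jj <- per_cond(bc$J, cc)[bi]
      out[use_pir] <- compute_pir(e1, e2, jj)
    }
    out
  }, numeric(length(bins)))
  vals <- matrix(vals, nrow = length(bins),
                 dimnames = list(NULL, paste0("metric_", conds)))
  data.frame(bin_id = bins$bin_id,
             metric = ifelse(use_pir, "PIR", "PSI"), vals,
             delta = vals[, 2] - vals[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential splicing call per bin
#'
#' Annotated bins are DS when FDR is strictly below `max_fdr` and the
#' absolute PSI/PIR change strictly exceeds `min_delta` percentage points;
#' bins discovered through novel junctions are DS when the absolute PSI
#' change strictly exceeds `novel_min_delta` points (no FDR requirement).
#' Bins with no junction support (NA metric) are untestable and never
#' flagged.
#'
#' @param fdr FDR per bin (NA allowed for novel-junction bins).
#' @param delta Metric change per bin, percentage points.
#' @param evidence `"annotated"` or `"novel_junction"` per bin.
#' @param max_fdr,min_delta,novel_min_delta Thresholds (defaults 0.15, 0.5,
#'   10 — strict inequalities).
#' @return Logical vector.
#' @export
call_ds <- function(fdr, delta, evidence = "annotated", max_fdr = 0.15,
                    min_delta = 0.5, novel_min_delta = 10) {
  evidence <- rep(evidence, length.out = length(delta))
  ifelse(evidence == "novel_junction",
         !is.na(delta) & abs(delta) > novel_min_delta,
         !is.na(fdr) & !is.na(delta) & fdr < max_fdr & abs(delta) > min_delta)
}

#' PSI of novel junctions against locally competing junctions
#'
#' For each unannotated junction, PSI per condition is
#' `100 * J / (J + competing)` where `competing` sums the counts of all
#' other junctions sharing its donor or its acceptor coordinate. A novel
#' junction with no competitor gets PSI 100 and is flagged low-confidence.
#'
#' @param jt `junction_table` (already read-filtered).
#' @param design data.frame with `sample`, `condition`.
#' @return data.frame with `junction`, one PSI column per condition,
#'   `delta`, `low_confidence`.
#' @export
psi_for_novel_junctions <- function(jt, design) {
  novel <- which(!jt$annotated)
  conds <- unique(as.character(design$condition))
  if (length(novel) == 0L) {
    out <- data.frame(junction = character(0))
    for (cc in conds) out[[paste0("psi_", cc)]] <- numeric(0)
    out$delta <- numeric(0); out$low_confidence <- logical(0)
    return(out)
  }
  js <- GenomicRanges::start(jt$junctions)
  je <- GenomicRanges::end(jt$junctions)
  jc <- as.character(GenomicRanges::seqnames(jt$junctions))
  cond_counts <- vapply(conds, function(cc)
    rowSums(jt$counts[, design$condition == cc, drop = FALSE]),
    numeric(length(jt$junctions)))
  cond_counts <- matrix(cond_counts, ncol = length(conds))
  psi <- matrix(NA_real_, length(novel), length(conds))
  low <- logical(length(novel))
  for (k in seq_along(novel)) {
    i <- novel[k]
    comp <- which(jc == jc[i] & (js == js[i] | je == je[i]))
    comp <- setdiff(comp, i)
    low[k] <- length(comp) == 0L
    for (ci in seq_along(conds)) {
      own <- cond_counts[i, ci]
      other <- if (length(comp)) sum(cond_counts[comp, ci]) else 0
      psi[k, ci] <- compute_psi(own, other)
      if (low[k]) psi[k, ci] <- 100
    }
  }
  out <- data.frame(junction = rownames(jt$counts)[novel],
                    stringsAsFactors = FALSE)
  for (ci in seq_along(conds)) out[[paste0("psi_", conds[ci])]] <- psi[, ci]
  out$delta <- psi[, 2] - psi[, 1]
  out$low_confidence <- low
  out
}

#' Overlap between DE and DS gene sets
#'
#' @param de_genes,ds_genes Character vectors of gene ids.
#' @return list with counts `de_only`, `both`, `ds_only`.
#' @export
overlap_de_ds <- function(de_genes, ds_genes) {
  list(de_only = length(setdiff(de_genes, ds_genes)),
       both = length(intersect(de_genes, ds_genes)),
       ds_only = length(setdiff(ds_genes, de_genes)))
}

#' Full differential splicing analysis
#'
#' Runs the bin filter cascade, the gene-normalized NB test with joint FDR,
#' junction-supported PSI/PIR quantification and the DS calls, and appends
#' candidate events discovered through novel junctions.
#'
#' @param bin_cm,gene_cm `count_matrix` objects over bins and genes.
#' @param bins `GRanges` of bins.
#' @param jt `junction_table`.
#' @param bc `boundary_counts` over the intron/IR bins.
#' @param design data.frame with `sample`, `condition`.
#' @param gms A [gene_model_set] (to map novel junctions to genes).
#' @param gene_reads,gene_rd,bin_reads,bin_rd_ratio Filter thresholds.
#' @param max_fdr,min_delta,novel_min_delta DS call thresholds.
#' @return list with `bins` (per-bin result table), `novel` (novel-junction
#'   events), `ds_genes` (character vector of genes owning at least one
#'   flagged bin or event).
#' @export
ds_analysis <- function(bin_cm, gene_cm, bins, jt, bc, design, gms,
                        gene_reads = 10, gene_rd = 0.05,
                        bin_reads = 5, bin_rd_ratio = 0.05,
                        max_fdr = 0.15, min_delta = 0.5,
                        novel_min_delta = 10) {
  testable <- filter_bins(bin_cm, gene_cm, bins, design,
                          gene_reads, gene_rd, bin_reads, bin_rd_ratio)
  keep <- names(testable)[testable]
  bsel <- bins[match(keep, bins$bin_id)]
  sub_cm <- list(counts = bin_cm$counts[keep, , drop = FALSE],
                 rd = bin_cm$rd[keep, , drop = FALSE],
                 width = bin_cm$width[keep])
  class(sub_cm) <- "count_matrix"
  test <- test_bins_normalized(sub_cm, gene_cm, bins, design)
  met <- bin_splice_metrics(bsel, jt, bc, design)
  tab <- cbind(test[match(met$bin_id, test$bin_id), ],
               met[, -1, drop = FALSE])
  tab$kind <- bsel$kind
  tab$as_class <- bsel$as_class
  tab$evidence <- "annotated"
  tab$ds <- call_ds(tab$fdr, tab$delta, tab$evidence, max_fdr, min_delta,
                    novel_min_delta)
  rownames(tab) <- NULL
  novel <- psi_for_novel_junctions(jt, design)
  if (nrow(novel) > 0) {
    novel$ds <- call_ds(NA_real_, novel$delta, "novel_junction", max_fdr,
                        min_delta, novel_min_delta)
    # map novel junctions to genes by overlap with gene extents
    jr <- jt$junctions[!jt$annotated]
    genes_gr <- GenomicRanges::GRanges(gms$genes$seqnames,
      IRanges::IRanges(gms$genes$start, gms$genes$end))
    hit <- GenomicRanges::findOverlaps(jr, genes_gr, ignore.strand = TRUE,
                                       select = "first")
    novel$gene_id <- gms$genes$gene_id[hit]
  } else novel$gene_id <- character(0)
  ds_genes <- union(unique(tab$gene_id[tab$ds]),
                    unique(stats::na.omit(novel$gene_id[novel$ds])))
  list(bins = tab, novel = novel, ds_genes = ds_genes)
}
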