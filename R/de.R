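#' Expression filter at the gene level
#'
#' A gene passes when, in at least one condition (or in every condition with
#' `all_conditions = TRUE`, the variant used as gate for splicing analysis),
#' its per-condition total read count strictly exceeds `min_reads` and its
#' per-condition read density (total reads / effective width) strictly
#' exceeds `min_rd`.
#'
#' @param gene_cm A `count_matrix` from [count_genes()].
#' @param design data.frame with `sample`, `condition`.
#' @param min_reads Read threshold (default 10, strict >).
#' @param min_rd Read-density threshold in reads/nt (default 0.05, strict >).
#' @param all_conditions Require the thresholds in every condition rather
#'   than at least one.
#' @return Named logical vector over genes.
#' @export
filter_expressed <- function(gene_cm, design, min_reads = 10, min_rd = 0.05,
                             all_conditions = FALSE) {
  if (!identical(colnames(gene_cm$counts), design$sample))
    stop("design samples do not match count matrix columns")
  conds <- unique(as.character(design$condition))
  pass_by_cond <- vapply(conds, function(cc) {
    tot <- rowSums(gene_cm$counts[, design$condition == cc, drop = FALSE])
    rd <- tot / gene_cm$width
    tot > min_reads & rd > min_rd
  }, logical(nrow(gene_cm$counts)))
  if (all_conditions) apply(pass_by_cond, 1L, all) else apply(pass_by_cond, 1L, any)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; the output is invariant to input
#' order and capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is DE when its FDR is strictly below `max_fdr` and its absolute
#' fold change strictly exceeds `min_fc` in either direction.
#'
#' @param results data.frame with `fdr` and `logFC` columns.
#' @param max_fdr FDR threshold (default 0.05).
#' @param min_fc Fold-change threshold (default 1.5).
#' @return Logical vector.
#' @export
call_de <- function(results, max_fdr = 0.05, min_fc = 1.5) {
  results$fdr < max_fdr & abs(results$logFC) > log2(min_fc)
}

#' Gene-level differential expression analysis
#'
#' Filters genes by expression, tests the survivors with the NB exact test,
#' adjusts p-values by Benjamini-Hochberg and applies the FDR and
#' fold-change calls. Genes failing the expression filter are kept in the
#' table with NA statistics and `de = FALSE`.
#'
#' @param gene_cm A `count_matrix` from [count_genes()].
#' @param design data.frame with `sample`, `condition`.
#' @param min_reads,min_rd Expression filter thresholds.
#' @param max_fdr,min_fc DE call thresholds.
#' @param norm_method Passed to [nb_test()].
#' @return data.frame with `gene_id`, `expressed`, `logFC`, `pvalue`, `fdr`,
#'   `de`.
#' @export
de_analysis <- function(gene_cm, design, min_reads = 10, min_rd = 0.05,
                        max_fdr = 0.05, min_fc = 1.5,
                        norm_method = "TMM") {
  expressed <- filter_expressed(gene_cm, design, min_reads, min_rd)
  out <- data.frame(gene_id = rownames(gene_cm$counts), expressed = expressed,
                    logFC = NA_real_, pvalue = NA_real_, fdr = NA_real_,
                    de = FALSE, row.names = NULL, stringsAsFactors = FALSE)
  if (any(expressed)) {
    res <- nb_test(gene_cm$counts[expressed, , drop = FALSE], design,
                   norm_method = norm_method)
    res$fdr <- bh_fdr(res$pvalue)
    idx <- match(res$feature_id, out$gene_id)
    out$logFC[idx] <- res$logFC
    out$pvalue[idx] <- res$pvalue
    out$fdr[idx] <- res$fdr
    out$de[idx] <- call_de(res, max_fdr, min_fc)
  }
  out
}
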