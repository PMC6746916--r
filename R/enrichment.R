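#' GO over-representation by Fisher's exact test
#'
#' One-sided (over-representation) hypergeometric test per term: with `k`
#' set genes in the term, `n` set genes, `K` universe genes in the term and
#' `N` universe genes, the p-value is the upper tail P(X >= k). FDR is
#' adjusted within each ontology (BP/MF/CC are separate analyses). The
#' enrichment factor is the proportion of the term in the set over its
#' proportion in the universe: `EF = (k/n) / (K/N)`. Terms with no universe
#' gene are skipped.
#'
#' @param gene_set Character vector, a subset of `universe`.
#' @param universe Character vector of background genes.
#' @param term_map data.frame with columns `gene_id`, `term_id`, `ontology`
#'   (pre-propagated gene-to-term mapping).
#' @return data.frame with `term_id`, `ontology`, `k`, `n`, `K`, `N`,
#'   `pvalue`, `fdr`, `EF`, ordered by ontology then p-value.
#' @export
fisher_enrichment <- function(gene_set, universe, term_map) {
  stopifnot(all(c("gene_id", "term_id", "ontology") %in% names(term_map)))
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  if (length(gene_set) == 0L)
    return(data.frame(term_id = character(0), ontology = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), pvalue = numeric(0), fdr = numeric(0),
                      EF = numeric(0)))
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(gene_set)
  out <- do.call(rbind, lapply(split(tm, tm$ontology), function(sub) {
    terms <- split(sub$gene_id, sub$term_id)
    K <- vapply(terms, function(g) length(unique(g)), integer(1))
    k <- vapply(terms, function(g) length(intersect(unique(g), gene_set)),
                integer(1))
    keep <- K > 0
    p <- stats::phyper(k[keep] - 1, K[keep], N - K[keep], n,
                       lower.tail = FALSE)
    data.frame(term_id = names(terms)[keep], ontology = sub$ontology[1],
               k = k[keep], n = n, K = K[keep], N = N, pvalue = p,
               fdr = bh_fdr(p),
               EF = (k[keep] / n) / (K[keep] / N),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$ontology, out$pvalue), , drop = FALSE]
}

#' Merge enrichment results into a bubble-plot table
#'
#' Keeps the union of terms whose adjusted p-value is strictly below
#' `max_fdr` in at least one dataset, with one adjusted-p and one EF column
#' per dataset — the data behind a bubble rendering (size ~ EF, colour ~
#' adjusted p).
#'
#' @param rows_list Named list of data.frames from [fisher_enrichment()].
#' @param max_fdr Inclusion threshold on the adjusted p (default 0.01,
#'   strict <).
#' @return data.frame with `term_id`, `ontology` and `fdr_<dataset>`,
#'   `EF_<dataset>` columns; empty (not an error) when no term passes.
#' @export
bubble_table <- function(rows_list, max_fdr = 0.01) {
  stopifnot(length(rows_list) >= 1L)
  if (is.null(names(rows_list)))
    names(rows_list) <- paste0("dataset", seq_along(rows_list))
  pass <- unique(do.call(rbind, lapply(rows_list, function(df)
    df[df$fdr < max_fdr, c("term_id", "ontology"), drop = FALSE])))
  if (is.null(pass) || nrow(pass) == 0L) {
    out <- data.frame(term_id = character(0), ontology = character(0))
    for (nm in names(rows_list)) {
      out[[paste0("fdr_", nm)]] <- numeric(0)
      out[[paste0("EF_", nm)]] <- numeric(0)
    }
    return(out)
  }
  out <- pass[order(pass$ontology, pass$term_id), , drop = FALSE]
  rownames(out) <- NULL
  for (nm in names(rows_list)) {
    df <- rows_list[[nm]]
    m <- match(paste(out$term_id, out$ontology),
               paste(df$term_id, df$ontology))
    out[[paste0("fdr_", nm)]] <- df$fdr[m]
    out[[paste0("EF_", nm)]] <- df$EF[m]
  }
  out
}
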