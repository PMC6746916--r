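#' Pipeline configuration with the study's default thresholds
#'
#' Houses every numeric threshold of the analysis. The defaults are the
#' values used throughout: gene expression filter (>10 reads, RD > 0.05),
#' bin filter (>5 reads, RD ratio > 0.05), junction read filter (5), DE
#' calls (FDR < 0.05, fold change > 1.5), DS calls (FDR < 0.15, |delta
#' PSI/PIR| > 0.5 points; novel junctions |delta PSI| > 10 points), GO
#' bubble inclusion (adjusted p < 0.01).
#'
#' @param ... Overrides for individual thresholds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(gene_reads = 10, gene_rd = 0.05,
              bin_reads = 5, bin_rd_ratio = 0.05,
              junction_reads = 5,
              de_fdr = 0.05, de_fc = 1.5,
              ds_fdr = 0.15, ds_delta = 0.5, novel_delta = 10,
              go_fdr = 0.01,
              min_anchor = 1, norm_method = "TMM", seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- vapply(cfg[setdiff(names(cfg), c("norm_method"))], is.numeric, logical(1))
  stopifnot(all(num), all(unlist(cfg[names(num)[num]]) >= 0))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end analysis
#'
#' Chains the stages over a set of spliced alignments: gene/bin counting,
#' junction and boundary extraction, differential expression, differential
#' splicing with junction support, DE/DS overlap, and (when a term map is
#' given) GO enrichment of both gene sets. A filter funnel records the
#' number of features entering and surviving every stage.
#'
#' @param gms A [gene_model_set].
#' @param alignments Named list of `GAlignments` (or of paths to SAM/BAM
#'   files, read on the fly), one per sample.
#' @param design data.frame with `sample`, `condition`.
#' @param config A [pipeline_config].
#' @param term_map Optional gene-to-GO mapping (data.frame with `gene_id`,
#'   `term_id`, `ontology`).
#' @param outdir Optional directory where stage tables are written as TSV.
#' @return list with `de`, `ds`, `overlap`, `enrichment` (or NULL),
#'   `funnel`, plus the intermediate `bins`, `gene_counts`, `bin_counts`,
#'   `junctions`.
#' @export
run_pipeline <- function(gms, alignments, design, config = pipeline_config(),
                         term_map = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(alignments))
    alignments <- stats::setNames(lapply(alignments, read_alignments),
                                  names(alignments))
  stopifnot(identical(names(alignments), design$sample))
  funnel <- list()
  note <- function(stage, value) {
    funnel[[stage]] <<- value
    message(sprintf("[splicebins] %-28s %d", stage, value))
  }

  note("genes_annotated", nrow(gms$genes))
  bins <- build_bins(gms)
  note("bins_defined", length(bins))

  gene_cm <- count_genes(alignments, gms)
  bin_cm <- count_features(alignments, bins)
  introns <- gene_introns(gms)
  jt <- extract_junctions(alignments, introns,
                          min_reads = config$junction_reads)
  note("junctions_kept", length(jt$junctions))
  intron_like <- bins[bins$kind == "intron" | bins$as_class == "IR"]
  bc <- count_boundaries(alignments, intron_like, jt,
                         min_anchor = config$min_anchor)

  de <- de_analysis(gene_cm, design, min_reads = config$gene_reads,
                    min_rd = config$gene_rd, max_fdr = config$de_fdr,
                    min_fc = config$de_fc, norm_method = config$norm_method)
  note("genes_expressed", sum(de$expressed))
  note("genes_de", sum(de$de))

  ds <- ds_analysis(bin_cm, gene_cm, bins, jt, bc, design, gms,
                    gene_reads = config$gene_reads, gene_rd = config$gene_rd,
                    bin_reads = config$bin_reads,
                    bin_rd_ratio = config$bin_rd_ratio,
                    max_fdr = config$ds_fdr, min_delta = config$ds_delta,
                    novel_min_delta = config$novel_delta)
  note("bins_testable", nrow(ds$bins))
  note("bins_ds", sum(ds$bins$ds))
  note("genes_ds", length(ds$ds_genes))

  de_genes <- de$gene_id[de$de]
  overlap <- overlap_de_ds(de_genes, ds$ds_genes)

  enr <- NULL
  if (!is.null(term_map)) {
    universe <- de$gene_id[de$expressed]
    enr <- list(DE = fisher_enrichment(intersect(de_genes, universe),
                                       universe, term_map),
                DS = fisher_enrichment(intersect(ds$ds_genes, universe),
                                       universe, term_map))
    enr$bubble <- bubble_table(enr[c("DE", "DS")], max_fdr = config$go_fdr)
  }

  out <- list(de = de, ds = ds, overlap = overlap, enrichment = enr,
              funnel = funnel, bins = bins, gene_counts = gene_cm,
              bin_counts = bin_cm, junctions = jt)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(de, file.path(outdir, "de_genes.tsv"))
    write_tsv(ds$bins, file.path(outdir, "ds_bins.tsv"))
    write_tsv(ds$novel, file.path(outdir, "ds_novel_junctions.tsv"))
    write_tsv(data.frame(gene_id = ds$ds_genes),
              file.path(outdir, "ds_genes.tsv"))
    write_tsv(data.frame(set = names(overlap),
                         n = unlist(overlap)),
              file.path(outdir, "de_ds_overlap.tsv"))
    write_bins(bins, file.path(outdir, "bins.tsv"))
    if (!is.null(enr)) {
      write_tsv(enr$DE, file.path(outdir, "go_de.tsv"))
      write_tsv(enr$DS, file.path(outdir, "go_ds.tsv"))
      write_tsv(enr$bubble, file.path(outdir, "go_bubble.tsv"))
    }
  }
  out
}
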