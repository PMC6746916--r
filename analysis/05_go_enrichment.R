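#!/usr/bin/env Rscript

# Stage 5: GO over-representation of the DE and DS gene sets.
#
# Builds a synthetic pre-propagated gene-to-GO map over the simulated
# transcriptome in which one BP term preferentially annotates DS genes
# (emulating the enrichment of mRNA-processing terms among light-regulated
# AS genes) and one term preferentially annotates DE genes. Fisher exact
# tests per term, BH FDR within each ontology, enrichment factors, and the
# bubble table of terms with adjusted p < 0.01 in at least one set.

library(splicebins)

outdir <- "results/go"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

de <- read.delim("results/de/de_genes.tsv")
ds_genes <- read.delim("results/ds/ds_genes.tsv")$gene_id
universe <- de$gene_id[de$expressed]    # expressed genes as background
de_genes <- intersect(de$gene_id[de$de], universe)
ds_genes <- intersect(ds_genes, universe)

set.seed(20190910)
terms <- sprintf("GO:%07d", 1:30)
ontos <- rep(c("BP", "MF", "CC"), each = 10)
rows <- lapply(seq_along(terms), function(i) {
  base <- sample(universe, 30)
  extra <- switch(as.character(i),
    "1" = sample(ds_genes, min(15, length(ds_genes))),  # splicing-like term
    "2" = sample(de_genes, min(15, length(de_genes))),  # light-response-like
    character(0))
  data.frame(gene_id = unique(c(base, extra)), term_id = terms[i],
             ontology = ontos[i])
})
term_map <- do.call(rbind, rows)
write_tsv(term_map, file.path(outdir, "synthetic_term_map.tsv"))

enr_de <- fisher_enrichment(de_genes, universe, term_map)
enr_ds <- fisher_enrichment(ds_genes, universe, term_map)
bt <- bubble_table(list(DE = enr_de, DS = enr_ds), max_fdr = 0.01)

write_tsv(enr_de, file.path(outdir, "go_de.tsv"))
write_tsv(enr_ds, file.path(outdir, "go_ds.tsv"))
write_tsv(bt, file.path(outdir, "go_bubble.tsv"))

cat(sprintf("universe %d genes; DE set %d; DS set %d; %d terms tested\n",
            length(universe), length(de_genes), length(ds_genes),
            length(terms)))
cat("top DS enrichments:\n")
print(head(enr_ds[, c("term_id", "ontology", "k", "K", "pvalue", "fdr", "EF")], 3))
cat(sprintf("%d term(s) in the bubble table (adjusted p < 0.01 somewhere)\n",
            nrow(bt)))
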