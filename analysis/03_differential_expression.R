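#!/usr/bin/env Rscript

# Stage 3: differential gene expression.
#
# Applies the expression filter (>10 reads and read density > 0.05 in at
# least one condition), tests filtered genes with the TMM-normalized NB
# exact test, adjusts p-values by Benjamini-Hochberg and calls DE at
# FDR < 0.05 with |fold change| > 1.5. Compares the calls against the
# simulation ground truth.

library(splicebins)

simdir <- "results/sim"
outdir <- "results/de"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

gms <- load_annotation(file.path(simdir, "annotation.gtf"))
design <- read.delim(file.path(simdir, "design.tsv"))
design$condition <- factor(design$condition, unique(design$condition))
aln <- lapply(design$sample, function(s)
  read_alignments(file.path(simdir, paste0(s, ".sam"))))
names(aln) <- design$sample
truth <- read.delim(file.path(simdir, "truth.tsv"))

gene_cm <- count_genes(aln, gms)
de <- de_analysis(gene_cm, design)
write_tsv(de, file.path(outdir, "de_genes.tsv"))

cat(sprintf("%d / %d genes pass the expression filter\n",
            sum(de$expressed), nrow(de)))
cat(sprintf("%d genes called DE (FDR < 0.05, |FC| > 1.5)\n", sum(de$de)))
true_de <- truth$gene_id[truth$de]
called <- de$gene_id[de$de]
cat(sprintf("recovery of planted DE genes: %.1f%%; false discoveries: %.1f%%\n",
            100 * mean(true_de %in% called),
            100 * mean(!(called %in% true_de))))
cat("wrote de_genes.tsv under", outdir, "\n")
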