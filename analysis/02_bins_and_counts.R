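#!/usr/bin/env Rscript

# Stage 2: partition genes into bins and summarise reads.
#
# Loads the GTF and SAM files from stage 1, partitions every multiexonic
# gene into exon/intron/AS bins at the union of exon boundaries, counts
# reads per gene and per bin (a read counts toward every bin an aligned
# block touches), and extracts splice junctions (gapped reads; junctions
# with fewer than five reads across all samples are discarded) and
# intron-boundary support. Tables go to results/counts/.

library(splicebins)

simdir <- "results/sim"
outdir <- "results/counts"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

gms <- load_annotation(file.path(simdir, "annotation.gtf"))
design <- read.delim(file.path(simdir, "design.tsv"))
design$condition <- factor(design$condition, unique(design$condition))
aln <- lapply(design$sample, function(s)
  read_alignments(file.path(simdir, paste0(s, ".sam"))))
names(aln) <- design$sample

bins <- build_bins(gms)
cat(sprintf("defined %d bins over %d multiexonic genes:\n",
            length(bins), sum(gms$genes$multiexonic)))
print(table(kind = bins$kind))
print(table(as_class = bins$as_class[bins$kind == "AS"]))

gene_cm <- count_genes(aln, gms)
bin_cm <- count_features(aln, bins)
jt <- extract_junctions(aln, gene_introns(gms), min_reads = 5)
cat(sprintf("kept %d junctions (>= 5 reads); %d annotated, %d novel\n",
            length(jt$junctions), sum(jt$annotated), sum(!jt$annotated)))
intron_like <- bins[bins$kind == "intron" | bins$as_class == "IR"]
bc <- count_boundaries(aln, intron_like, jt, min_anchor = 1)

write_bins(bins, file.path(outdir, "bins.tsv"))
write_tsv(data.frame(gene_id = rownames(gene_cm$counts), gene_cm$counts,
                     check.names = FALSE),
          file.path(outdir, "gene_counts.tsv"))
write_tsv(data.frame(bin_id = rownames(bin_cm$counts), bin_cm$counts,
                     check.names = FALSE),
          file.path(outdir, "bin_counts.tsv"))
write_tsv(data.frame(junction = rownames(jt$counts),
                     annotated = jt$annotated, jt$counts,
                     check.names = FALSE),
          file.path(outdir, "junction_counts.tsv"))
write_tsv(data.frame(bin_id = rownames(bc$E1I),
                     E1I = rowSums(bc$E1I), IE2 = rowSums(bc$IE2),
                     J = rowSums(bc$J)),
          file.path(outdir, "boundary_counts_total.tsv"))
cat("wrote bins.tsv, gene_counts.tsv, bin_counts.tsv, junction_counts.tsv\n")
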