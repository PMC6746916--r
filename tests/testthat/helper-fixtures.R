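# Hand-built filter-cascade fixture: 12 genes / 30 bins with pass/fail
# status enumerated by hand at every threshold (gene >10 reads & RD>0.05;
# bin >5 reads & RD ratio >0.05; all inequalities strict). One replicate
# per condition keeps the arithmetic auditable.

cascade_design <- function() {
  data.frame(sample = c("Rp_1", "FRp_1"),
             condition = factor(c("Rp", "FRp"), levels = c("Rp", "FRp")))
}

cascade_genes <- function() {
  # width, Rp, FRp | RD_Rp, RD_FRp | expressed (>=1 cond) | gate (all conds)
  g <- read.table(header = TRUE, text = "
gene  width  rp   frp  expressed gate
g01   100    20   20   TRUE      TRUE
g02   100    11   6    TRUE      FALSE
g03   100    10   10   FALSE     FALSE
g04   1000   40   60   TRUE      FALSE
g05   100000 1000 1000 FALSE     FALSE
g06   200    11   11   TRUE      TRUE
g07   220    11   11   FALSE     FALSE
g08   100    0    0    FALSE     FALSE
g09   100    500  500  TRUE      TRUE
g10   100    12   300  TRUE      TRUE
g11   100    1000 8    TRUE      FALSE
g12   500    100  100  TRUE      TRUE
", stringsAsFactors = FALSE)
  # enumeration notes: g02 fails the gate in FRp (6 <= 10); g03 fails 10 > 10;
  # g04 RD_Rp = 0.04 <= 0.05; g05 RD = 0.01; g07 RD = 11/220 = 0.05 exactly
  # (strict >); g11 fails the gate in FRp (8 <= 10).
  g
}

cascade_bins <- function() {
  # per-bin: width, Rp, FRp counts, hand-derived expectation. ratio =
  # (bin_count/width) / (gene_count/gene_width), needed > 0.05 with
  # bin_count > 5, in at least one condition, and the parent gate open.
  read.table(header = TRUE, text = "
bin  gene width rp  frp expected
b01  g01  50    6   0   TRUE
b02  g01  50    5   5   FALSE
b03  g01  100   6   6   TRUE
b04  g01  600   6   6   FALSE
b05  g02  50    30  30  FALSE
b06  g02  50    6   6   FALSE
b07  g03  50    8   8   FALSE
b08  g03  50    0   0   FALSE
b09  g04  100   20  30  FALSE
b10  g04  100   6   6   FALSE
b11  g05  100   90  90  FALSE
b12  g05  100   7   7   FALSE
b13  g06  100   6   6   TRUE
b14  g06  100   5   4   FALSE
b15  g07  100   11  11  FALSE
b16  g07  100   6   0   FALSE
b17  g08  100   0   0   FALSE
b18  g09  10    6   0   TRUE
b19  g09  100   100 100 TRUE
b20  g09  100   26  25  TRUE
b21  g09  100   25  25  FALSE
b22  g09  500   6   6   FALSE
b23  g09  20    6   500 TRUE
b24  g10  50    6   0   TRUE
b25  g10  50    0   6   FALSE
b26  g10  50    0   10  TRUE
b27  g11  50    400 4   FALSE
b28  g12  100   30  2   TRUE
b29  g12  100   6   1   TRUE
b30  g12  400   5   5   FALSE
", stringsAsFactors = FALSE)
  # boundary notes: b02/b14/b30 fail 5 > 5; b04 ratio = (6/600)/(20/100) =
  # 0.05 exactly; b21 ratio = 0.05 exactly both conditions; b20 ratio_Rp =
  # (26/100)/5 = 0.052 passes; b23 ratio_Rp = (6/20)/5 = 0.06 passes while
  # ratio_FRp = (500/20)/5 = 5 but paired with 500 > 5 also passes; b25
  # fails ratio in FRp ((6/50)/3 = 0.04) and reads in Rp; b26 ratio_FRp =
  # (10/50)/3 = 0.0667 with 10 > 5 passes; b05/b06 parent g02 gated out;
  # b09-b12, b15-b17, b27 parent gated out.
}

cascade_matrices <- function() {
  g <- cascade_genes()
  b <- cascade_bins()
  design <- cascade_design()
  gcounts <- as.matrix(g[, c("rp", "frp")])
  dimnames(gcounts) <- list(g$gene, design$sample)
  gw <- stats::setNames(as.numeric(g$width), g$gene)
  gcm <- structure(list(counts = gcounts, rd = gcounts / gw, width = gw),
                   class = "count_matrix")
  bcounts <- as.matrix(b[, c("rp", "frp")])
  dimnames(bcounts) <- list(b$bin, design$sample)
  bw <- stats::setNames(as.numeric(b$width), b$bin)
  bcm <- structure(list(counts = bcounts, rd = bcounts / bw, width = bw),
                   class = "count_matrix")
  # bin coordinates are irrelevant to the cascade; lay them out in a line
  bins <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_len(nrow(b)) * 1000L,
                     width = as.integer(b$width)),
    bin_id = b$bin, gene_id = b$gene, kind = "exon", as_class = "none")
  list(design = design, genes = g, bins_tab = b, gcm = gcm, bcm = bcm,
       bins = bins)
}
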