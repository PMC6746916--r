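---
title: "Bin-based differential alternative splicing analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based differential alternative splicing analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicebins)
```

# The problem

Red light perceived by phytochromes releases Arabidopsis seed dormancy and
triggers germination. Beyond transcript abundance, light also reshapes the
alternative splicing (AS) of a substantial set of genes — notably of the
splicing machinery itself. Detecting those AS changes from bulk RNA-seq of
seeds irradiated with a red pulse (Rp) versus a far-red pulse (FRp) is the
task this package implements: a bin-based differential splicing analysis
with junction-level confirmation, alongside conventional differential
expression, GO over-representation, and the statistics used for germination
assays and RT-PCR splicing indices.

# Subgenic bins

Every multiexonic gene is partitioned at the union of the exon start/end
positions of all its transcripts. Each resulting subinterval is a *bin*:

* **exon bin** — exonic in every transcript that spans it;
* **intron bin** — intronic in every transcript that spans it;
* **AS bin** — exonic in some transcripts and intronic in others.

Adjacent subintervals with the same kind and identical per-transcript
support are merged, so bins tile the gene span between the first and last
exon boundary without gaps or overlaps (a property the test suite asserts
on simulated annotations). AS bins are further classified:

* **IR** — the bin equals a full intron of one transcript and lies inside
  an exon of another;
* **ES** — the bin equals a full exon of one transcript and is spliced
  over by another;
* **Alt5SS / Alt3SS** — the bin abuts a shared exonic region on exactly
  one side; whether the varying boundary is a donor or an acceptor follows
  from the side and the strand (the classifier is antisymmetric under
  strand reversal, which the tests check with strand-flipped fixtures);
* **multiple** — a run of adjacent AS bins showing three or more distinct
  event classes, and any geometry matching none of the above (alternative
  first/last exons end up here rather than being dropped). The extent of
  the "same subgenic region" is taken as the maximal run of adjacent AS
  bins, the most conservative reading available.

Bins supported only by alternative transcription starts/ends are not given
a dedicated class; they fall into the catch-all and are flagged by the
classifier's warning rather than silently guessed.

Coordinates are held in `GRanges`/`IRanges` containers throughout (1-based,
closed intervals, the Bioconductor convention); GTF, SAM and BED-like I/O
goes through `rtracklayer`/`Rsamtools`/`GenomicAlignments`, so no manual
coordinate conversion exists in the package.

# Counting

A read counts toward a feature when any of its aligned blocks overlaps the
feature by at least one nucleotide. A gapped read spanning two exons
therefore counts toward both exon bins and not toward the intron bin its
N gap jumps over; a read may count toward several bins but only once per
bin. Gene counts use the union of the gene's exons; the *effective width*
of a gene is the size of that union ("all the exons of a given gene" is
read as the union rather than the per-transcript sum, which would double-
count shared exons). Read density (RD) is count / width. Counting is
strand-unaware (an unstranded library is assumed) and integer; no
mapping-quality or duplicate handling is applied beyond what the caller
feeds in.

Splice junctions are the N-gap intervals of gapped alignments. Junctions
with fewer than five reads are discarded; the filter is applied to the
maximum count over all samples, which keeps junctions usable in at least
one condition. Survivors are flagged *annotated* when they exactly match
an annotated intron. For intron bins, boundary support is counted with a
configurable anchor (default 1 nt, the weakest literal reading of a
boundary-spanning read): `E1I` reads cover the exon–intron boundary with
at least the anchor on each side, `IE2` the intron–exon boundary, and `J`
counts the junction that exactly excises the intron.

# Differential expression

Genes enter the test when, in at least one condition, the summed replicate
count strictly exceeds 10 and RD strictly exceeds 0.05 (sums are the most
permissive literal reading and are stable at n = 3). Testing is a
negative-binomial exact test implemented in the package:

1. **TMM normalization** — trimmed mean of M-values (30% two-sided trim on
   log-ratios, 5% on average intensities, precision weights), factors
   normalized to geometric mean one. A `norm_method = "none"` switch is
   exposed because the original normalization choice is not documented.
2. **Depth equalization** — counts are scaled to the geometric-mean
   effective library size, after which samples are treated as
   exchangeable.
3. **Dispersion** — the NB dispersion φ (variance μ + φμ²) is estimated by
   maximizing the conditional likelihood of the equalized counts given
   their group sums (which does not depend on the means); a common value
   over all genes is refined by a golden-section step, then per-gene
   estimates are shrunk toward it by weighting the common likelihood with
   a prior weight of 10 genes.
4. **Exact test** — conditional on the total of the two group sums, the
   first group's sum follows a distribution depending only on φ and the
   group sizes; the two-sided p-value sums all outcomes no more probable
   than the observed one. As φ → 0 this converges to the conditional
   binomial test, a limit the tests verify against an independent
   enumeration oracle (and, separately, the whole gene-level path is
   cross-checked against edgeR's exact test, which must agree in ranking
   and calls without being part of the implementation).

Log2 fold changes use a prior count of 0.5 per group so zero counts stay
finite. BH-adjusted p-values below 0.05 with fold change above 1.5 in
either direction call a gene DE; all inequalities at stated thresholds are
strict throughout the package.

# Differential splicing

The filter cascade keeps a bin only when (a) its gene passes the
expression thresholds in *every* condition and (b) the bin itself has
strictly more than 5 reads and an RD(bin)/RD(gene) ratio strictly above
0.05 in at least one condition.

**The usage test.** Bin counts must be normalized to their gene so that
expression changes do not masquerade as splicing changes. The package
tests each bin with a 2×2 conditional (hypergeometric) exact test of bin
reads versus remaining gene reads across the two conditions, on
replicate-summed counts, with a mid-p correction by default. The design
was chosen over an offset-NB formulation deliberately: conditional on its
gene's counts, a bin's count is a binomial thinning — *sub*-Poisson — so
an NB test that conditions only on the bin total is structurally
conservative (on a 2,000-gene splicing-null simulation it yields a raw
p < 0.05 fraction of ~0.011). Conditioning on both margins removes the
gene-expression variance exactly, which is precisely what "normalizing to
the gene" is meant to achieve; measured on the same null the mid-p version
gives a p < 0.05 fraction of 0.050 and passes a KS uniformity test.
`p_method = "exact"` restores the classical conservative Fisher p. The
conditional test carries no replicate-level overdispersion parameter:
biological variability of splicing ratios *between replicates of the same
condition* is not modelled (see Limitations). FDR is computed jointly
across all tested bins, exon, intron and AS alike.

**Junction confirmation.** Per condition (replicates summed):

* PSI = 100 · inclusion / (inclusion + exclusion). Inclusion junctions are
  those abutting the bin; a cassette exon has one on each side and their
  counts are *averaged* over the sides present in the junction table,
  because summing them makes the junction PSI of a true 50% event converge
  to 2p/(2p+q) ≈ 67% rather than 50% — averaging is also the convention of
  event-level tools. Alternative splice-site bins have a single proximal
  junction, compared against the distal junction spanning the bin.
* PIR = 100 · (E1I + IE2) / (E1I + IE2 + 2·J) for intron and IR bins.

A bin is DS when FDR < 0.15 *and* |ΔPSI| or |ΔPIR| > 0.5 percentage
points (">0.5%" is read as percentage points, consistently with the 10%
novel-junction rule). Bins with no junction support are reported
untestable and never flagged. Regions seen only through novel junctions
(no annotated match) are quantified against competing junctions sharing a
donor or acceptor and called DS at |ΔPSI| > 10 points with no FDR
requirement — exactly the stated rule, with no additional test imposed. A
novel junction without any competitor gets PSI 100 and a low-confidence
flag. DS genes are genes owning at least one flagged bin or novel-junction
event.

# GO over-representation

One-sided hypergeometric p-values per term (over-representation being the
question asked), BH FDR within each of BP/MF/CC separately (the three
ontologies are separate analyses), and the enrichment factor
EF = (k/n)/(K/N). The universe defaults to the genes passing the
expression filter but can be switched to the whole annotation; the term
map is taken as given (pre-propagated) — no GO-graph propagation is
performed. The bubble table unions terms with adjusted p strictly below
0.01 in at least one input set.

# Germination and splicing-index statistics

The splicing index is the longest isoform's densitometric share of all
isoforms, in [0, 1], scale-invariant per sample. Germination percentages
are arcsine-square-root transformed (degrees by default) before a two-way
ANOVA (genotype × treatment) with Type II sums of squares — the
conventional choice for possibly unbalanced factorial germination designs.
When the interaction is significant at 0.05 the "Fisher post-test" is run
as Fisher's (unprotected) LSD on the pooled residual mean square over all
cell means, summarized as a compact letter display in which two cells
share a letter exactly when their comparison p ≥ 0.05. Genotype
backgrounds (e.g. Col-0/phyB-9 vs Ler/phyB-5) can be analyzed jointly or
per background simply by subsetting before the call, as the analysis
scripts do. A constant response returns zero sums of squares with p = 1
for every effect rather than an error.

# The simulator

`sim_config()` fixes the study conditions: two conditions labelled Rp/FRp
with three biological replicates each; single-end 100 nt reads; NB gene
counts with dispersion 0.05 (typical for bulk RNA-seq replicates; 0 gives
Poisson); 20% DE genes at 3-fold (the red pulse changes roughly a fifth of
the transcriptome); 20% of genes carrying exactly one AS event whose
inclusion shifts by 30 points around a base of 50%. Genes have 2–4 exons
(100–300 nt) and introns of 120–200 nt on either strand; alternative
splice sites shift a boundary by 30 nt; one AS event per DS gene keeps the
ground truth unambiguous. DE and DS gene sets are drawn independently, so
they overlap at chance rates like the partial overlap between
expression- and splicing-regulated sets. Reads are emitted pre-aligned
(SAM records with M/N CIGARs) because the analysis starts from aligned
reads; there is no sequencing-error model, no positional bias, no
paired-end structure, no multimapping, and no sequence content.

Two modelling points deserve emphasis. First, a read picks its isoform
with probability proportional to molar fraction × effective transcript
length (positions a read can start at), the physically correct sampling;
with a plain Bernoulli on the inclusion level, junction-based PSI would
converge to a length-biased value (~41% for a true 50% cassette between
isoforms of typical simulated lengths) instead of the configured truth.
Second, `delta_inclusion = 0` produces AS events with no condition effect
— a splicing null with live junction variation — and such genes are *not*
flagged DS in the ground truth, so null calibration runs are meaningful.

What passing tests on this simulator do **not** show: robustness to
misalignment, soft-clipping, degraded RNA, overlapping genes, unannotated
transcripts, or replicate-level splicing heterogeneity. The simulator
shares no counting code with the pipeline, and the test suite additionally
recounts junctions, boundaries and PSI/PIR with a brute-force CIGAR walker
written in plain base R.

# Numerical choices

* Dispersion search on a 31-point log grid over [10⁻⁶, 4] with local
  refinement; tagwise maxima taken on the grid.
* Exact-test tail sums include outcomes with probability ≤ observed ×
  (1 + 10⁻¹⁰) to absorb floating-point ties; mid-p gives weight ½ to the
  observed table.
* PSI/PIR with zero support are NA, never 0/0; genes with zero counts get
  p = 1 and logFC 0; a zero gene count in the usage test contributes a
  clamped non-negative complement.
* Problem sizes in the tests were chosen to finish a full run in a few
  minutes: null calibration on 2,000 genes, recovery on 500 genes at mean
  coverage 1,000, oracle equivalence on 50 genes, the Fisher sweep
  exhaustive to N = 200.

# Limitations

* Two-group designs only; no covariates, batch terms or GLM interface.
* The usage test models no replicate-level splicing overdispersion; on
  real data with biological splicing variability its p-values will be
  anticonservative, and a beta-binomial extension would be the natural
  upgrade.
* PSI junction assignment relies on the annotation's splice sites; events
  expressed only through unannotated structures surface via the
  novel-junction route with its cruder ΔPSI-only rule.
* The GO module assumes a pre-propagated term map and performs no
  graph-aware correction.
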