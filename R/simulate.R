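#' Simulation configuration
#'
#' Defines the study conditions emulated by the spliced-read simulator: a
#' small multiexonic transcriptome sampled under two light treatments (a red
#' pulse, `Rp`, and a far-red pulse, `FRp`) with three biological replicates
#' each, negative-binomially overdispersed gene counts and
#' condition-dependent isoform ratios.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition (>= 2).
#' @param condition_labels Condition names; default `c("Rp", "FRp")`.
#' @param read_length Read length in nt (single-end, fixed length).
#' @param library_size Expected total reads per sample.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi * mu^2);
#'   0 gives Poisson counts.
#' @param frac_de_genes Fraction of genes with a true expression change.
#' @param de_fold_change True fold change of DE genes (applied up or down).
#' @param frac_ds_genes Fraction of genes carrying one AS event whose
#'   inclusion level shifts between conditions.
#' @param delta_inclusion True PSI/PIR shift of event genes, in percentage
#'   points (0 gives AS events with no condition effect, i.e. a splicing
#'   null).
#' @param event_classes AS event classes to draw from (default all four:
#'   IR, ES, Alt5SS, Alt3SS; a single class makes every event that class).
#' @param seed Integer RNG seed; all simulator output is a deterministic
#'   function of the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       n_replicates = 3,
                       condition_labels = c("Rp", "FRp"),
                       read_length = 100,
                       library_size = 50000,
                       nb_dispersion = 0.05,
                       frac_de_genes = 0.2,
                       de_fold_change = 3,
                       frac_ds_genes = 0.2,
                       delta_inclusion = 30,
                       event_classes = c("IR", "ES", "Alt5SS", "Alt3SS"),
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
              condition_labels = as.character(condition_labels),
              read_length = as.integer(read_length),
              library_size = as.numeric(library_size),
              nb_dispersion = as.numeric(nb_dispersion),
              frac_de_genes = as.numeric(frac_de_genes),
              de_fold_change = as.numeric(de_fold_change),
              frac_ds_genes = as.numeric(frac_ds_genes),
              delta_inclusion = as.numeric(delta_inclusion),
              event_classes = match.arg(event_classes,
                c("IR", "ES", "Alt5SS", "Alt3SS"), several.ok = TRUE),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 0, cfg$n_replicates >= 2,
            length(cfg$condition_labels) == 2,
            cfg$read_length > 0, cfg$library_size > 0, cfg$nb_dispersion >= 0,
            cfg$frac_de_genes >= 0, cfg$frac_de_genes <= 1,
            cfg$frac_ds_genes >= 0, cfg$frac_ds_genes <= 1,
            cfg$de_fold_change >= 1,
            cfg$delta_inclusion >= 0, cfg$delta_inclusion <= 100)
  class(cfg) <- "sim_config"
  cfg
}

#' Design table for a simulation
#'
#' @param config A [sim_config].
#' @return data.frame with columns `sample` and `condition`.
#' @export
sim_design <- function(config) {
  data.frame(
    sample = paste0(rep(config$condition_labels, each = config$n_replicates),
                    "_", seq_len(config$n_replicates)),
    condition = factor(rep(config$condition_labels, each = config$n_replicates),
                       levels = config$condition_labels),
    stringsAsFactors = FALSE)
}

# run `expr` under a local RNG state seeded from `seed` + `offset`
.with_seed <- function(seed, expr, offset = 0L) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed((seed + 1299709L * offset) %% .Machine$integer.max)
  expr
}

#' Generate a toy annotated transcriptome with known AS ground truth
#'
#' Each gene has 2-4 exons; a configured fraction of genes carries exactly
#' one AS event, realised as two transcripts (inclusion and exclusion
#' isoform) of one of the classes intron retention (IR), exon skipping (ES),
#' alternative 5' splice site (Alt5SS) or alternative 3' splice site
#' (Alt3SS). Gene loci do not overlap. Deterministic given the config seed.
#'
#' @param config A [sim_config].
#' @return list with `gms` (a [gene_model_set]) and `truth` (data.frame with
#'   one row per gene: true mean expression per condition at nominal library
#'   size, event class and genomic interval, true inclusion level per
#'   condition, `de` and `ds` flags).
#' @export
make_toy_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes == 0L) stop("n_genes = 0: empty annotation requested")
  .with_seed(config$seed, .make_toy_annotation_impl(config), offset = 1L)
}

.make_toy_annotation_impl <- function(config) {
  G <- config$n_genes
  n_ds <- round(config$frac_ds_genes * G)
  n_de <- round(config$frac_de_genes * G)
  # independent draws: DE and DS gene sets overlap at chance rates, like
  # the partial overlap seen between expression- and splicing-regulated sets
  is_ds <- seq_len(G) %in% sample.int(G, n_ds)
  is_de <- seq_len(G) %in% sample.int(G, n_de)
  classes <- config$event_classes
  ev_class <- ifelse(is_ds, sample(classes, G, replace = TRUE), NA_character_)

  cursor <- 1000L
  ex_rows <- vector("list", G)
  truth <- vector("list", G)
  alt_shift <- 30L
  for (g in seq_len(G)) {
    gid <- sprintf("g%04d", g)
    n_ex <- sample(2:4, 1L)
    if (!is.na(ev_class[g]) && ev_class[g] == "ES" && n_ex < 3L) n_ex <- 3L
    ex_len <- sample(100:300, n_ex, replace = TRUE)
    in_len <- sample(120:200, max(n_ex - 1L, 0L), replace = TRUE)
    starts <- integer(n_ex); ends <- integer(n_ex)
    p <- cursor
    for (i in seq_len(n_ex)) {
      starts[i] <- p; ends[i] <- p + ex_len[i] - 1L
      p <- ends[i] + (if (i < n_ex) in_len[i] else 0L) + 1L
    }
    strand <- sample(c("+", "-"), 1L)
    incl <- list(start = starts, end = ends)   # inclusion isoform
    excl <- NULL                               # exclusion isoform
    ev_start <- NA_integer_; ev_end <- NA_integer_
    if (!is.na(ev_class[g])) {
      cls <- ev_class[g]
      if (cls == "IR") {
        j <- sample(n_ex - 1L, 1L)
        # inclusion isoform retains intron j: exons j and j+1 merge
        incl <- list(start = starts[-(j + 1L)],
                     end = ends[-j])
        excl <- list(start = starts, end = ends)
        ev_start <- ends[j] + 1L; ev_end <- starts[j + 1L] - 1L
      } else if (cls == "ES") {
        # internal exon only (sample(2:2, 1) would draw from 1:2)
        j <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1L), 1L)
        excl <- list(start = starts[-j], end = ends[-j])
        ev_start <- starts[j]; ev_end <- ends[j]
      } else if (cls == "Alt5SS") {
        # alternative donor: extend the transcript-5' exon into the intron
        j <- sample(n_ex - 1L, 1L)
        if (strand == "+") {            # extend exon j rightwards
          long <- ends; long[j] <- ends[j] + alt_shift
          incl <- list(start = starts, end = long)
          ev_start <- ends[j] + 1L; ev_end <- ends[j] + alt_shift
        } else {                        # extend exon j+1 leftwards
          long <- starts; long[j + 1L] <- starts[j + 1L] - alt_shift
          incl <- list(start = long, end = ends)
          ev_start <- starts[j + 1L] - alt_shift; ev_end <- starts[j + 1L] - 1L
        }
        excl <- list(start = starts, end = ends)
      } else {                          # Alt3SS: alternative acceptor
        j <- sample(n_ex - 1L, 1L)
        if (strand == "+") {            # extend exon j+1 leftwards
          long <- starts; long[j + 1L] <- starts[j + 1L] - alt_shift
          incl <- list(start = long, end = ends)
          ev_start <- starts[j + 1L] - alt_shift; ev_end <- starts[j + 1L] - 1L
        } else {                        # extend exon j rightwards
          long <- ends; long[j] <- ends[j] + alt_shift
          incl <- list(start = starts, end = long)
          ev_start <- ends[j] + 1L; ev_end <- ends[j] + alt_shift
        }
        excl <- list(start = starts, end = ends)
      }
    }
    tx <- list(incl)
    tx_id <- paste0(gid, ".1")
    if (!is.null(excl)) { tx <- c(tx, list(excl)); tx_id <- c(tx_id, paste0(gid, ".2")) }
    ex_rows[[g]] <- do.call(rbind, lapply(seq_along(tx), function(k)
      data.frame(seqnames = "chr1", start = tx[[k]]$start, end = tx[[k]]$end,
                 strand = strand, gene_id = gid, transcript_id = tx_id[k])))
    truth[[g]] <- data.frame(gene_id = gid, strand = strand,
                             event_class = ev_class[g],
                             event_start = ev_start, event_end = ev_end,
                             de = is_de[g], ds = FALSE,
                             stringsAsFactors = FALSE)
    cursor <- p + 500L
  }
  ex <- do.call(rbind, ex_rows)
  truth <- do.call(rbind, truth)

  # expression: relative abundances, DE genes shifted in FRp
  w <- stats::rlnorm(G, meanlog = 0, sdlog = 0.6)
  mu1 <- w / sum(w) * config$library_size
  fc_dir <- sample(c(1, -1), G, replace = TRUE)
  mu2 <- mu1 * ifelse(truth$de, config$de_fold_change^fc_dir, 1)
  truth$mu_cond1 <- mu1
  truth$mu_cond2 <- mu2
  truth$true_log2fc <- log2(mu2 / mu1)

  # inclusion levels (percent of reads from the inclusion isoform)
  base <- 50
  shift_dir <- sample(c(1, -1), G, replace = TRUE)
  d <- config$delta_inclusion / 2
  truth$incl_cond1 <- ifelse(is.na(truth$event_class), NA,
                             pmin(100, pmax(0, base + shift_dir * d)))
  truth$incl_cond2 <- ifelse(is.na(truth$event_class), NA,
                             pmin(100, pmax(0, base - shift_dir * d)))
  # a gene is truly DS when it carries an event whose inclusion level shifts
  truth$ds <- !is.na(truth$event_class) & config$delta_inclusion > 0
  gr <- GenomicRanges::GRanges(ex$seqnames, IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand, gene_id = ex$gene_id,
                               transcript_id = ex$transcript_id)
  list(gms = gene_model_set(gr), truth = truth)
}

#' Simulate spliced single-end alignments for every sample
#'
#' Per sample, each gene's read count is drawn NB with mean proportional to
#' its true abundance (dispersion `nb_dispersion`; Poisson when 0). Each read
#' picks the inclusion isoform Bernoulli(inclusion level) and a uniform start
#' along the chosen transcript; reads crossing spliced-out introns get gapped
#' (M/N) CIGARs, reads inside a retained intron map contiguously. Genes whose
#' shortest transcript is shorter than the read length are rejected with a
#' diagnostic and dropped from sampling.
#'
#' @param gms A [gene_model_set] from [make_toy_annotation()] (or compatible).
#' @param truth Ground-truth table from [make_toy_annotation()].
#' @param config A [sim_config].
#' @return Named list (one element per sample) of data.frames with columns
#'   `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, coordinate-sorted.
#' @export
simulate_alignments <- function(gms, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(gms$genes$gene_id %in% truth$gene_id))
    stop("ground truth does not cover all genes")
  .with_seed(config$seed, .simulate_alignments_impl(gms, truth, config), offset = 2L)
}

.simulate_alignments_impl <- function(gms, truth, config) {
  design <- sim_design(config)
  truth <- truth[match(gms$genes$gene_id, truth$gene_id), ]
  txs <- .tx_structures(gms)

  # reject genes whose shortest transcript cannot hold one read
  tx_len <- vapply(txs, function(t) sum(t$width), numeric(1))
  min_len <- tapply(tx_len, vapply(txs, `[[`, character(1), "gene_id"), min)
  bad <- names(min_len)[min_len < config$read_length]
  if (length(bad) > 0)
    warning("rejecting ", length(bad),
            " gene(s) shorter than the read length: ",
            paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  keep <- !(truth$gene_id %in% bad)

  out <- vector("list", nrow(design))
  names(out) <- design$sample
  for (s in seq_len(nrow(design))) {
    cond <- as.integer(design$condition[s])
    mu <- if (cond == 1L) truth$mu_cond1 else truth$mu_cond2
    incl <- if (cond == 1L) truth$incl_cond1 else truth$incl_cond2
    mu <- mu * config$library_size / sum(truth$mu_cond1)  # nominal depth scale
    mu[!keep] <- 0
    n_reads <- if (config$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    else stats::rpois(length(mu), mu)
    out[[s]] <- .sample_reads(gms, truth, txs, n_reads, incl,
                              config$read_length, design$sample[s])
  }
  out
}

# exon structure per transcript in genomic order, with transcript-coordinate
# cumulative lengths (transcript coordinate runs along the genome; reads are
# unstranded so this is distributionally equivalent for uniform sampling)
.tx_structures <- function(gms) {
  mc <- S4Vectors::mcols(gms$exons)
  key <- paste0(mc$gene_id, "\r", mc$transcript_id)
  st <- split(GenomicRanges::start(gms$exons), key)
  en <- split(GenomicRanges::end(gms$exons), key)
  out <- mapply(function(s, e, k) {
    o <- order(s)
    s <- s[o]; e <- e[o]
    w <- e - s + 1L
    list(gene_id = sub("\r.*$", "", k), tx_id = sub("^.*\r", "", k),
         start = s, end = e, width = w,
         cum_end = cumsum(w), cum_start = cumsum(w) - w + 1L)
  }, st, en, names(st), SIMPLIFY = FALSE)
  names(out) <- sub("^.*\r", "", names(st))
  out
}

.sample_reads <- function(gms, truth, txs, n_reads, incl, read_length, sample_id) {
  gene_tx <- split(names(txs), vapply(txs, `[[`, character(1), "gene_id"))
  recs <- vector("list", sum(n_reads > 0) * 2L)
  ri <- 0L
  for (g in which(n_reads > 0)) {
    gid <- truth$gene_id[g]
    ids <- sort(gene_tx[[gid]])
    n <- n_reads[g]
    if (length(ids) == 2L && !is.na(incl[g])) {
      # reads sample molecules in proportion to molar fraction x length, so
      # junction-based PSI/PIR estimates converge to the inclusion level
      L1 <- sum(txs[[ids[1]]]$width) - read_length + 1L
      L2 <- sum(txs[[ids[2]]]$width) - read_length + 1L
      w1 <- incl[g] / 100 * max(L1, 0L)
      w2 <- (1 - incl[g] / 100) * max(L2, 0L)
      n_inc <- stats::rbinom(1L, n, w1 / (w1 + w2))
      alloc <- c(n_inc, n - n_inc)
    } else alloc <- c(n, rep(0L, length(ids) - 1L))
    for (k in seq_along(ids)) {
      if (alloc[k] == 0L) next
      tx <- txs[[ids[k]]]
      L <- sum(tx$width)
      if (L < read_length) next
      s <- sample.int(L - read_length + 1L, alloc[k], replace = TRUE)
      ri <- ri + 1L
      recs[[ri]] <- .reads_to_blocks(tx, s, read_length)
    }
  }
  if (ri == 0L)
    return(data.frame(qname = character(0), flag = integer(0), rname = character(0),
                      pos = integer(0), mapq = integer(0), cigar = character(0)))
  pos <- unlist(lapply(recs[seq_len(ri)], `[[`, "pos"), use.names = FALSE)
  cig <- unlist(lapply(recs[seq_len(ri)], `[[`, "cigar"), use.names = FALSE)
  o <- order(pos, cig)
  data.frame(qname = sprintf("%s_r%07d", sample_id, seq_along(pos)),
             flag = 0L, rname = "chr1", pos = pos[o], mapq = 255L,
             cigar = cig[o], stringsAsFactors = FALSE)
}

# map transcript-coordinate read starts to genomic positions + CIGARs
.reads_to_blocks <- function(tx, s, read_length) {
  e <- s + read_length - 1L
  i1 <- findInterval(s, tx$cum_start)
  i2 <- findInterval(e, tx$cum_start)
  pos <- tx$start[i1] + (s - tx$cum_start[i1])
  n_seg <- i2 - i1 + 1L
  cigar <- character(length(s))
  one <- n_seg == 1L
  cigar[one] <- paste0(read_length, "M")
  two <- n_seg == 2L
  if (any(two)) {                      # the common spanning case, vectorised
    w1 <- tx$cum_end[i1[two]] - s[two] + 1L
    w2 <- e[two] - tx$cum_start[i2[two]] + 1L
    gap <- tx$start[i2[two]] - tx$end[i1[two]] - 1L
    cigar[two] <- paste0(w1, "M", gap, "N", w2, "M")
  }
  rest <- which(n_seg > 2L)
  if (length(rest) > 0) {
    cigar[rest] <- vapply(rest, function(r) {
      segs <- i1[r]:i2[r]
      lo <- pmax(s[r], tx$cum_start[segs])
      hi <- pmin(e[r], tx$cum_end[segs])
      w <- hi - lo + 1L
      gaps <- tx$start[segs[-1L]] - tx$end[segs[-length(segs)]] - 1L
      paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
             w[length(w)], "M")
    }, character(1))
  }
  list(pos = pos, cigar = cigar)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: annotation + truth + per-sample alignments + design.
#'
#' @param config A [sim_config].
#' @return list with `gms`, `truth`, `alignments` (list of record tables),
#'   `design`.
#' @export
sim_dataset <- function(config) {
  ann <- make_toy_annotation(config)
  aln <- simulate_alignments(ann$gms, ann$truth, config)
  list(gms = ann$gms, truth = ann$truth, alignments = aln,
       design = sim_design(config))
}
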