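# Negative-binomial testing machinery for two-group count comparisons:
# trimmed-mean-of-M-values normalization, conditional-likelihood dispersion
# estimation (common, then shrunk tagwise), and an exact conditional test on
# depth-equalized counts. The same engine tests gene counts (library-size
# offsets) and bin counts (parent-gene offsets).

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per sample, a scaling factor computed from
#' log-ratios to a reference sample after trimming extreme log-ratios
#' (`logratio_trim`) and extreme average intensities (`sum_trim`), weighted
#' by inverse asymptotic variance. Factors are normalized to geometric mean
#' one; multiplying library sizes by them gives effective library sizes.
#'
#' @param counts Integer matrix, features x samples.
#' @param logratio_trim Two-sided trim fraction on M values (default 0.3).
#' @param sum_trim Two-sided trim fraction on A values (default 0.05).
#' @return Numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2L, function(x) stats::quantile(x[x > 0], 0.75))
  ref <- which.min(abs(uq / lib - mean(uq / lib)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    ok <- counts[, s] > 0 & counts[, ref] > 0
    y <- counts[ok, s] / lib[s]
    r <- counts[ok, ref] / lib[ref]
    M <- log2(y / r)
    A <- (log2(y) + log2(r)) / 2
    w <- (1 - counts[ok, s] / lib[s]) / counts[ok, s] +
         (1 - counts[ok, ref] / lib[ref]) / counts[ok, ref]
    keep <- M > stats::quantile(M, logratio_trim) &
            M < stats::quantile(M, 1 - logratio_trim) &
            A > stats::quantile(A, sum_trim) &
            A < stats::quantile(A, 1 - sum_trim)
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Scale each sample's counts to the geometric-mean effective depth, so the
# conditional test below can assume exchangeable samples.
.equalize <- function(counts, eff_lib) {
  target <- exp(mean(log(eff_lib)))
  sweep(counts, 2L, target / eff_lib, `*`)
}

# Conditional log-likelihood of equalized counts given their group sums, as
# a function of dispersion phi; rows = features. For iid NB(mu, 1/phi) the
# distribution of (y_1..y_n) given their sum does not depend on mu.
.cond_ll <- function(y, groups, phi) {
  r <- 1 / phi
  ll <- numeric(nrow(y))
  for (g in levels(groups)) {
    yg <- y[, groups == g, drop = FALSE]
    n <- ncol(yg)
    t <- rowSums(yg)
    ll <- ll + rowSums(lgamma(yg + r)) - n * lgamma(r) -
      rowSums(lgamma(yg + 1)) -
      (lgamma(t + n * r) - lgamma(n * r) - lgamma(t + 1))
  }
  ll
}

#' Estimate NB dispersions by conditional maximum likelihood
#'
#' A common dispersion maximizes the summed conditional log-likelihood over
#' all features; tagwise dispersions maximize each feature's conditional
#' likelihood plus `prior_n` times the average, shrinking noisy per-feature
#' estimates toward the common value.
#'
#' @param pseudo Depth-equalized count matrix (features x samples).
#' @param groups Factor of group membership per sample.
#' @param tagwise Return per-feature shrunk estimates (default) or the
#'   common value recycled.
#' @param prior_n Weight (in features) of the common likelihood in the
#'   tagwise objective.
#' @return Numeric vector of dispersions, one per feature.
#' @export
estimate_dispersion <- function(pseudo, groups, tagwise = TRUE, prior_n = 10) {
  groups <- droplevels(as.factor(groups))
  informative <- rowSums(pseudo) > 0
  if (!any(informative)) return(rep(1e-4, nrow(pseudo)))
  y <- pseudo[informative, , drop = FALSE]
  grid <- exp(seq(log(1e-6), log(4), length.out = 31))
  ll <- vapply(grid, function(phi) .cond_ll(y, groups, phi), numeric(nrow(y)))
  ll <- matrix(ll, nrow = nrow(y))
  total <- colSums(ll)
  common <- grid[which.max(total)]
  # refine the common estimate between neighbouring grid points
  i <- which.max(total)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  common <- stats::optimize(function(lphi)
    sum(.cond_ll(y, groups, exp(lphi))), c(log(lo), log(hi)),
    maximum = TRUE)$maximum
  common <- exp(common)
  out <- rep(common, nrow(pseudo))
  if (tagwise) {
    score <- ll + prior_n * matrix(total / nrow(y), nrow(y), length(grid),
                                   byrow = TRUE)
    out[informative] <- grid[max.col(score, ties.method = "first")]
  }
  out
}

#' Exact conditional NB test for a two-group comparison
#'
#' Group sums of depth-equalized counts are compared conditionally on their
#' total: for groups of n1 and n2 exchangeable NB samples with dispersion
#' phi, the first group's sum given the total follows a
#' beta-binomial-type distribution with sizes n1/phi and n2/phi that does
#' not depend on the mean. The two-sided p-value sums all outcomes with
#' probability not exceeding the observed one. As phi -> 0 this converges to
#' the conditional binomial test.
#'
#' @param pseudo Depth-equalized count matrix.
#' @param groups Two-level factor per sample.
#' @param dispersion Per-feature dispersions (recycled if length 1).
#' @param prior_count Prior added per group mean when computing log2 fold
#'   changes (default 0.5), keeping them finite at zero counts.
#' @return data.frame with `logFC` (log2 second level / first level) and
#'   `pvalue`; all-zero features get `logFC` 0 and `pvalue` 1.
#' @export
nb_exact_test <- function(pseudo, groups, dispersion, prior_count = 0.5) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2L)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  s1 <- round(rowSums(pseudo[, groups == levels(groups)[1], drop = FALSE]))
  s2 <- round(rowSums(pseudo[, groups == levels(groups)[2], drop = FALSE]))
  if (length(dispersion) == 1L) dispersion <- rep(dispersion, length(s1))
  pval <- vapply(seq_along(s1), function(i)
    .exact_cond_p(s1[i], s2[i], n1, n2, dispersion[i]), numeric(1))
  logFC <- log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  logFC[s1 + s2 == 0] <- 0
  data.frame(logFC = logFC, pvalue = pval)
}

.exact_cond_p <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  r1 <- n1 / phi; r2 <- n2 / phi
  y <- 0:t
  logp <- lgamma(y + r1) - lgamma(y + 1) - lgamma(r1) +
    lgamma(t - y + r2) - lgamma(t - y + 1) - lgamma(r2)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- p[s1 + 1]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Two-group NB differential test with normalization
#'
#' The full gene-level testing path: TMM (or no) normalization, depth
#' equalization, conditional-likelihood dispersion estimation (common +
#' tagwise shrinkage, unless a fixed dispersion is supplied), and the exact
#' conditional test per feature.
#'
#' @param counts Integer matrix, features x samples.
#' @param design data.frame with columns `sample` and `condition` matching
#'   the count columns.
#' @param norm_method `"TMM"` (default) or `"none"`.
#' @param dispersion Optional fixed dispersion overriding estimation.
#' @param tagwise Shrink dispersions tagwise (default TRUE).
#' @param prior_count Prior count per group for log fold changes.
#' @param lib_sizes Optional library sizes overriding the column sums
#'   (e.g. equal sizes for pre-normalized counts).
#' @return data.frame with `feature_id`, `logFC` (log2 of second condition
#'   over first), `pvalue`, `dispersion`.
#' @export
nb_test <- function(counts, design, norm_method = c("TMM", "none"),
                    dispersion = NULL, tagwise = TRUE, prior_count = 0.5,
                    lib_sizes = NULL) {
  norm_method <- match.arg(norm_method)
  stopifnot(identical(colnames(counts), design$sample))
  groups <- droplevels(as.factor(design$condition))
  stopifnot(nlevels(groups) == 2L, all(table(groups) >= 2L))
  lib <- if (is.null(lib_sizes)) colSums(counts)
         else rep(lib_sizes, length.out = ncol(counts))
  nf <- if (norm_method == "TMM") tmm_factors(counts) else rep(1, ncol(counts))
  pseudo <- .equalize(counts, lib * nf)
  disp <- if (is.null(dispersion))
    estimate_dispersion(pseudo, groups, tagwise = tagwise)
  else rep(dispersion, length.out = nrow(counts))
  res <- nb_exact_test(pseudo, groups, disp, prior_count = prior_count)
  data.frame(feature_id = rownames(counts), res, dispersion = disp,
             row.names = NULL, stringsAsFactors = FALSE)
}
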