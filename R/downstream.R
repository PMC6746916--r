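#' Splicing index from band intensities
#'
#' SI is the densitometric abundance of the longest splicing isoform
#' relative to the summed abundance of all isoforms of the gene, a value in
#' `[0, 1]`. Samples with zero total intensity are undefined (NA, with a
#' warning) and should be excluded downstream. SI is invariant to
#' rescaling all intensities of a sample by a positive constant.
#'
#' @param bands data.frame (or matrix) of non-negative isoform intensities,
#'   one row per sample, one column per isoform.
#' @param longest Column name or index of the longest isoform (default 1).
#' @return Numeric vector of SI values, one per row.
#' @export
compute_si <- function(bands, longest = 1L) {
  m <- as.matrix(bands)
  if (any(m < 0, na.rm = TRUE)) stop("band intensities must be >= 0")
  if (is.character(longest)) longest <- match(longest, colnames(m))
  tot <- rowSums(m)
  if (any(tot == 0))
    warning(sum(tot == 0), " sample(s) with zero total intensity excluded",
            call. = FALSE)
  ifelse(tot > 0, m[, longest] / tot, NA_real_)
}

#' Angular (arcsine-square-root) transform of a proportion
#'
#' The variance-stabilizing transform applied to germination percentages
#' before ANOVA: `arcsin(sqrt(p))`, in degrees by default.
#'
#' @param p Proportions in `[0, 1]`.
#' @param units `"degrees"` (default) or `"radians"`.
#' @return Transformed values (0 -> 0, 0.5 -> 45 degrees, 1 -> 90 degrees).
#' @export
angular_transform <- function(p, units = c("degrees", "radians")) {
  units <- match.arg(units)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  x <- asin(sqrt(p))
  if (units == "degrees") x * 180 / pi else x
}

#' Two-way ANOVA with Fisher's LSD post-test
#'
#' Fits `response ~ A * B` and reports Type II sums of squares, F and p for
#' both main effects and the interaction. When the interaction is
#' significant (p < `alpha`), all pairwise cell-mean comparisons are made by
#' Fisher's (unprotected) LSD on the pooled residual mean square, and a
#' compact letter display is built: two cells share a letter exactly when
#' their comparison p-value is >= `alpha`. With a zero residual and zero
#' effect sum of squares the F ratio is undefined; such effects are
#' reported with p = 1 (no evidence of an effect in a degenerate layout).
#'
#' @param data data.frame containing the response and both factors.
#' @param response,factor_a,factor_b Column names.
#' @param alpha Significance level gating the post-test (default 0.05).
#' @return list with `anova` (table incl. residuals), `interaction_p`,
#'   `lsd` (pairwise comparisons, or NULL), `letters` (cell means with
#'   letters, or NULL).
#' @export
two_way_anova <- function(data, response, factor_a, factor_b, alpha = 0.05) {
  df <- data.frame(y = data[[response]],
                   A = factor(data[[factor_a]]),
                   B = factor(data[[factor_b]]))
  if (any(table(df$A, df$B) < 2L))
    warning("cells with fewer than 2 replicates: LSD unavailable for them",
            call. = FALSE)
  fit <- stats::lm(y ~ A * B, data = df)
  if (stats::var(df$y) < .Machine$double.eps) {
    # constant response: every sum of squares is zero, nothing to test
    terms <- c("A", "B", "A:B", "Residuals")
    dfs <- c(nlevels(df$A) - 1L, nlevels(df$B) - 1L,
             (nlevels(df$A) - 1L) * (nlevels(df$B) - 1L),
             nrow(df) - nlevels(df$A) * nlevels(df$B))
    tab <- data.frame(term = terms, sum_sq = 0, df = dfs, F = NA_real_,
                      pvalue = c(1, 1, 1, NA), stringsAsFactors = FALSE)
    return(list(anova = tab, interaction_p = 1, lsd = NULL, letters = NULL))
  }
  a2 <- car::Anova(fit, type = 2)
  tab <- data.frame(term = rownames(a2), sum_sq = a2$`Sum Sq`, df = a2$Df,
                    F = a2$`F value`, pvalue = a2$`Pr(>F)`,
                    row.names = NULL, stringsAsFactors = FALSE)
  degenerate <- !is.na(tab$sum_sq) & tab$sum_sq < .Machine$double.eps^0.75
  tab$pvalue[degenerate] <- 1
  int_p <- tab$pvalue[tab$term == "A:B"]
  lsd <- NULL; letters <- NULL
  if (!is.na(int_p) && int_p < alpha) {
    mse <- a2["Residuals", "Sum Sq"] / a2["Residuals", "Df"]
    dfr <- a2["Residuals", "Df"]
    cells <- stats::aggregate(y ~ A + B, df, mean)
    nrep <- stats::aggregate(y ~ A + B, df, length)$y
    cells$cell <- paste(cells$A, cells$B, sep = ":")
    cmb <- utils::combn(nrow(cells), 2)
    pij <- apply(cmb, 2L, function(ij) {
      i <- ij[1]; j <- ij[2]
      if (nrep[i] < 2L || nrep[j] < 2L) return(NA_real_)
      se <- sqrt(mse * (1 / nrep[i] + 1 / nrep[j]))
      if (se == 0) return(if (cells$y[i] == cells$y[j]) 1 else 0)
      2 * stats::pt(-abs((cells$y[i] - cells$y[j]) / se), dfr)
    })
    lsd <- data.frame(cell1 = cells$cell[cmb[1, ]],
                      cell2 = cells$cell[cmb[2, ]], pvalue = pij,
                      stringsAsFactors = FALSE)
    letters <- data.frame(cell = cells$cell, mean = cells$y, n = nrep,
                          letters = .letter_display(cells$cell, cells$y,
                                                    lsd, alpha),
                          stringsAsFactors = FALSE)
  }
  list(anova = tab, interaction_p = int_p, lsd = lsd, letters = letters)
}

# Compact letter display: cells sorted by decreasing mean; maximal runs of
# mutually non-significant cells each get one letter.
.letter_display <- function(cell, mean, lsd, alpha) {
  o <- order(-mean)
  k <- length(cell)
  ns <- matrix(TRUE, k, k, dimnames = list(cell, cell))
  for (r in seq_len(nrow(lsd))) {
    sig <- !is.na(lsd$pvalue[r]) && lsd$pvalue[r] < alpha
    ns[lsd$cell1[r], lsd$cell2[r]] <- !sig
    ns[lsd$cell2[r], lsd$cell1[r]] <- !sig
  }
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(ns[o[i:(j + 1)], o[i:(j + 1)]])) j <- j + 1
    grp <- o[i:j]
    covered <- any(vapply(groups, function(g) all(grp %in% g), logical(1)))
    if (!covered) groups[[length(groups) + 1L]] <- grp
  }
  lab <- rep("", k)
  for (gi in seq_along(groups))
    lab[groups[[gi]]] <- paste0(lab[groups[[gi]]], letters[gi])
  lab
}
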