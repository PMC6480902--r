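#' Global TE derepression test within one strain
#'
#' Paired t-test of per-family mean expression, young vs old, on the
#' log2(RPKM + offset) scale. A significant positive shift would indicate
#' global derepression of transposable elements with age; the degenerate
#' all-tied case (zero variance of differences) is reported as t = 0, p = 1.
#'
#' @param summary `expression_summary` restricted to TE families (or any
#'   feature set; the test only uses the young/old cell means).
#' @param strain Strain label.
#' @param offset Pseudo-RPKM for the log transform.
#' @param log_scale If FALSE, pairs raw RPKM means instead.
#' @return List with `t`, `df`, `p`, `mean_log2_shift` (old minus young),
#'   `n_families`.
#' @export
te_global_test <- function(summary, strain, offset = 0.5, log_scale = TRUE) {
  sub <- summary[summary$strain == strain, , drop = FALSE]
  if (nrow(sub) < 3) stop("need >= 3 TE families")
  if (log_scale) {
    young <- log2(sub$mean_young + offset)
    old <- log2(sub$mean_old + offset)
  } else {
    young <- sub$mean_young
    old <- sub$mean_old
  }
  d <- old - young
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1, p = 1,
                mean_log2_shift = mean(d), n_families = length(d)))
  }
  tt <- stats::t.test(old, young, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_log2_shift = mean(d), n_families = length(d))
}

#' Family-level TE differential-expression summary
#'
#' Runs the same negative-binomial age and strain-by-age machinery as genes
#' ([test_age()]) on the TE-family rows of the count matrix and attaches the
#' per-strain fold differences and aging direction from the expression
#' summary. There is no TE-specific statistical code path.
#'
#' @param counts `count_matrix` whose `kind` attribute marks `te_family`
#'   rows (or a matrix already restricted to TE families).
#' @param design Sample design data.frame.
#' @param annotation `feature_annotation` with family lengths (for RPKM).
#' @param fdr FDR threshold.
#' @param offset Pseudo-RPKM.
#' @return data.frame: family, per-strain fold difference (offset-free RPKM
#'   ratio, old/young orientation chosen by direction), direction,
#'   padj_age, padj_interaction, significant.
#' @export
te_family_tests <- function(counts, design, annotation, fdr = 0.05,
                            offset = 0.5) {
  kinds <- attr(counts, "kind")
  te <- if (!is.null(kinds) && any(kinds == "te_family")) {
    count_matrix(counts[kinds == "te_family", , drop = FALSE])
  } else counts
  if (nrow(te) < 2) stop("need >= 2 TE families")
  de <- test_age(te, design, fdr = fdr)
  r <- rpkm(count_matrix(te), annotation)
  summ <- summarize_expression(r, design, offset = offset)
  strains <- sort(unique(design$strain))
  out <- data.frame(family = de$feature, stringsAsFactors = FALSE)
  for (s in strains) {
    sub <- summ[summ$strain == s, ]
    idx <- match(de$feature, sub$feature)
    # Table-4-style fold: ratio of strain-level mean RPKMs, >= 1, direction
    # carried separately
    fold <- pmax(sub$mean_old[idx], .Machine$double.eps) /
      pmax(sub$mean_young[idx], .Machine$double.eps)
    out[[paste0("fold_", s)]] <- ifelse(fold >= 1, fold, 1 / fold)
    out[[paste0("direction_", s)]] <- sub$direction[idx]
  }
  out$padj_age <- de$padj_age
  out$padj_interaction <- de$padj_interaction
  out$significant <- de$significant
  out
}

#' Cross-strain correlation of TE aging ratios
#'
#' [cross_strain_correlation()] restricted to TE families: Pearson r between
#' the two strains' per-family log2 old/young ratios.
#'
#' @param summary `expression_summary` over TE families.
#' @return List with `r`, `p`, `n`.
#' @export
te_cross_strain_correlation <- function(summary) {
  cross_strain_correlation(summary)
}
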