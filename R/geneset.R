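#' Build an expression-matched control table for a focal gene set
#'
#' Features are ranked by overall mean expression (the mean of the per-strain
#' young and old cell means, pooling strains and ages so the age contrast
#' does not leak into the null). Each focal gene is matched to the `k_up`
#' nearest-ranked non-focal genes above it and the `k_down` nearest below it
#' (defaults 10 + 10, i.e. the 20 most similarly expressed genes). At rank
#' extremes the deficit is filled from the other side so every focal gene
#' keeps `k_up + k_down` matches. Focal-set members are never used as
#' matches.
#'
#' @param summary `expression_summary` from [summarize_expression()].
#' @param focal Character vector of focal feature ids (all present in
#'   `summary`).
#' @param k_up,k_down Number of matches ranked above / below each focal gene.
#' @return Named list (one element per focal gene) of match id vectors, with
#'   attribute `expression` (the ranking statistic).
#' @export
build_match_table <- function(summary, focal, k_up = 10, k_down = 10) {
  expr <- overall_expression(summary)
  if (!all(focal %in% names(expr)))
    stop("focal gene(s) absent from summary: ",
         paste(utils::head(setdiff(focal, names(expr)), 3), collapse = ", "))
  k <- k_up + k_down
  cand <- setdiff(names(expr), focal)
  if (length(cand) < k)
    stop("need >= ", k, " non-focal features to match against")
  ord <- order(expr[cand])        # stable; ties keep input order
  cand_sorted <- cand[ord]
  cand_expr <- expr[cand_sorted]
  matches <- lapply(focal, function(g) {
    # number of candidates ranked strictly below the focal gene
    pos <- sum(cand_expr < expr[[g]])
    below <- min(k_down, pos)
    above <- min(k_up, length(cand) - pos)
    # fill deficits from the opposite side
    if (below + above < k) {
      below <- min(pos, k - above)
      above <- min(length(cand) - pos, k - below)
    }
    c(if (below > 0) cand_sorted[seq(pos, by = -1, length.out = below)],
      if (above > 0) cand_sorted[seq(pos + 1, length.out = above)])
  })
  names(matches) <- focal
  attr(matches, "expression") <- expr
  matches
}

# ranking statistic for matching: mean over strain x age cell means
overall_expression <- function(summary) {
  feats <- unique(summary$feature)
  tot <- tapply(summary$mean_young + summary$mean_old, summary$feature, mean) / 2
  stats::setNames(as.numeric(tot[feats]), feats)
}

#' Expression-matched permutation test for a coordinated gene-set shift
#'
#' The observed statistic is, per strain, the mean log2 old/young ratio over
#' the focal genes. Each permutation replicate swaps every focal gene for one
#' of its expression-matched controls (drawn uniformly and independently per
#' gene; a control may serve several focal genes within a replicate) and
#' recomputes the per-strain means. A replicate counts as an exceedance when
#' its mean is greater than or equal to the observed mean in every strain
#' simultaneously. The reported p is the add-one estimator
#' `(exceedances + 1) / (n_perm + 1)`, which can never be exactly 0; the raw
#' proportion is also returned.
#'
#' @param summary `expression_summary`.
#' @param matches Match table from [build_match_table()].
#' @param focal Character vector of focal feature ids.
#' @param n_perm Number of permutation replicates (values below 100 warn).
#' @param seed Integer seed making the replicate draws reproducible.
#' @param unique_within If TRUE, controls are drawn without replacement
#'   within a replicate (non-default variant).
#' @param criterion `"joint"` (default) scores a replicate as an exceedance
#'   when it reaches the observed mean in every strain simultaneously;
#'   `"min"` compares the scalar minimum-over-strains mean of the replicate
#'   against the observed minimum. The joint rule mirrors the published
#'   procedure but its p is not uniform under a strain-independent null
#'   (it behaves like a product of per-strain uniforms); the min rule is a
#'   calibrated scalar alternative.
#' @return A `set_test_result` list: observed (named per-strain means),
#'   n_perm, exceedances, p (add-one), p_raw, null_quantiles (2.5/50/97.5%
#'   of the per-replicate minimum over strains), seed, criterion.
#' @export
matched_permutation_test <- function(summary, matches, focal,
                                     n_perm = 10000, seed = NULL,
                                     unique_within = FALSE,
                                     criterion = c("joint", "min")) {
  criterion <- match.arg(criterion)
  if (length(focal) == 0) stop("focal set is empty")
  if (!all(focal %in% names(matches))) stop("matches missing for focal gene(s)")
  if (any(lengths(matches[focal]) < 1)) stop("every focal gene needs >= 1 match")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  ratios <- summary_ratio_matrix(summary)
  strains <- colnames(ratios)
  obs <- colMeans(ratios[focal, , drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  nf <- length(focal)
  # per-replicate per-strain mean over one sampled control per focal gene
  null_means <- matrix(0, n_perm, length(strains),
                       dimnames = list(NULL, strains))
  if (unique_within) {
    pool <- unique(unlist(matches[focal]))
    for (b in seq_len(n_perm)) {
      picked <- character(nf); used <- character(0)
      for (j in seq_len(nf)) {
        avail <- setdiff(matches[[focal[j]]], used)
        if (!length(avail)) avail <- matches[[focal[j]]]
        picked[j] <- avail[sample.int(length(avail), 1)]
        used <- c(used, picked[j])
      }
      null_means[b, ] <- colMeans(ratios[picked, , drop = FALSE])
    }
  } else {
    acc <- matrix(0, n_perm, length(strains))
    for (j in seq_len(nf)) {
      mj <- matches[[focal[j]]]
      idx <- sample.int(length(mj), n_perm, replace = TRUE)
      acc <- acc + ratios[mj[idx], , drop = FALSE]
    }
    null_means[] <- acc / nf
  }
  exceed <- if (criterion == "joint") {
    sum(apply(sweep(null_means, 2, obs, ">="), 1, all))
  } else {
    sum(apply(null_means, 1, min) >= min(obs))
  }
  res <- list(
    observed = obs,
    n_perm = n_perm,
    exceedances = exceed,
    p = (exceed + 1) / (n_perm + 1),
    p_raw = exceed / n_perm,
    null_quantiles = stats::quantile(apply(null_means, 1, min),
                                     c(0.025, 0.5, 0.975)),
    seed = seed, criterion = criterion)
  class(res) <- "set_test_result"
  res
}

#' @exportS3Method base::print
print.set_test_result <- function(x, ...) {
  cat("Expression-matched permutation test\n")
  cat("  observed per-strain mean log2 ratio:\n")
  print(round(x$observed, 4))
  cat(sprintf("  exceedances: %d / %d permutations\n", x$exceedances, x$n_perm))
  cat(sprintf("  p (add-one) = %.4g   p (raw) = %.4g\n", x$p, x$p_raw))
  invisible(x)
}

#' Count aging directions within a gene set
#'
#' Per strain, and pooled (sign of the across-strain mean log2 ratio), the
#' number of set members going up, down, or flat with age.
#'
#' @param summary `expression_summary`.
#' @param set Character vector of member feature ids.
#' @return data.frame with rows per strain plus "pooled" and columns
#'   n_up, n_down, n_flat.
#' @export
direction_count <- function(summary, set) {
  if (!length(set)) stop("gene set is empty")
  ratios <- summary_ratio_matrix(summary)
  set <- intersect(set, rownames(ratios))
  if (!length(set)) stop("no set member present in summary")
  m <- ratios[set, , drop = FALSE]
  count_one <- function(v) {
    d <- ratio_direction(v)
    c(n_up = sum(d == "up"), n_down = sum(d == "down"), n_flat = sum(d == "flat"))
  }
  rows <- rbind(t(apply(m, 2, count_one)), pooled = count_one(rowMeans(m)))
  data.frame(group = rownames(rows), rows, row.names = NULL)
}

#' Exact two-sided sign test for a directional gene set
#'
#' Binomial test of `n_down` successes in `n_total` trials at p0 = 0.5,
#' two-sided as twice the smaller tail, capped at 1. Flat (tied) members
#' must be excluded by the caller.
#'
#' @param n_down Number of members moving down (or up; the test is symmetric).
#' @param n_total Number of non-flat members.
#' @return Two-sided p-value.
#' @export
sign_test <- function(n_down, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_down < 0 || n_down > n_total) stop("n_down must lie in [0, n_total]")
  lower <- stats::pbinom(n_down, n_total, 0.5)
  # upper tail via the p0 = 1/2 symmetry, avoiding 1 - pbinom() cancellation
  upper <- stats::pbinom(n_total - n_down, n_total, 0.5)
  min(1, 2 * min(lower, upper))
}

#' Enrichment of a gene set in the top significance decile
#'
#' Tested features are ranked by FDR-adjusted age p (ties by raw p, then by
#' stable input order); the top `ceiling(top_fraction * n)` features are
#' crossed with set membership in a 2x2 table tested by [yates_chi2()].
#'
#' @param de `de_result` from [test_age()] with >= 10 tested features.
#' @param set Character vector of member ids.
#' @param top_fraction Fraction of the ranked list called "top" (default
#'   0.10, the top decile). Must be in (0, 1).
#' @return List with `table` (2x2: top/rest x in-set/out), `chi2`, `df`, `p`.
#' @export
topk_enrichment <- function(de, set, top_fraction = 0.10) {
  tested <- de[!is.na(de$p_age), , drop = FALSE]
  if (nrow(tested) < 10) stop("need >= 10 tested features")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie strictly between 0 and 1")
  if (!any(set %in% tested$feature))
    stop("gene set is disjoint from tested features")
  ord <- order(tested$padj_age, tested$p_age)
  m <- ceiling(top_fraction * nrow(tested))
  top <- tested$feature[ord[seq_len(m)]]
  in_top <- tested$feature %in% top
  in_set <- tested$feature %in% set
  tab <- matrix(c(sum(in_top & in_set), sum(in_top & !in_set),
                  sum(!in_top & in_set), sum(!in_top & !in_set)),
                2, 2, byrow = TRUE,
                dimnames = list(c("top", "rest"), c("in_set", "out")))
  c(list(table = tab), yates_chi2(tab))
}
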