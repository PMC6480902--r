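#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count / (length_kb * total_sample_counts / 1e6)`. The per-sample total is
#' the column sum over all features in the matrix (genes, TE families and
#' mitochondrial features alike).
#'
#' @param counts `count_matrix` (features x samples).
#' @param annotation `feature_annotation` carrying a `length` (bp) for every
#'   feature in `counts`.
#' @return Numeric matrix of RPKM values, same dimnames as `counts`.
#' @export
rpkm <- function(counts, annotation) {
  idx <- match(rownames(counts), annotation$feature)
  if (anyNA(idx))
    stop("annotation lacks length for ",
         sum(is.na(idx)), " feature(s), e.g. ",
         rownames(counts)[which(is.na(idx))[1]])
  len_kb <- annotation$length[idx] / 1000
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample(s) with zero total counts")
  sweep(unclass(counts) / len_kb, 2, totals / 1e6, "/")
}

#' Summarize expression per strain as old/young aging ratios
#'
#' Replicates are averaged on the RPKM scale within each strain x age cell,
#' then the strain-level aging signature is
#' `log2((mean_old + offset) / (mean_young + offset))`. The offset (default
#' 0.5) keeps the ratio finite at zero expression.
#'
#' @param rpkm_mat RPKM matrix from [rpkm()].
#' @param design Sample design data.frame (sample, strain, age, replicate).
#' @param offset Pseudo-RPKM added to both means before the log ratio.
#' @return An `expression_summary` data.frame: feature, strain, mean_young,
#'   mean_old, log2_ratio, fold (offset-free mean_old/mean_young ratio, NA
#'   when mean_young is 0), direction (up/down/flat).
#' @export
summarize_expression <- function(rpkm_mat, design, offset = 0.5) {
  design <- validate_design(design)
  if (!setequal(design$sample, colnames(rpkm_mat)))
    stop("design samples do not match expression matrix columns")
  if (offset <= 0 && any(rpkm_mat == 0))
    stop("offset must be > 0 when zero expression values are present")
  out <- list()
  for (s in unique(design$strain)) {
    ys <- design$sample[design$strain == s & design$age == "young"]
    os <- design$sample[design$strain == s & design$age == "old"]
    if (!length(ys) || !length(os))
      stop("strain ", s, " is missing a young or old cell")
    my <- rowMeans(rpkm_mat[, ys, drop = FALSE])
    mo <- rowMeans(rpkm_mat[, os, drop = FALSE])
    lr <- log2((mo + offset) / (my + offset))
    out[[s]] <- data.frame(
      feature = rownames(rpkm_mat), strain = s,
      mean_young = my, mean_old = mo,
      log2_ratio = lr,
      fold = ifelse(my > 0, mo / my, NA_real_),
      direction = ratio_direction(lr),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "offset") <- offset
  class(res) <- c("expression_summary", "data.frame")
  res
}

# exact-tie guard: |log2 ratio| below tol counts as flat
ratio_direction <- function(lr, tol = 1e-9) {
  ifelse(abs(lr) < tol, "flat", ifelse(lr > 0, "up", "down"))
}

# expression_summary in wide per-strain form: one row per feature,
# one log2_ratio column per strain
summary_ratio_matrix <- function(summary) {
  strains <- unique(summary$strain)
  feats <- unique(summary$feature)
  m <- sapply(strains, function(s) {
    sub <- summary[summary$strain == s, ]
    sub$log2_ratio[match(feats, sub$feature)]
  })
  rownames(m) <- feats
  m
}

#' Cross-strain correlation of aging ratios
#'
#' Pearson correlation between the two strains' per-feature log2 old/young
#' ratios, with the two-sided p from the t distribution on n-2 df.
#'
#' @param summary `expression_summary` covering exactly two strains.
#' @param features Optional feature subset (e.g. the DE set).
#' @return List with `r`, `p`, `n`.
#' @export
cross_strain_correlation <- function(summary, features = NULL) {
  m <- summary_ratio_matrix(summary)
  if (ncol(m) != 2) stop("cross-strain correlation needs exactly 2 strains")
  if (!is.null(features)) m <- m[rownames(m) %in% features, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("need >= 3 features with ratios in both strains")
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0)
    stop("zero variance in a strain's ratio vector")
  ct <- stats::cor.test(m[, 1], m[, 2], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Verify oogenic stage by correlation against reference profiles
#'
#' Correlates a sample's expression against each stage's reference profile
#' over the shared marker-gene panel, on the log2(RPKM + offset) scale, and
#' assigns the best-correlated stage. Ties are broken by stage order with a
#' warning; a maximum correlation below `min_r` flags the call as
#' low-confidence.
#'
#' @param expr Named numeric vector of the sample's RPKM over (at least) the
#'   panel genes.
#' @param profiles Named list or data.frame of per-stage reference RPKM
#'   vectors over the panel (names = stage labels); or a matrix with panel
#'   genes as rownames and stages as columns.
#' @param offset Pseudo-RPKM for the log transform.
#' @param min_r Confidence threshold on the winning correlation.
#' @return List with `stage`, `r` (named per-stage correlations),
#'   `confident` (logical).
#' @export
verify_stage <- function(expr, profiles, offset = 0.5, min_r = 0.3) {
  pm <- as.matrix(as.data.frame(profiles))
  shared <- intersect(names(expr), rownames(pm))
  if (length(shared) < 3) stop("need >= 3 shared panel genes")
  x <- log2(expr[shared] + offset)
  rs <- apply(log2(pm[shared, , drop = FALSE] + offset), 2,
              function(p) stats::cor(x, p))
  best <- which(rs == max(rs))
  if (length(best) > 1)
    warning("stage correlation tie; keeping first stage in profile order")
  list(stage = colnames(pm)[best[1]], r = rs,
       confident = max(rs) >= min_r)
}
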