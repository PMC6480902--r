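#' Median-of-ratios size factors
#'
#' DESeq-style robust library-size estimate: for each sample, the median over
#' features with all-positive counts of the ratio to the feature's geometric
#' mean across samples.
#'
#' @param counts `count_matrix` or integer matrix.
#' @return Named numeric vector of size factors (geometric mean 1 when all
#'   medians are positive).
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no feature has positive counts in every sample")
  logg <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logg))
  })
  sf / exp(mean(log(sf)))
}

#' Per-feature negative-binomial dispersion estimates
#'
#' Method-of-moments dispersion on size-factor-normalized counts under the
#' Var = mu + alpha * mu^2 parameterization, estimated within strain x age
#' cells and pooled, then shrunk toward a fitted mean-dispersion trend
#' alpha(mu) = a0 + a1/mu (the weighted midpoint between the gene-wise value
#' and the trend; `trend_weight` = 1 uses the trend alone). Degenerate
#' features get the floor.
#'
#' @param counts `count_matrix`.
#' @param design Sample design data.frame.
#' @param trend_weight Weight on the trend in the shrunk estimate, in [0,1].
#' @param floor Lower bound on the returned dispersion.
#' @return Named numeric vector of dispersions, one per feature.
#' @export
estimate_dispersion <- function(counts, design, trend_weight = 0.5,
                                floor = 1e-8) {
  design <- validate_design(design, counts)
  sf <- size_factors(counts)
  nc <- sweep(unclass(counts), 2, sf, "/")
  cell <- interaction(design$strain, design$age, drop = TRUE)
  num <- 0; den <- 0
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    mu <- rowMeans(nc[, idx, drop = FALSE])
    v <- apply(nc[, idx, drop = FALSE], 1, stats::var)
    w <- length(idx) - 1
    num <- num + w * (v - mu)
    den <- den + w * mu^2
  }
  raw <- ifelse(den > 0, num / den, 0)
  mu_all <- rowMeans(nc)
  # trend on informative genes only; coefficients clamped nonnegative
  use <- mu_all > 1 & is.finite(raw)
  a <- c(0, 0)
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu_all[use]))
    a <- pmax(unname(stats::coef(fit)), 0)
  }
  trend <- a[1] + a[2] / pmax(mu_all, 1e-8)
  shrunk <- (1 - trend_weight) * pmax(raw, 0) + trend_weight * trend
  out <- pmax(shrunk, floor)
  names(out) <- rownames(counts)
  attr(out, "trend_coef") <- a
  out
}

# single NB GLM fit via glm.fit; returns coefficients, covariance, converged
nb_wald_fit <- function(y, X, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = list(maxit = 50)))
  if (!fit$converged || any(!is.finite(fit$coefficients)))
    return(NULL)
  w <- fit$weights
  xtwx <- crossprod(X, X * w)
  cov <- tryCatch(solve(xtwx), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(beta = fit$coefficients, cov = cov)
}

#' Negative-binomial Wald tests for age, strain and strain-by-age effects
#'
#' Per feature, fits the log-linear model
#' `log mu = beta0 + beta_strain + beta_age` (reduced) and the same model
#' plus `beta_strain:age` (full), with `log(size factor)` offsets and the
#' supplied fixed dispersions. The age test is the Wald test on `beta_age`
#' in the reduced model (age while controlling for strain); the interaction
#' test is the Wald test on the interaction coefficient in the full model.
#' Raw p-values are BH-adjusted via [bh_adjust()]; non-convergent features
#' get NA p-values and are excluded from the FDR denominator. Features with
#' zero counts in every sample are dropped before testing.
#'
#' @param counts `count_matrix`.
#' @param design Sample design data.frame (two strains, two ages).
#' @param dispersions Optional named dispersion vector; estimated via
#'   [estimate_dispersion()] when missing.
#' @param fdr Significance threshold on the adjusted age p-value.
#' @return A `de_result` data.frame: feature, log2fc_age (pooled, from the
#'   reduced model), per-strain log2fc columns, se_log2fc, p_age,
#'   p_interaction, padj_age, padj_interaction, significant, converged.
#' @export
test_age <- function(counts, design, dispersions = NULL, fdr = 0.05) {
  design <- validate_design(design, counts)
  if (length(unique(design$strain)) != 2)
    stop("test_age expects exactly 2 strains")
  keep <- rowSums(unclass(counts)) > 0
  counts_t <- counts[keep, , drop = FALSE]
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(count_matrix(counts_t), design)
  } else {
    dispersions <- dispersions[rownames(counts_t)]
    if (anyNA(dispersions)) stop("dispersions missing for tested features")
  }
  sf <- size_factors(counts_t)
  off <- log(sf)
  strains <- sort(unique(design$strain))
  s2 <- as.integer(design$strain == strains[2])
  aold <- as.integer(design$age == "old")
  Xr <- cbind(1, s2, aold)
  Xf <- cbind(1, s2, aold, s2 * aold)
  n <- nrow(counts_t)
  lfc <- se <- p_age <- p_int <- lfc_s1 <- lfc_s2 <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- counts_t[i, ]
    fr <- nb_wald_fit(y, Xr, off, dispersions[i])
    ff <- nb_wald_fit(y, Xf, off, dispersions[i])
    if (is.null(fr) || is.null(ff)) next
    conv[i] <- TRUE
    b <- fr$beta[3]; s <- sqrt(fr$cov[3, 3])
    lfc[i] <- b / log(2); se[i] <- s / log(2)
    p_age[i] <- 2 * stats::pnorm(-abs(b / s))
    bi <- ff$beta[4]; si <- sqrt(ff$cov[4, 4])
    p_int[i] <- 2 * stats::pnorm(-abs(bi / si))
    lfc_s1[i] <- ff$beta[3] / log(2)
    lfc_s2[i] <- (ff$beta[3] + ff$beta[4]) / log(2)
  }
  padj_age <- bh_adjust(p_age)
  padj_int <- bh_adjust(p_int)
  res <- data.frame(
    feature = rownames(counts_t),
    log2fc_age = lfc, se_log2fc = se,
    lfc_s1, lfc_s2,
    p_age = p_age, p_interaction = p_int,
    padj_age = padj_age, padj_interaction = padj_int,
    significant = !is.na(padj_age) & padj_age < fdr,
    converged = conv,
    stringsAsFactors = FALSE)
  names(res)[names(res) == "lfc_s1"] <- paste0("log2fc_", strains[1])
  names(res)[names(res) == "lfc_s2"] <- paste0("log2fc_", strains[2])
  attr(res, "fdr") <- fdr
  attr(res, "strains") <- strains
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; NA p-values pass through
#' and are excluded from the number of tests m.
#'
#' @param p Numeric vector of p-values in [0,1], NA allowed.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
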