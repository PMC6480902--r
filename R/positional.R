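#' Flag genes overlapping chromatin domains
#'
#' A gene is flagged when its body overlaps any domain interval by at least
#' one base (after both are expressed in the same 1-based inclusive
#' convention; a BED domain abutting the gene end-to-start does not count).
#' An optional promoter window extends each gene upstream before testing
#' (non-default).
#'
#' @param annotation `feature_annotation` with chrom/start/end (1-based
#'   inclusive).
#' @param domains `GRanges` of domain intervals (e.g. from [read_bed()]).
#' @param promoter_bp Upstream extension in bp (default 0 = gene body only).
#' @return Named logical vector, one entry per annotation row. Chromosome
#'   names present in the annotation but absent from the domain file trigger
#'   a warning with the affected gene count.
#' @export
flag_compartment <- function(annotation, domains, promoter_bp = 0) {
  st <- annotation$start
  en <- annotation$end
  if (promoter_bp > 0) {
    minus <- annotation$strand == "-"
    st <- ifelse(minus, st, pmax(1, st - promoter_bp))
    en <- ifelse(minus, en + promoter_bp, en)
  }
  genes <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(st, en))
  missing_chr <- setdiff(unique(annotation$chrom),
                         as.character(GenomeInfoDb::seqlevels(domains)))
  if (length(missing_chr)) {
    n_aff <- sum(annotation$chrom %in% missing_chr)
    warning(n_aff, " gene(s) on chromosome(s) absent from the domain file: ",
            paste(missing_chr, collapse = ", "))
  }
  # seqlevel-mismatch chatter is covered by the explicit warning above
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(genes, domains, minoverlap = 1))
  out <- rep(FALSE, nrow(annotation))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  names(out) <- annotation$feature
  out
}

#' Yates-corrected chi-squared test on a 2x2 table
#'
#' chi2 = sum over cells of (max(|O - E| - 0.5, 0))^2 / E with expectations
#' from the margins; the continuity correction is truncated at zero so a
#' perfectly proportional table scores exactly 0. p is the upper tail of
#' chi-squared with 1 df (the usual two-tailed reading of the 2x2 test).
#'
#' @param t 2x2 numeric matrix or a length-4 vector (a, b, c, d by row).
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
yates_chi2 <- function(t) {
  m <- matrix(as.numeric(t), 2, 2, byrow = is.null(dim(t)))
  if (any(m < 0)) stop("counts must be nonnegative")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  E <- outer(rs, cs) / n
  chi2 <- sum(pmax(abs(m - E) - 0.5, 0)^2 / E)
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cross-classify DE significance with a compartment flag
#'
#' Builds the 2x2 contingency table (rows: FDR-significant / not; columns:
#' in-compartment / not) over tested features.
#'
#' @param de `de_result` from [test_age()].
#' @param flags Named logical vector from [flag_compartment()] covering all
#'   tested features.
#' @return 2x2 integer matrix with informative dimnames.
#' @export
build_de_compartment_table <- function(de, flags) {
  tested <- de[!is.na(de$padj_age), , drop = FALSE]
  if (!all(tested$feature %in% names(flags)))
    stop("flags missing for tested feature(s)")
  f <- flags[tested$feature]
  sig <- tested$significant
  matrix(c(sum(sig & f), sum(sig & !f),
           sum(!sig & f), sum(!sig & !f)),
         2, 2, byrow = TRUE,
         dimnames = list(c("significant", "not_significant"),
                         c("in_compartment", "out")))
}

#' Heterochromatin expression-shift test
#'
#' Welch two-sample t-test comparing the log2 old/young aging ratios of
#' in-compartment genes against the rest of the genome, within one strain.
#' A mean difference of 0 means compartment genes age like everything else.
#'
#' @param summary `expression_summary`.
#' @param flags Named logical compartment membership per feature.
#' @param strain Strain label to test.
#' @return List with `t`, `df`, `p`, `mean_difference` (in-compartment minus
#'   rest), `n_in`, `n_out`.
#' @export
compartment_shift_test <- function(summary, flags, strain) {
  sub <- summary[summary$strain == strain, , drop = FALSE]
  if (!nrow(sub)) stop("unknown strain: ", strain)
  if (!all(sub$feature %in% names(flags)))
    stop("flags missing for feature(s) in summary")
  f <- flags[sub$feature]
  x <- sub$log2_ratio[f]
  y <- sub$log2_ratio[!f]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 genes per group")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_difference = mean(x) - mean(y),
       n_in = length(x), n_out = length(y))
}
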