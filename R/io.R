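#' Read a count matrix from TSV or MatrixMarket files
#'
#' Counts are features x samples. The TSV dialect has a header row of sample
#' ids and feature ids in the first column. The MatrixMarket dialect is a
#' `.mtx` triplet file accompanied by plain-text row (feature) and column
#' (sample) id files, one id per line.
#'
#' @param path Path to the TSV file, or to the `.mtx` file when `rows` and
#'   `cols` are given.
#' @param kind_map Optional named character vector mapping feature ids to a
#'   feature kind (`"gene"`, `"te_family"` or `"mito"`). Features absent from
#'   the map default to `"gene"`.
#' @param rows,cols For MTX input, paths to the row-id and column-id files.
#' @return A `count_matrix`: an integer matrix with feature-id rownames,
#'   sample-id colnames, and a `kind` attribute (character vector parallel to
#'   the rows).
#' @export
read_counts <- function(path, kind_map = NULL, rows = NULL, cols = NULL) {
  if (!file.exists(path)) stop("count file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(rows) || is.null(cols))
      stop("MTX input requires 'rows' and 'cols' id files")
    m <- as.matrix(Matrix::readMM(path))
    rid <- readLines(rows)
    cid <- readLines(cols)
    if (nrow(m) != length(rid) || ncol(m) != length(cid))
      stop("MTX dimensions (", nrow(m), "x", ncol(m),
           ") do not match id files (", length(rid), "x", length(cid), ")")
    dimnames(m) <- list(rid, cid)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("count TSV needs a feature-id column plus samples")
    rid <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- rid
  }
  storage_ok <- is.numeric(m) && all(is.finite(m))
  if (!storage_ok) stop("counts contain non-numeric or non-finite cells")
  if (any(m < 0)) stop("counts contain negative cells")
  if (any(m != round(m))) stop("counts contain non-integer cells")
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids in count matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in count matrix")
  count_matrix(m, kind = kind_map)
}

#' Construct and validate a count matrix
#'
#' @param m Numeric matrix of nonnegative integer counts, features x samples,
#'   with rownames and colnames.
#' @param kind `NULL`, a character vector of length `nrow(m)`, or a named map
#'   from feature id to kind. Valid kinds: gene, te_family, mito.
#' @return The validated integer matrix with a `kind` attribute and class
#'   `count_matrix`.
#' @export
count_matrix <- function(m, kind = NULL) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs feature rownames and sample colnames")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  kinds <- rep("gene", nrow(m))
  if (!is.null(kind)) {
    if (!is.null(names(kind))) {
      hit <- match(rownames(m), names(kind))
      kinds[!is.na(hit)] <- unname(kind[hit[!is.na(hit)]])
    } else {
      if (length(kind) != nrow(m)) stop("kind vector length must match rows")
      kinds <- as.character(kind)
    }
  }
  bad <- setdiff(unique(kinds), c("gene", "te_family", "mito"))
  if (length(bad)) stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  attr(m, "kind") <- kinds
  class(m) <- c("count_matrix", class(m))
  m
}

#' Read a sample design table
#'
#' TSV with columns `sample`, `strain`, `age`, `replicate`. Age values must be
#' `young` or `old`.
#'
#' @param path Path to the design TSV.
#' @param counts Optional `count_matrix`; when given, samples are checked for
#'   exact one-to-one agreement with the matrix columns.
#' @return A data.frame with the four columns, `age` as a factor with levels
#'   young, old.
#' @export
read_design <- function(path, counts = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(d, counts)
}

validate_design <- function(d, counts = NULL) {
  need <- c("sample", "strain", "age", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample)) stop("duplicate sample ids in design")
  if (!all(d$age %in% c("young", "old")))
    stop("age must be 'young' or 'old'")
  d$age <- factor(d$age, levels = c("young", "old"))
  d$strain <- as.character(d$strain)
  tab <- table(d$strain, d$age)
  if (any(tab < 2))
    stop("every strain x age cell needs >= 2 replicates")
  if (!is.null(counts)) {
    if (!setequal(d$sample, colnames(counts)) ||
        anyDuplicated(d$sample))
      stop("design samples do not match count matrix columns")
    d <- d[match(colnames(counts), d$sample), , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk; the returned `GRanges` uses the usual
#' 1-based inclusive R convention, so a BED line `chr4 0 100` becomes
#' `chr4:1-100` (width 100).
#'
#' @param path Path to the BED file.
#' @return A `GRanges` with any name column in `mcols(x)$name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED parse error in ", path, ": ",
                                          conditionMessage(e)))
  gr
}

#' Read gene annotation from GFF3
#'
#' GFF3 is 1-based inclusive. Feature ids are taken from the `ID` attribute
#' (falling back to `Name`). Length is the annotated `transcript_length`
#' attribute when present, otherwise the genomic span; RPKM uses this length.
#'
#' @param path Path to the GFF3 file.
#' @param feature_type GFF3 `type` to keep (default `"gene"`).
#' @return A `feature_annotation` data.frame: feature, chrom, start, end,
#'   strand, length.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) stop("GFF3 features lack ID attributes")
  span <- GenomicRanges::width(gr)
  tl <- S4Vectors::mcols(gr)$transcript_length
  len <- if (is.null(tl)) span else {
    tl <- suppressWarnings(as.integer(tl))
    ifelse(is.na(tl), span, tl)
  }
  feature_annotation(data.frame(
    feature = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = len,
    stringsAsFactors = FALSE))
}

#' Construct and validate a feature annotation table
#'
#' Coordinates are 1-based inclusive; `length` is transcript length in bp
#' (what RPKM divides by), which need not equal the genomic span.
#'
#' @param df data.frame with columns feature, chrom, start, end, length and
#'   optionally strand and compartment label columns (het, dot, domain).
#' @return The validated data.frame with class `feature_annotation`.
#' @export
feature_annotation <- function(df) {
  need <- c("feature", "chrom", "start", "end", "length")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$feature)) stop("duplicate feature ids in annotation")
  if (any(df$start > df$end)) stop("annotation has start > end")
  if (any(df$length <= 0)) stop("annotation has non-positive lengths")
  if (is.null(df$strand)) df$strand <- "+"
  class(df) <- c("feature_annotation", "data.frame")
  df
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is: set name, description, then tab-separated member ids.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector of known feature ids; members
#'   outside it are dropped with a warning, never silently kept.
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (!is.null(universe)) {
    for (nm in names(sets)) {
      lost <- setdiff(sets[[nm]], universe)
      if (length(lost)) {
        warning("gene set '", nm, "': dropping ", length(lost),
                " member(s) not in annotation")
        sets[[nm]] <- intersect(sets[[nm]], universe)
      }
    }
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Stable column order, no quoting, no row names.
#'
#' @param table data.frame to write.
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' @param counts `count_matrix`.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), as.data.frame(unclass(counts)),
                   check.names = FALSE)
  write_results(df, path)
}
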