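#' Simulation configuration for the two-strain, two-age egg-chamber design
#'
#' Encodes the statistical structure the analysis assumes: negative-binomial
#' counts (Var = mu + alpha * mu^2, one genome-wide alpha by default) around
#' log-normal baseline abundances and log-normal library sizes, a 2-strain x
#' 2-age design with unbalanced replicates, gene sets carrying injected log2
#' age effects, heterochromatin domain membership for a fixed fraction of
#' genes, a small dot chromosome, and TE families quantified at the family
#' level.
#'
#' @param n_genes Number of genic features.
#' @param n_te_families Number of TE families.
#' @param n_mito Number of mitochondrial-genome features.
#' @param strains Strain labels (2 expected downstream).
#' @param replicates_per_cell Replicates per strain x age cell: single count
#'   or per-strain vector (default 4 and 3, mirroring an unbalanced design).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean/sd of relative
#'   feature abundance.
#' @param nb_dispersion Genome-wide NB dispersion alpha (> 0).
#' @param library_size_mean Mean mapped reads per sample.
#' @param library_size_cv Coefficient of variation of the log-normal library
#'   sizes (replicate-pool variability).
#' @param strain_effect_sd SD of per-gene log2 strain offsets.
#' @param effect_table data.frame with columns `set`, `strain` (a strain
#'   label or "*" for all) and `log2_age` giving the injected old-vs-young
#'   log2 effect for members of each named set. `NULL` uses
#'   [default_effect_table()]; an empty data.frame gives a global null.
#' @param set_sizes Named sizes for the built-in gene sets (pirna, eggshell,
#'   etc).
#' @param het_fraction Fraction of genes inside heterochromatin domains
#'   (dot-chromosome genes included).
#' @param dot_gene_count Genes on the dot chromosome; `NULL` scales the
#'   84-of-14289 proportion to `n_genes`.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal transcript-length
#'   parameters (bp); lengths are floored at 200 bp.
#' @param seed Integer seed; fully determines every output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_te_families = 125,
                              n_mito = 15,
                              strains = c("Ral_321", "Ral_237"),
                              replicates_per_cell = c(4, 3),
                              baseline_log_mean = 3,
                              baseline_log_sd = 1.5,
                              nb_dispersion = 0.05,
                              library_size_mean = 5e6,
                              library_size_cv = 0.2,
                              strain_effect_sd = 0.2,
                              effect_table = NULL,
                              set_sizes = c(pirna = 31, eggshell = 49,
                                            etc = 40),
                              het_fraction = 1695 / 14289,
                              dot_gene_count = NULL,
                              gene_length_meanlog = log(2000),
                              gene_length_sdlog = 0.7,
                              seed = 1L) {
  reps <- replicates_per_cell
  if (length(reps) == 1) reps <- rep(reps, length(strains))
  if (length(reps) != length(strains))
    stop("replicates_per_cell must be scalar or one per strain")
  names(reps) <- strains
  if (any(reps < 2)) stop("replicates_per_cell must be >= 2")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (n_genes < 100) stop("n_genes must be >= 100")
  if (is.null(dot_gene_count))
    dot_gene_count <- max(2L, round(n_genes * 84 / 14289))
  if (is.null(effect_table)) effect_table <- default_effect_table(strains)
  if (nrow(effect_table) &&
      !all(c("set", "strain", "log2_age") %in% names(effect_table)))
    stop("effect_table needs columns set, strain, log2_age")
  if (nrow(effect_table) && !all(is.finite(effect_table$log2_age)))
    stop("effect_table log2_age entries must be finite")
  cfg <- list(n_genes = as.integer(n_genes),
              n_te_families = as.integer(n_te_families),
              n_mito = as.integer(n_mito),
              strains = strains, replicates_per_cell = reps,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              library_size_cv = library_size_cv,
              strain_effect_sd = strain_effect_sd,
              effect_table = effect_table,
              set_sizes = set_sizes,
              het_fraction = het_fraction,
              dot_gene_count = as.integer(dot_gene_count),
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Default injected gene-set effects
#'
#' A 31-gene focal set with a mild coordinated up-shift in both strains
#' (+0.4 log2), mitochondrial-genome and electron-transport-chain sets with
#' coordinated down-shifts, an eggshell set with a strain-asymmetric
#' down-shift, one TE family up in both strains, four TE families down, and
#' an opposite-sign strain-by-age TE pair.
#'
#' @param strains Two strain labels.
#' @return data.frame with columns set, strain, log2_age.
#' @export
default_effect_table <- function(strains = c("Ral_321", "Ral_237")) {
  s1 <- strains[1]; s2 <- strains[2]
  data.frame(
    set = c("pirna", "mito", "etc", "eggshell", "eggshell",
            "te_up", "te_down", "te_interaction", "te_interaction"),
    strain = c("*", "*", "*", s1, s2, "*", "*", s1, s2),
    log2_age = c(0.4, -0.8, -0.5, -1.0, -0.3, 1.5, -1.2, 0.8, -0.8),
    stringsAsFactors = FALSE)
}

#' Convenience preset matching the published annotation marginals
#'
#' Returns a [simulation_config()] whose annotation has exactly 14,289 genic
#' features, 1,695 of them heterochromatin-flagged and 84 on the dot
#' chromosome.
#'
#' @param ... Overrides passed to [simulation_config()] (not the three
#'   pinned marginals).
#' @return A `simulation_config`.
#' @export
paper_marginal_config <- function(...) {
  simulation_config(n_genes = 14289, het_fraction = 1695 / 14289,
                    dot_gene_count = 84, ...)
}

# chromosome layout used by the generator (bp)
sim_chromosomes <- function() {
  list(big = c("2L" = 24e6, "2R" = 24e6, "3L" = 25e6, "3R" = 28e6,
               "X" = 23e6),
       dot = c("4" = 1.35e6),
       mito = c("mito" = 19517))
}

# heterochromatin domain GRanges: dot chromosome fully covered, a pericentric
# block plus dispersed intercalary blocks on each big chromosome
sim_domains <- function() {
  ch <- sim_chromosomes()
  chroms <- names(ch$big)
  istarts <- seq(4e6, 20e6, by = 4e6)
  GenomicRanges::GRanges(
    c(chroms, rep(chroms, each = length(istarts)), "4"),
    IRanges::IRanges(
      c(rep(1, length(chroms)), rep(istarts, length(chroms)), 1),
      c(rep(2e6, length(chroms)),
        rep(istarts + 2e5 - 1, length(chroms)), ch$dot[["4"]])),
    name = c(rep("pericentric", length(chroms)),
             rep("intercalary", length(chroms) * length(istarts)),
             "pericentric"))
}

# deterministic gene placement: het genes uniformly inside domains on their
# chromosome, non-het genes inside inter-domain gaps
place_genes <- function(n_genes, lengths, het, dot) {
  ch <- sim_chromosomes()
  big <- names(ch$big)
  chrom <- character(n_genes)
  start <- integer(n_genes)
  dom_label <- rep("none", n_genes)
  chrom[dot] <- "4"
  chrom[!dot] <- sample(big, sum(!dot), replace = TRUE)
  for (i in seq_len(n_genes)) {
    len <- lengths[i]
    if (dot[i]) {
      start[i] <- sample.int(ch$dot[["4"]] - len, 1)
      dom_label[i] <- "pericentric"
      next
    }
    if (het[i]) {
      # 1/3 pericentric, 2/3 intercalary
      if (stats::runif(1) < 1 / 3) {
        start[i] <- sample.int(2e6 - len, 1)
        dom_label[i] <- "pericentric"
      } else {
        blk <- sample(seq(4e6, 20e6, by = 4e6), 1)
        start[i] <- blk + sample.int(2e5 - len, 1) - 1
        dom_label[i] <- "intercalary"
      }
    } else {
      # euchromatic gaps between domains: [2.5,3.8], [4.3,7.8], ... Mb
      gap_starts <- c(2.5e6, seq(4.3e6, 20.3e6, by = 4e6))
      gap_ends <- c(3.8e6, seq(7.8e6, 23.8e6, by = 4e6))
      g <- sample.int(length(gap_starts), 1)
      start[i] <- gap_starts[g] + sample.int(gap_ends[g] - gap_starts[g] - len, 1)
    }
  }
  list(chrom = chrom, start = start, end = start + lengths - 1,
       domain = dom_label)
}

#' Simulate a full egg-chamber aging dataset
#'
#' Draws feature-wise negative-binomial counts with mean
#' `library_size x relative abundance x 2^(strain offset + age effect)`,
#' emits the matching sample design, genomic annotation (with
#' heterochromatin-domain and dot-chromosome placement), domain intervals,
#' gene sets, oogenic stage reference profiles, and a ground-truth table for
#' recovery tests. The seed in the config fully determines every output.
#'
#' @param config A [simulation_config()].
#' @return List with elements `counts` (`count_matrix`), `design`,
#'   `annotation` (`feature_annotation` with `het`, `dot`, `domain` columns),
#'   `domains` (`GRanges`), `gene_sets` (named list), `stage_profiles`
#'   (matrix, panel genes x stages), `truth` (data.frame with per-strain true
#'   log2 age effects, set membership and compartment labels), and `config`.
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must come from simulation_config()")
  set.seed(config$seed)
  ng <- config$n_genes; nte <- config$n_te_families; nm <- config$n_mito
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  te_ids <- sprintf("TEfam%03d", seq_len(nte))
  mito_ids <- sprintf("mt_gene%02d", seq_len(nm))
  ids <- c(gene_ids, mito_ids, te_ids)
  kind <- c(rep("gene", ng), rep("mito", nm), rep("te_family", nte))
  nfeat <- length(ids)

  # transcript lengths (bp), log-normal floored at 200
  lengths <- pmax(200L, as.integer(round(stats::rlnorm(
    nfeat, config$gene_length_meanlog, config$gene_length_sdlog))))

  # gene sets: mito set is the mito features; others sampled among genes
  sizes <- config$set_sizes
  pool <- sample(gene_ids)
  take <- function(n) {
    out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out
  }
  gene_sets <- list(pirna = take(sizes[["pirna"]]),
                    eggshell = take(sizes[["eggshell"]]),
                    etc = take(sizes[["etc"]]),
                    mito = mito_ids)
  te_sets <- list(te_up = te_ids[1],
                  te_down = te_ids[2:5],
                  te_interaction = te_ids[6:7])

  # true per-strain log2 age effects from the effect table
  strains <- config$strains
  eff <- matrix(0, nfeat, length(strains),
                dimnames = list(ids, strains))
  et <- config$effect_table
  all_sets <- c(gene_sets, te_sets)
  if (nrow(et)) for (r in seq_len(nrow(et))) {
    members <- all_sets[[et$set[r]]]
    if (is.null(members)) next
    cols <- if (et$strain[r] == "*") strains else et$strain[r]
    eff[members, cols] <- eff[members, cols] + et$log2_age[r]
  }

  # compartments: dot genes on chr 4 (all het), remaining het genes spread
  n_het <- round(config$het_fraction * ng)
  n_dot <- min(config$dot_gene_count, n_het)
  dot <- c(rep(FALSE, ng))
  dot[sample.int(ng, n_dot)] <- TRUE
  het <- dot
  het[sample(which(!dot), n_het - n_dot)] <- TRUE
  pos <- place_genes(ng, lengths[seq_len(ng)], het, dot)
  mito_starts <- cumsum(c(1, lengths[ng + seq_len(nm)][-nm] + 10))
  annotation <- feature_annotation(data.frame(
    feature = ids,
    chrom = c(pos$chrom, rep("mito", nm), rep("TEcontig", nte)),
    start = c(pos$start, mito_starts, seq(1, by = 2e4, length.out = nte)),
    end = c(pos$end, mito_starts + lengths[ng + seq_len(nm)] - 1,
            seq(1, by = 2e4, length.out = nte) + lengths[ng + nm + seq_len(nte)] - 1),
    strand = "+",
    length = lengths,
    kind = kind,
    het = c(het, rep(FALSE, nm + nte)),
    dot = c(dot, rep(FALSE, nm + nte)),
    domain = c(pos$domain, rep("none", nm + nte)),
    stringsAsFactors = FALSE))

  # design: unbalanced replicates per strain, both ages
  design <- do.call(rbind, lapply(strains, function(s) {
    r <- config$replicates_per_cell[[s]]
    data.frame(sample = paste(s, rep(c("young", "old"), each = r),
                              seq_len(r), sep = "_"),
               strain = s, age = rep(c("young", "old"), each = r),
               replicate = seq_len(r), stringsAsFactors = FALSE)
  }))
  design$age <- factor(design$age, levels = c("young", "old"))

  # expected counts: library size x relative abundance x 2^(effects)
  abund <- stats::rlnorm(nfeat, config$baseline_log_mean, config$baseline_log_sd)
  # mito features highly expressed; TE families low-to-mid
  abund[kind == "mito"] <- abund[kind == "mito"] * 50
  abund[kind == "te_family"] <- abund[kind == "te_family"] * 0.5
  q <- stats::setNames(abund / sum(abund), ids)
  strain_off <- matrix(0, nfeat, length(strains),
                       dimnames = list(ids, strains))
  for (s in strains[-1])
    strain_off[, s] <- stats::rnorm(nfeat, 0, config$strain_effect_sd)
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  lib <- stats::rlnorm(nrow(design),
                       log(config$library_size_mean) - sdlog^2 / 2, sdlog)
  counts <- matrix(0L, nfeat, nrow(design),
                   dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    s <- design$strain[j]
    old <- design$age[j] == "old"
    mu <- lib[j] * q * 2^(strain_off[, s] + if (old) eff[, s] else 0)
    counts[, j] <- stats::rnbinom(nfeat, mu = mu,
                                  size = 1 / config$nb_dispersion)
  }
  cm <- count_matrix(counts, kind = kind)

  # stage reference profiles over the eggshell panel: the sample profile
  # mirrors stage 14; earlier stages are decorrelated scrambles
  panel <- gene_sets$eggshell
  mu14 <- q[panel] * config$library_size_mean
  rpkm14 <- mu14 / (lengths[match(panel, ids)] / 1000) /
    (config$library_size_mean / 1e6)
  stages <- c("9-10a", "10b", "12", "14")
  stage_profiles <- sapply(stages, function(st) {
    if (st == "14") rpkm14 * stats::rlnorm(length(panel), 0, 0.15)
    else sample(rpkm14) * stats::rlnorm(length(panel), 0, 0.3)
  })
  rownames(stage_profiles) <- panel

  truth <- data.frame(feature = ids, kind = kind, stringsAsFactors = FALSE)
  for (s in strains) truth[[paste0("log2_age_", s)]] <- eff[, s]
  truth$set <- "none"
  for (nm2 in names(all_sets)) truth$set[ids %in% all_sets[[nm2]]] <- nm2
  truth$het <- annotation$het
  truth$dot <- annotation$dot

  list(counts = cm, design = design, annotation = annotation,
       domains = sim_domains(), gene_sets = gene_sets,
       stage_profiles = stage_profiles, truth = truth, config = config)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Counts and design as TSV; gene annotation as GFF3 (1-based inclusive,
#' with a `transcript_length` attribute) and BED (0-based half-open); domain
#' intervals as BED; gene sets as GMT; stage profiles and ground truth as
#' TSV.
#'
#' @param sim Output of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(counts = file.path(dir, "counts.tsv"),
         design = file.path(dir, "design.tsv"),
         gff3 = file.path(dir, "annotation.gff3"),
         bed = file.path(dir, "annotation.bed"),
         domains = file.path(dir, "domains.bed"),
         gmt = file.path(dir, "gene_sets.gmt"),
         stages = file.path(dir, "stage_profiles.tsv"),
         truth = file.path(dir, "truth.tsv"))
  write_counts(sim$counts, p[["counts"]])
  write_results(sim$design, p[["design"]])
  a <- sim$annotation
  gr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end),
                               strand = a$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- a$feature
  S4Vectors::mcols(gr)$transcript_length <- a$length
  rtracklayer::export(gr, p[["gff3"]], format = "gff3")
  bed <- gr
  S4Vectors::mcols(bed) <- NULL
  S4Vectors::mcols(bed)$name <- a$feature
  rtracklayer::export(bed, p[["bed"]], format = "bed")
  rtracklayer::export(sim$domains, p[["domains"]], format = "bed")
  write_gmt(sim$gene_sets, p[["gmt"]])
  write_results(data.frame(gene = rownames(sim$stage_profiles),
                           sim$stage_profiles, check.names = FALSE),
                p[["stages"]])
  write_results(sim$truth, p[["truth"]])
  invisible(p)
}
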