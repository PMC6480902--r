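#' Assemble and validate a pipeline run configuration
#'
#' Either `simulation` holds a [simulation_config()] (or a list of its
#' arguments) and the pipeline runs on generated data, or the input paths
#' (`counts`, `design`, `annotation`, `domains`, `gene_sets`) point at files
#' on disk. All referenced paths are checked before any computation.
#'
#' @param simulation `NULL`, a `simulation_config`, or a list of arguments
#'   for one.
#' @param counts,design,annotation,domains,gene_sets,stage_profiles Input
#'   file paths (TSV / GFF3 / BED / GMT / TSV) when not simulating.
#' @param fdr FDR threshold for DE significance.
#' @param offset Pseudo-RPKM for log ratios.
#' @param n_perm,k_up,k_down Permutation-test settings.
#' @param focal_set Name of the gene set given the matched permutation test
#'   (default "pirna").
#' @param directional_set Name of the gene set given per-strain sign tests
#'   (default "eggshell").
#' @param dot_chrom Dot-chromosome label (default "4").
#' @param seed Integer seed for all stochastic stages (mandatory when any is
#'   enabled).
#' @param out_dir Optional output directory for per-stage TSVs and the JSON
#'   summary.
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulation = NULL, counts = NULL, design = NULL,
                       annotation = NULL, domains = NULL, gene_sets = NULL,
                       stage_profiles = NULL,
                       fdr = 0.05, offset = 0.5,
                       n_perm = 10000, k_up = 10, k_down = 10,
                       focal_set = "pirna", directional_set = "eggshell",
                       dot_chrom = "4", seed = NULL, out_dir = NULL) {
  if (is.null(simulation)) {
    need <- list(counts = counts, design = design, annotation = annotation)
    for (nm in names(need))
      if (is.null(need[[nm]])) stop("run_config: '", nm, "' path is required")
    paths <- c(need, list(domains = domains, gene_sets = gene_sets,
                          stage_profiles = stage_profiles))
    for (nm in names(paths)) {
      p <- paths[[nm]]
      if (!is.null(p) && !file.exists(p))
        stop("run_config: ", nm, " file not found: ", p)
    }
  } else if (!inherits(simulation, "simulation_config")) {
    simulation <- do.call(simulation_config, as.list(simulation))
  }
  if (is.null(seed)) stop("run_config: seed is required")
  cfg <- list(simulation = simulation, counts = counts, design = design,
              annotation = annotation, domains = domains,
              gene_sets = gene_sets, stage_profiles = stage_profiles,
              fdr = fdr, offset = offset, n_perm = n_perm,
              k_up = k_up, k_down = k_down, focal_set = focal_set,
              directional_set = directional_set, dot_chrom = dot_chrom,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments
#'   (with a `simulation:` block for simulated runs).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

pipeline_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[ovage] %-12s %6.2fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full egg-chamber aging pipeline
#'
#' Stage order: load or simulate inputs; RPKM and per-strain aging ratios;
#' negative-binomial DE for age, strain-by-age; expression-matched
#' permutation test and top-decile enrichment for the focal set; per-strain
#' sign tests for the directional set; heterochromatin and dot-chromosome
#' contingency tables with Yates chi-squared plus the compartment shift
#' t-test; TE global, family-level and cross-strain statistics; cross-strain
#' correlations (DE set and transcriptome-wide); oogenic stage verification
#' when reference profiles are available. Deterministic given the seed.
#'
#' @param config A [run_config()] (or a YAML path for one).
#' @return A list: `summary` (the machine-readable statistics bundle, also
#'   written as JSON when `out_dir` is set), `de`, `expression`, `te`,
#'   `tables`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("config must come from run_config()")

  inp <- pipeline_stage("load", {
    if (!is.null(config$simulation)) {
      simulate_counts(config$simulation)
    } else {
      ann <- read_gff3(config$annotation)
      cm <- read_counts(config$counts)
      sets <- if (!is.null(config$gene_sets))
        read_gmt(config$gene_sets, universe = ann$feature) else list()
      dom <- if (!is.null(config$domains)) read_bed(config$domains) else NULL
      sp <- if (!is.null(config$stage_profiles)) {
        df <- utils::read.delim(config$stage_profiles, check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- df[[1]]; m
      } else NULL
      list(counts = cm, design = read_design(config$design, cm),
           annotation = ann, domains = dom, gene_sets = sets,
           stage_profiles = sp, truth = NULL)
    }
  })
  ann <- inp$annotation
  kinds <- attr(inp$counts, "kind")
  gene_rows <- kinds == "gene" | kinds == "mito"

  expr <- pipeline_stage("summarize", {
    r <- rpkm(inp$counts, ann)
    summarize_expression(r, inp$design, offset = config$offset)
  })
  gene_summary <- expr[expr$feature %in% rownames(inp$counts)[gene_rows], ]
  class(gene_summary) <- class(expr)

  de <- pipeline_stage("detest", {
    test_age(count_matrix(inp$counts[gene_rows, , drop = FALSE]),
             inp$design, fdr = config$fdr)
  })

  summary_json <- list(
    parameters = list(fdr = config$fdr, offset = config$offset,
                      n_perm = config$n_perm, k_up = config$k_up,
                      k_down = config$k_down, seed = config$seed),
    de = list(n_tested = sum(!is.na(de$p_age)),
              n_significant = sum(de$significant),
              n_up = sum(de$significant & de$log2fc_age > 0),
              n_down = sum(de$significant & de$log2fc_age < 0),
              n_interaction = sum(!is.na(de$padj_interaction) &
                                    de$padj_interaction < config$fdr)))
  tables <- list()

  sets <- inp$gene_sets
  if (!is.null(sets[[config$focal_set]])) {
    st <- pipeline_stage("settest", {
      focal <- intersect(sets[[config$focal_set]], gene_summary$feature)
      matches <- build_match_table(gene_summary, focal,
                                   k_up = config$k_up, k_down = config$k_down)
      perm <- matched_permutation_test(gene_summary, matches, focal,
                                       n_perm = config$n_perm,
                                       seed = config$seed)
      dirs <- direction_count(gene_summary, focal)
      topk <- topk_enrichment(de, focal)
      list(perm = perm, dirs = dirs, topk = topk)
    })
    summary_json$focal_set <- list(
      name = config$focal_set,
      observed = as.list(st$perm$observed),
      p_permutation = st$perm$p, p_permutation_raw = st$perm$p_raw,
      direction_pooled = as.list(st$dirs[st$dirs$group == "pooled",
                                         c("n_up", "n_down", "n_flat")]),
      top_decile = list(table = unname(st$topk$table),
                        chi2 = st$topk$chi2, p = st$topk$p))
    tables$focal <- st
  }

  if (!is.null(sets[[config$directional_set]])) {
    sg <- pipeline_stage("signtest", {
      out <- list()
      for (s in unique(inp$design$strain)) {
        sub <- gene_summary[gene_summary$strain == s &
                              gene_summary$feature %in%
                              sets[[config$directional_set]], ]
        n_down <- sum(sub$direction == "down")
        n_tot <- sum(sub$direction != "flat")
        out[[s]] <- list(n_down = n_down, n_total = n_tot,
                         p = sign_test(n_down, n_tot))
      }
      out
    })
    summary_json$directional_set <- c(list(name = config$directional_set), sg)
  }

  if (!is.null(inp$domains) || !is.null(ann$het)) {
    en <- pipeline_stage("enrich", {
      gann <- if (!is.null(ann$kind))
        ann[ann$kind == "gene", , drop = FALSE] else ann
      gann <- gann[!gann$chrom %in% c("mito", "TEcontig"), , drop = FALSE]
      het_flags <- if (!is.null(inp$domains)) {
        flag_compartment(gann, inp$domains)
      } else stats::setNames(gann$het, gann$feature)
      dot_flags <- stats::setNames(gann$chrom == config$dot_chrom,
                                   gann$feature)
      de_g <- de[de$feature %in% gann$feature, ]
      class(de_g) <- class(de)
      het_tab <- build_de_compartment_table(de_g, het_flags)
      dot_tab <- build_de_compartment_table(de_g, dot_flags)
      shift <- lapply(stats::setNames(nm = unique(inp$design$strain)),
                      function(s) {
        gs <- gene_summary[gene_summary$feature %in% gann$feature, ]
        class(gs) <- class(gene_summary)
        compartment_shift_test(gs, het_flags, s)
      })
      list(het_table = het_tab, het_test = yates_chi2(het_tab),
           dot_table = dot_tab, dot_test = yates_chi2(dot_tab),
           shift = shift)
    })
    summary_json$heterochromatin <- list(
      table = unname(en$het_table), chi2 = en$het_test$chi2,
      p = en$het_test$p,
      shift_p = lapply(en$shift, `[[`, "p"))
    summary_json$dot_chromosome <- list(
      table = unname(en$dot_table), chi2 = en$dot_test$chi2,
      p = en$dot_test$p)
    tables$enrichment <- en
  }

  te_res <- NULL
  if (any(kinds == "te_family")) {
    te_res <- pipeline_stage("te", {
      te_summary <- expr[expr$feature %in% rownames(inp$counts)[kinds == "te_family"], ]
      class(te_summary) <- class(expr)
      glob <- lapply(stats::setNames(nm = unique(inp$design$strain)),
                     function(s) te_global_test(te_summary, s,
                                                offset = config$offset))
      fam <- te_family_tests(inp$counts, inp$design, ann,
                             fdr = config$fdr, offset = config$offset)
      corr <- te_cross_strain_correlation(te_summary)
      list(global = glob, families = fam, correlation = corr)
    })
    summary_json$te <- list(
      global_p = lapply(te_res$global, `[[`, "p"),
      n_significant_age = sum(te_res$families$significant),
      n_significant_interaction =
        sum(!is.na(te_res$families$padj_interaction) &
              te_res$families$padj_interaction < config$fdr),
      cross_strain = te_res$correlation[c("r", "p")])
  }

  corr <- pipeline_stage("correlate", {
    de_set <- de$feature[de$significant]
    list(de_set = if (length(de_set) >= 3)
      cross_strain_correlation(gene_summary, de_set) else NULL,
      all = cross_strain_correlation(gene_summary))
  })
  summary_json$cross_strain <- list(
    de_set = if (!is.null(corr$de_set)) corr$de_set[c("r", "p", "n")],
    all = corr$all[c("r", "p", "n")])

  if (!is.null(inp$stage_profiles)) {
    sv <- pipeline_stage("stage", {
      r <- rpkm(inp$counts, ann)
      calls <- apply(r, 2, function(col)
        verify_stage(col, inp$stage_profiles, offset = config$offset)$stage)
      list(calls = calls)
    })
    summary_json$stage_verification <- list(
      assigned = as.list(sv$calls),
      all_stage14 = all(sv$calls == "14"))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(de, file.path(config$out_dir, "de_results.tsv"))
    write_results(expr, file.path(config$out_dir, "expression_summary.tsv"))
    if (!is.null(te_res))
      write_results(te_res$families, file.path(config$out_dir, "te_families.tsv"))
    jsonlite::write_json(summary_json,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(summary = summary_json, de = de, expression = expr,
       te = te_res, tables = tables, inputs = inp)
}
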