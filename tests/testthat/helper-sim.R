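# shared fixture builders

null_effects <- function() {
  data.frame(set = character(), strain = character(), log2_age = numeric(),
             stringsAsFactors = FALSE)
}

# small dataset with no injected effects
small_null_sim <- function(seed, n_genes = 500, ...) {
  simulate_counts(simulation_config(n_genes = n_genes,
                                    effect_table = null_effects(),
                                    seed = seed, ...))
}

# hand-built expression summary over two strains from explicit ratio vectors
summary_from_ratios <- function(rA, rB, offset = 0.5) {
  feats <- names(rA)
  mk <- function(r, s) {
    data.frame(feature = feats, strain = s,
               mean_young = 1, mean_old = (1 + offset) * 2^r - offset,
               log2_ratio = r, fold = NA_real_,
               direction = ifelse(abs(r) < 1e-9, "flat",
                                  ifelse(r > 0, "up", "down")),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(rA, "A"), mk(rB, "B"))
  attr(out, "offset") <- offset
  class(out) <- c("expression_summary", "data.frame")
  out
}

gene_counts <- function(sim) {
  count_matrix(sim$counts[attr(sim$counts, "kind") == "gene", , drop = FALSE])
}
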