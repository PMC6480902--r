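ranked_summary <- function(n, seed = 5) {
  set.seed(seed)
  ids <- sprintf("g%04d", seq_len(n))
  expr <- seq_len(n)  # expression equals rank, no ties
  s <- rbind(
    data.frame(feature = ids, strain = "A", mean_young = expr,
               mean_old = expr, log2_ratio = rnorm(n), fold = 1,
               direction = "up", stringsAsFactors = FALSE),
    data.frame(feature = ids, strain = "B", mean_young = expr,
               mean_old = expr, log2_ratio = rnorm(n), fold = 1,
               direction = "up", stringsAsFactors = FALSE))
  class(s) <- c("expression_summary", "data.frame")
  s
}

test_that("match table takes the 10 + 10 rank neighbours with edge fill", {
  s <- ranked_summary(1001)
  focal <- "g0501"  # exactly median
  mt <- build_match_table(s, focal)
  expected <- sprintf("g%04d", c(491:500, 502:511))
  expect_setequal(mt[[focal]], expected)
  expect_length(mt[[focal]], 20)

  # highest-expressed focal gene: 0 above, 20 below
  top <- "g1001"
  mt2 <- build_match_table(s, top)
  expect_setequal(mt2[[top]], sprintf("g%04d", 981:1000))

  # focal-set members are never candidates
  mt3 <- build_match_table(s, c("g0501", "g0502"))
  expect_false("g0502" %in% mt3[["g0501"]])
  expect_true(all(lengths(mt3) == 20))
})

test_that("match table equals the brute-force sort-and-scan oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 80
    ids <- sprintf("g%03d", 1:n)
    expr <- setNames(runif(n), ids)
    s <- summary_from_ratios(setNames(rnorm(n), ids), setNames(rnorm(n), ids))
    s$mean_young <- rep(expr, 2); s$mean_old <- rep(expr, 2)
    focal <- sample(ids, 4)
    mt <- build_match_table(s, focal, k_up = 7, k_down = 5)
    for (g in focal) {
      expect_setequal(mt[[g]], brute_force_matches(expr, focal, g, 7, 5))
    }
  }
})

test_that("permutation test handles the degenerate all-equal case", {
  n <- 60
  ids <- sprintf("g%03d", 1:n)
  s <- summary_from_ratios(setNames(rep(0.3, n), ids),
                           setNames(rep(0.3, n), ids))
  focal <- ids[1:5]
  mt <- build_match_table(s, focal, k_up = 3, k_down = 3)
  res <- matched_permutation_test(s, mt, focal, n_perm = 500, seed = 1)
  expect_equal(res$p, 1)
  expect_equal(res$exceedances, 500)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on small instances", {
  set.seed(17)
  for (nf in 2:4) {
    for (nm in 2:3) {
      ids <- sprintf("g%03d", 1:40)
      rA <- setNames(rnorm(40), ids); rB <- setNames(rnorm(40), ids)
      s <- summary_from_ratios(rA, rB)
      focal <- ids[1:nf]
      matches <- lapply(focal, function(g) sample(ids[-(1:nf)], nm))
      names(matches) <- focal
      ratios <- cbind(A = rA, B = rB)
      p_exact <- enumerate_perm_p(ratios, matches, focal)
      res <- matched_permutation_test(s, matches, focal,
                                      n_perm = 10000, seed = 100 + nf * nm)
      se <- sqrt(p_exact * (1 - p_exact) / 10000)
      expect_lte(abs(res$p_raw - p_exact), 3 * se + 1e-9)
    }
  }
})

test_that("permutation p is reproducible, never zero, and seed-stable", {
  set.seed(3)
  n <- 200
  ids <- sprintf("g%03d", 1:n)
  s <- summary_from_ratios(setNames(rnorm(n), ids), setNames(rnorm(n), ids))
  focal <- sample(ids, 8)
  mt <- build_match_table(s, focal)
  r1 <- matched_permutation_test(s, mt, focal, n_perm = 1000, seed = 42)
  r2 <- matched_permutation_test(s, mt, focal, n_perm = 1000, seed = 42)
  expect_identical(r1$exceedances, r2$exceedances)
  expect_gt(r1$p, 0)
  expect_warning(matched_permutation_test(s, mt, focal, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("direction counts match a sign-by-sign loop", {
  ids <- c("a", "b", "c")
  s <- summary_from_ratios(setNames(c(1, 1, -1), ids),
                           setNames(c(1, 1, -1), ids))
  d <- direction_count(s, ids)
  pooled <- d[d$group == "pooled", ]
  expect_equal(unlist(pooled[, c("n_up", "n_down", "n_flat")]),
               c(n_up = 2, n_down = 1, n_flat = 0))

  z <- summary_from_ratios(setNames(rep(0, 4), letters[1:4]),
                           setNames(rep(0, 4), letters[1:4]))
  dz <- direction_count(z, letters[1:4])
  expect_equal(dz$n_flat, rep(4, 3))

  set.seed(12)
  ids <- sprintf("g%02d", 1:30)
  rA <- setNames(rnorm(30), ids); rB <- setNames(rnorm(30), ids)
  s2 <- summary_from_ratios(rA, rB)
  d2 <- direction_count(s2, ids)
  expect_equal(d2[d2$group == "A", "n_up"], sum(rA > 1e-9))
  expect_equal(d2[d2$group == "B", "n_down"], sum(rB < -1e-9))
  pooled_r <- (rA + rB) / 2
  expect_equal(d2[d2$group == "pooled", "n_up"], sum(pooled_r > 1e-9))
})

test_that("sign test equals the exact binomial oracle for all n <= 60", {
  expect_equal(sign_test(2, 4), 1)
  expect_equal(sign_test(4, 5), 0.375)
  expect_lt(sign_test(47, 49), 1e-10)
  for (n in c(1:15, 30, 49, 60)) {
    for (k in unique(c(0, 1, floor(n / 2), n - 1, n))) {
      if (k < 0 || k > n) next
      expect_equal(sign_test(k, n), binom_sign_oracle(k, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("top-decile enrichment detects planted membership", {
  set.seed(8)
  n <- 600
  de <- data.frame(feature = sprintf("g%03d", 1:n),
                   p_age = runif(n), stringsAsFactors = FALSE)
  de$padj_age <- bh_adjust(de$p_age)
  de$significant <- de$padj_age < 0.05
  class(de) <- c("de_result", "data.frame")
  # plant a set entirely inside the top decile
  top <- de$feature[order(de$padj_age, de$p_age)][1:30]
  res <- topk_enrichment(de, top, top_fraction = 0.10)
  expect_lt(res$p, 1e-6)
  expect_equal(res$table["top", "in_set"], 30L)

  # membership independent of rank: chi2 small on average
  rand <- sample(de$feature, 60)
  res2 <- topk_enrichment(de, rand)
  expect_lt(res2$chi2, 10)

  expect_error(topk_enrichment(de, top, top_fraction = 1), "between 0 and 1")
  expect_error(topk_enrichment(de, c("zzz"), 0.1), "disjoint")
})
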