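make_design <- function(reps, strains = c("A", "B")) {
  do.call(rbind, lapply(strains, function(s) {
    data.frame(sample = paste(s, rep(c("young", "old"), each = reps),
                              seq_len(reps), sep = "_"),
               strain = s, age = rep(c("young", "old"), each = reps),
               replicate = seq_len(reps), stringsAsFactors = FALSE)
  }))
}

sim_counts <- function(n, design, mu = 100, alpha = 0.1, lfc_old = 0) {
  m <- sapply(seq_len(nrow(design)), function(j) {
    mm <- mu * 2^(if (design$age[j] == "old") lfc_old else 0)
    if (alpha > 0) rnbinom(n, mu = mm, size = 1 / alpha) else rpois(n, mm)
  })
  dimnames(m) <- list(sprintf("g%04d", seq_len(n)), design$sample)
  count_matrix(m)
}

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  # NAs pass through and do not count toward m
  expect_equal(bh_adjust(c(0.01, NA, 0.03)),
               c(bh_adjust(c(0.01, 0.03))[1], NA, bh_adjust(c(0.01, 0.03))[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("dispersion estimation is calibrated on Poisson and NB truth", {
  design <- make_design(8)
  set.seed(21)
  cm <- sim_counts(800, design, mu = 150, alpha = 0)  # Poisson
  d <- estimate_dispersion(cm, design)
  expect_lt(median(d), 0.05)

  # constant counts across replicates -> floored
  const <- matrix(5L, 4, nrow(design),
                  dimnames = list(paste0("c", 1:4), design$sample))
  dd <- suppressWarnings(estimate_dispersion(count_matrix(const), design))
  expect_true(all(dd <= 1e-6))

  # alpha = 0.2 truth, 12 replicates, 2000 genes: trend recovers 0.2
  design12 <- make_design(12)
  set.seed(22)
  cm2 <- sim_counts(2000, design12, mu = 200, alpha = 0.2)
  d2 <- estimate_dispersion(cm2, design12)
  expect_lt(abs(attr(d2, "trend_coef")[1] - 0.2), 0.05)
  expect_lt(abs(median(d2) - 0.2), 0.05)
})

test_that("age Wald test is symmetric and matches Poisson GLM in the limit", {
  design <- make_design(3)
  set.seed(31)
  cm <- sim_counts(40, design, mu = 80, alpha = 0.05, lfc_old = 0.7)
  de <- test_age(cm, design)

  # swapping young/old labels flips the sign of the age effect exactly
  flipped <- design
  flipped$age <- ifelse(design$age == "old", "young", "old")
  de_f <- test_age(cm, flipped)
  expect_equal(de_f$log2fc_age, -de$log2fc_age, tolerance = 1e-8)

  # with dispersion -> 0 the Wald statistic matches a Poisson GLM
  disp0 <- setNames(rep(1e-8, nrow(cm)), rownames(cm))
  de0 <- test_age(cm, design, dispersions = disp0)
  s2 <- as.integer(design$strain == "B")
  aold <- as.integer(design$age == "old")
  off <- log(size_factors(cm))
  for (i in c(1, 7, 23)) {
    g <- glm(cm[i, ] ~ s2 + aold, family = poisson, offset = off)
    z_pois <- coef(summary(g))["aold", "z value"]
    z_pkg <- (de0$log2fc_age[i] / de0$se_log2fc[i])
    expect_equal(z_pkg, z_pois, tolerance = 1e-3)
  }
})

test_that("estimates are stable under per-sample rescaling via size factors", {
  design <- make_design(3)
  set.seed(32)
  cm <- sim_counts(200, design, mu = 120, alpha = 0.05, lfc_old = 0.5)
  de1 <- test_age(cm, design)
  m2 <- unclass(cm)
  m2[, 1] <- m2[, 1] * 4L   # quadruple one library
  de2 <- test_age(count_matrix(m2), design)
  expect_lt(median(abs(de2$log2fc_age - de1$log2fc_age)), 0.05)
})

test_that("type-I error is calibrated and injected effects are recovered", {
  design <- make_design(4)
  set.seed(33)
  cm <- sim_counts(2000, design, mu = 100, alpha = 0.05)
  de <- test_age(cm, design)
  frac <- mean(de$p_age < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  # under the global null the BH-significant fraction stays near zero
  expect_lte(mean(de$significant), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))

  # +1 log2 age effect in a 10% subset (a global shift would be absorbed by
  # the size factors and is unidentifiable by design)
  set.seed(34)
  null_part <- sim_counts(1800, design, mu = 100, alpha = 0.05)
  eff_part <- sim_counts(200, design, mu = 100, alpha = 0.05, lfc_old = 1)
  rownames(eff_part) <- sprintf("e%04d", 1:200)
  cm1 <- count_matrix(rbind(unclass(null_part), unclass(eff_part)))
  de1 <- test_age(cm1, design)
  hit <- grepl("^e", de1$feature)
  expect_lt(abs(mean(de1$log2fc_age[hit]) - 1), 0.1)
  expect_gt(mean(de1$significant[hit]), 0.8)
})
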