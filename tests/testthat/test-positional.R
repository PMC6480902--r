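ann_from <- function(starts, ends, chrom = "2L") {
  feature_annotation(data.frame(
    feature = sprintf("g%02d", seq_along(starts)), chrom = chrom,
    start = starts, end = ends, length = ends - starts + 1))
}

test_that("compartment flagging follows 1 bp overlap with half-open BED input", {
  bed <- withr::local_tempfile(fileext = ".bed")
  # BED [150,160) and [200,300) on 0-based half-open coordinates
  writeLines(c("2L\t150\t160\thet", "2L\t200\t300\thet"), bed)
  dom <- read_bed(bed)
  # gene occupying bases 101..200 1-based == BED [100,200)
  ann <- ann_from(c(101, 101), c(200, 200))
  flags <- flag_compartment(ann, dom)
  expect_true(flags[["g01"]])          # overlaps 151..160
  ann2 <- ann_from(50, 100)            # BED [49,100): abuts [100?]
  # gene 50..100 vs domain 151..160 and 201..300: no overlap
  expect_false(flag_compartment(ann2, dom)[["g01"]])
  # half-open abutment: gene ending at base 200 does not reach domain 201..300
  ann3 <- ann_from(161, 200)
  expect_false(flag_compartment(ann3, dom)[["g01"]])

  expect_warning(flag_compartment(ann_from(1, 10, chrom = "chrZZ"), dom),
                 "absent")
})

test_that("flagging equals a per-base brute-force oracle on random input", {
  set.seed(14)
  for (rep in 1:5) {
    gs <- sample(1:500, 12); ge <- gs + sample(5:80, 12, replace = TRUE)
    ds <- sample(1:500, 4); de_ <- ds + sample(5:120, 4, replace = TRUE)
    ann <- ann_from(gs, ge)
    dom <- GenomicRanges::GRanges("2L", IRanges::IRanges(ds, de_))
    flags <- flag_compartment(ann, dom)
    for (i in seq_along(gs)) {
      expect_equal(unname(flags[i]),
                   brute_force_overlap(gs[i], ge[i], ds, de_))
    }
    # invariant to domain order and to splitting a domain in two
    expect_identical(flags, flag_compartment(ann, rev(dom)))
    half <- floor((ds + de_) / 2)
    dom_split <- GenomicRanges::GRanges(
      "2L", IRanges::IRanges(c(ds, half + 1), c(half, de_)))
    expect_identical(flags, flag_compartment(ann, dom_split))
  }
})

test_that("Yates chi-squared reproduces the published 2x2 statistics", {
  # dot-chromosome table: (8, 292; 76, 13913)
  dot <- yates_chi2(matrix(c(8, 292, 76, 13913), 2, 2, byrow = TRUE))
  expect_equal(dot$chi2, 19.172, tolerance = 0.001)
  expect_equal(dot$df, 1)
  expect_lt(dot$p, 1e-4)

  # heterochromatin table: (47, 253; 1648, 12341), two-tailed p = 0.0489
  het <- yates_chi2(matrix(c(47, 253, 1648, 12341), 2, 2, byrow = TRUE))
  expect_equal(het$p, 0.0489, tolerance = 0.0005)

  # perfectly proportional table scores exactly 0 (truncated correction)
  expect_equal(yates_chi2(matrix(c(10, 90, 100, 900), 2, 2))$chi2, 0)

  expect_error(yates_chi2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("Yates chi-squared matches the stats oracle on random tables", {
  set.seed(15)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 40) + 1, 2, 2)
    got <- yates_chi2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("DE x compartment tables match a counting loop", {
  set.seed(16)
  n <- 300
  de <- data.frame(feature = sprintf("g%03d", 1:n),
                   p_age = runif(n), stringsAsFactors = FALSE)
  de$padj_age <- bh_adjust(de$p_age)
  de$significant <- de$padj_age < 0.5
  class(de) <- c("de_result", "data.frame")
  flags <- setNames(runif(n) < 0.2, de$feature)
  tab <- build_de_compartment_table(de, flags)
  hand <- c(0, 0, 0, 0)
  for (i in 1:n) {
    s <- de$significant[i]; f <- flags[[de$feature[i]]]
    k <- if (s && f) 1 else if (s && !f) 2 else if (!s && f) 3 else 4
    hand[k] <- hand[k] + 1
  }
  expect_equal(as.vector(t(tab)), hand)
  expect_equal(sum(tab), n)

  # no significant genes: top row zero, chi-squared refuses the margin
  de0 <- de; de0$significant <- FALSE
  tab0 <- build_de_compartment_table(de0, flags)
  expect_equal(unname(rowSums(tab0))[1], 0)
  expect_error(yates_chi2(tab0), "margin")
})

test_that("compartment shift test is a Welch t-test with power and level", {
  # two genes per group, hand-computed Welch t
  ids <- c("a", "b", "c", "d")
  s <- summary_from_ratios(setNames(c(0.9, 1.3, 0.1, -0.2), ids),
                           setNames(c(0.9, 1.3, 0.1, -0.2), ids))
  flags <- setNames(c(TRUE, TRUE, FALSE, FALSE), ids)
  got <- compartment_shift_test(s, flags, "A")
  hand <- welch_oracle(c(0.9, 1.3), c(0.1, -0.2))
  expect_equal(got$t, hand$t, tolerance = 1e-12)
  expect_equal(got$p, hand$p, tolerance = 1e-12)
  expect_equal(got$mean_difference, 1.1 - (-0.05), tolerance = 1e-12)

  # injected +0.5 shift into the flagged group is detected
  set.seed(18)
  n <- 2500
  ids <- sprintf("g%04d", 1:n)
  r <- rnorm(n, 0, 0.4)
  flags2 <- setNames(c(rep(TRUE, 250), rep(FALSE, n - 250)), ids)
  r[1:250] <- r[1:250] + 0.5
  s2 <- summary_from_ratios(setNames(r, ids), setNames(r, ids))
  expect_lt(compartment_shift_test(s2, flags2, "A")$p, 1e-6)

  # permuted labels: p behaves like a null p-value
  ps <- replicate(20, {
    f <- setNames(sample(flags2), ids)
    compartment_shift_test(s2, f, "A")$p
  })
  expect_gt(max(ps), 0.1)  # not systematically significant
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})
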