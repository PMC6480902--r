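# Independent oracles used to freeze expected values. These deliberately use
# the dumbest correct algorithm and never share code with the implementation.

# exhaustive permutation-test p: enumerate every assignment of one match per
# focal gene and count assignments whose per-strain means all reach the
# observed focal means
enumerate_perm_p <- function(ratios, matches, focal) {
  obs <- colMeans(ratios[focal, , drop = FALSE])
  grid <- do.call(expand.grid, lapply(matches[focal], seq_along))
  hits <- 0
  for (r in seq_len(nrow(grid))) {
    picked <- vapply(seq_along(focal), function(j) {
      matches[[focal[j]]][grid[r, j]]
    }, character(1))
    m <- colMeans(ratios[picked, , drop = FALSE])
    if (all(m >= obs)) hits <- hits + 1
  }
  hits / nrow(grid)
}

# sort-and-scan matching oracle for one focal gene: walk outward from the
# focal gene's expression rank among non-focal genes
brute_force_matches <- function(expr, focal_set, gene, k_up, k_down) {
  cand <- setdiff(names(expr), focal_set)
  cand <- cand[order(expr[cand])]
  below <- cand[expr[cand] < expr[[gene]]]
  above <- cand[expr[cand] >= expr[[gene]]]
  nb <- min(k_down, length(below))
  na_ <- min(k_up, length(above))
  k <- k_up + k_down
  if (nb + na_ < k) {
    nb <- min(length(below), k - na_)
    na_ <- min(length(above), k - nb)
  }
  c(rev(below)[seq_len(nb)], above[seq_len(na_)])
}

# per-base interval overlap oracle on small coordinates (1-based inclusive)
brute_force_overlap <- function(g_start, g_end, d_start, d_end) {
  any(seq(g_start, g_end) %in% unlist(Map(seq, d_start, d_end)))
}

# exact two-sided doubled-tail binomial p by direct summation
binom_sign_oracle <- function(k, n) {
  probs <- vapply(0:n, function(i) choose(n, i) / 2^n, numeric(1))
  lower <- sum(probs[seq_len(k + 1)])
  upper <- sum(probs[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# textbook Welch t on two samples
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
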