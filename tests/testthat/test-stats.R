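# independent brute-force two-sided Fisher p over all tables with the
# observed margins, using only choose()
fisher_two_sided_oracle <- function(tb) {
  a <- tb[1, 1]; r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, support) * choose(r2, c1 - support) / choose(N, c1)
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

test_that("the published overshoot contingency table reproduces the
           printed statistics", {
  tb <- matrix(c(16, 5, 38, 49), 2, 2)
  res <- fisher_exact(tb, tail = "right")
  expect_equal(res$p_right, 0.006854, tolerance = 1e-4)
  expect_equal(res$odds_ratio, 784 / 190, tolerance = 1e-12)
  expect_equal(res$p_two_sided, 0.0137, tolerance = 1e-3)
})

test_that("symmetric and small tables give exact textbook values", {
  res <- fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$odds_ratio, 1)
  res2 <- fisher_exact(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(res2$p_two_sided, 34 / 70, tolerance = 1e-12)
})

test_that("exact tails match enumeration and fisher.test over assorted
           margins up to N = 40", {
  set.seed(8)
  for (i in 1:40) {
    repeat {
      tb <- matrix(rpois(4, 4), 2, 2)
      if (all(rowSums(tb) > 0) && all(colSums(tb) > 0) && sum(tb) <= 40)
        break
    }
    res <- fisher_exact(tb)
    expect_equal(res$p_two_sided, fisher_two_sided_oracle(tb),
                 tolerance = 1e-12)
    expect_equal(res$p_two_sided, fisher.test(tb)$p.value,
                 tolerance = 1e-9)
    # point probabilities over the support sum to one
    m <- sum(tb[1, ]); n2 <- sum(tb[2, ]); k <- sum(tb[, 1])
    supp <- max(0, k - n2):min(k, m)
    expect_equal(sum(dhyper(supp, m, n2, k)), 1, tolerance = 1e-12)
  }
})

test_that("odds-ratio edge cases and input validation", {
  expect_equal(fisher_exact(matrix(c(3, 0, 1, 5), 2, 2))$odds_ratio, Inf)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
  expect_error(fisher_exact(matrix(c(1, 0, 2, 0), 2, 2)), "margins")
})

test_that("Mann-Whitney exact p matches enumeration for separated
           samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)   # 2 / choose(6, 3)
})

test_that("identical samples give the central U and p = 1", {
  x <- c(2, 4, 4, 7)
  res <- mann_whitney_u(x, x)
  expect_equal(res$U, length(x)^2 / 2)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
})

test_that("exact and normal methods agree for moderate samples", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.3)
    pe <- mann_whitney_u(x, y, method = "exact")$p_value
    pn <- mann_whitney_u(x, y, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("exact p equals full-permutation enumeration for n1+n2 <= 12,
           with and without ties", {
  perm_oracle <- function(x, y) {
    pooled <- c(x, y); n1 <- length(x); N <- length(pooled)
    r <- rank(pooled)
    mu <- n1 * length(y) / 2
    obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
  }
  set.seed(99)
  for (i in 1:6) {
    x <- sample(1:8, 5, replace = TRUE)   # ties likely
    y <- sample(1:8, 6, replace = TRUE)
    expect_equal(mann_whitney_u(x, y, method = "exact")$p_value,
                 perm_oracle(x, y), tolerance = 1e-12)
  }
  # tie-free case additionally cross-checked against wilcox.test
  x <- c(1.2, 3.4, 5.1, 2.2, 9.9); y <- c(0.4, 4.4, 6.1, 7.7)
  expect_equal(mann_whitney_u(x, y, method = "exact")$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("kymograph correlation endpoints, symmetry and affine
           invariance", {
  set.seed(3)
  s <- seq(0, 10, 0.5); t <- seq(0, 5, 0.25)
  K <- kinematic_field(s, t, matrix(rnorm(length(s) * length(t)),
                                    length(t), length(s)))
  expect_equal(kymograph_correlation(K, K)$r, 1)
  Kneg <- kinematic_field(s, t, -K$values)
  expect_equal(kymograph_correlation(K, Kneg)$r, -1)
  B <- kinematic_field(s, t, matrix(rnorm(length(s) * length(t)),
                                    length(t), length(s)))
  r1 <- kymograph_correlation(K, B)$r
  expect_equal(kymograph_correlation(B, K)$r, r1, tolerance = 1e-12)
  B2 <- kinematic_field(s, t, 3.2 * B$values + 7)
  expect_equal(kymograph_correlation(K, B2)$r, r1, tolerance = 1e-12)
})

test_that("phase-shifted waves correlate as the analytic inner products", {
  s <- seq(0, 36, by = 0.25)
  t <- seq(0, 23.75, by = 0.25)   # whole number of periods (Tp = 3)
  w0 <- wave_field(wave_params(Tp = 3, vp = 12), s, t)
  wpi <- wave_field(wave_params(Tp = 3, vp = 12, phase = pi), s, t)
  w90 <- wave_field(wave_params(Tp = 3, vp = 12, phase = pi / 2), s, t)
  expect_equal(kymograph_correlation(w0, wpi)$r, -1, tolerance = 1e-6)
  expect_lt(abs(kymograph_correlation(w0, w90)$r), 1e-3)
})

test_that("degenerate correlation inputs are rejected", {
  s <- seq(0, 10, 0.5); t <- seq(0, 5, 0.25)
  K <- kinematic_field(s, t, matrix(rnorm(length(s) * length(t)),
                                    length(t), length(s)))
  const <- kinematic_field(s, t, matrix(2, length(t), length(s)))
  expect_error(kymograph_correlation(K, const), "zero variance")
  tiny <- kinematic_field(c(0, 1), 1:3, matrix(rnorm(6), 3, 2))
  expect_error(kymograph_correlation(tiny, tiny), "at least 10")
})

test_that("cohort comparison handles identical groups, missing values and
           degenerate groups", {
  df <- data.frame(group = rep(c("straight", "tilted"), each = 4),
                   Tp = rep(c(2.9, 3.0, 3.1, 2.8), 2),
                   vp = c(10, 11, 12, 13, 10, 11, 12, NA))
  rep1 <- suppressWarnings(cohort_compare(df))
  expect_equal(rep1$p[rep1$quantity == "Tp"], 1, tolerance = 1e-9)
  expect_equal(rep1$n_tilted[rep1$quantity == "vp"], 3)
  expect_warning(cohort_compare(df), "skipped")
  expect_error(cohort_compare(df[c(1, 5:8), ]), "at least 2")
  expect_error(cohort_compare(df[1:4, ]), "two treatment groups")
})
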