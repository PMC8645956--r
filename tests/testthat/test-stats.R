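test_that("median and IQR follow the weighted-average percentile convention", {
  m5 <- median_iqr(1:5)
  expect_equal(m5$median, 3)
  # SPSS HAVERAGE (type 6): (n+1)p positions -> Q1 = 1.5, Q3 = 4.5
  expect_equal(m5$q1, 1.5)
  expect_equal(m5$q3, 4.5)
  expect_equal(m5$iqr, 3)
  # the conventional type-7 alternative remains available
  expect_equal(median_iqr(1:5, type = 7)$iqr, 2)

  m8 <- median_iqr(1:8)
  expect_equal(m8$median, 4.5)
  # hand enumeration, type 6: positions 2.25 and 6.75
  expect_equal(m8$q1, 2.25)
  expect_equal(m8$q3, 6.75)

  expect_equal(median_iqr(7)$iqr, 0)
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("asymptotic Wilcoxon reproduces the n = 8 significance ladder", {
  # all eight differences positive, no ties: Z = 18/sqrt(51)
  w <- wilcoxon_asymptotic(rep(0, 8), 1:8)
  expect_equal(w$w_plus, 36)
  expect_equal(w$w_minus, 0)
  expect_equal(w$z, 18 / sqrt(51), tolerance = 1e-12)
  expect_equal(round(w$p, 3), 0.012)
  expect_equal(w$w_plus + w$w_minus, w$n_used * (w$n_used + 1) / 2)

  # minority-sign rank sums 1, 2, 3 give the remaining printed p-values
  p_for <- function(neg_rank) {
    d <- 1:8
    d[neg_rank] <- -d[neg_rank]
    wilcoxon_asymptotic(d)$p
  }
  expect_equal(round(p_for(1), 3), 0.017)
  expect_equal(round(p_for(2), 3), 0.025)
  expect_equal(round(p_for(3), 3), 0.036)
})

test_that("Wilcoxon conventions: zeros dropped, ties midranked, symmetry", {
  # antisymmetric differences: Z = 0, p = 1
  w <- wilcoxon_asymptotic(c(-3, -2, -1, 1, 2, 3))
  expect_equal(w$z, 0)
  expect_equal(w$p, 1)
  # zero differences are dropped before ranking
  wz <- wilcoxon_asymptotic(c(0, 0, 1, 2, 3, -4))
  expect_equal(wz$n_used, 4)
  # W statistic agrees with the base implementation (which uses a
  # different p convention) on tied data
  d <- c(1.5, 1.5, -2, 3, 3, 4, -1, 5)
  w2 <- wilcoxon_asymptotic(d)
  base <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                              correct = FALSE))
  expect_equal(w2$w_plus, unname(base$statistic))
  expect_equal(w2$p, base$p.value, tolerance = 1e-12)
  expect_error(wilcoxon_asymptotic(c(0, 0, 1)), "fewer than 2")
})

test_that("Spearman rho and t-approximation p match closed forms", {
  s <- spearman(1:8, perm_sd2_22)
  expect_equal(s$rho, 1 - 6 * 22 / (8 * 63), tolerance = 1e-12)
  expect_equal(s$rho, 0.738, tolerance = 1e-3)
  expect_equal(s$t, s$rho * sqrt(6 / (1 - s$rho^2)), tolerance = 1e-12)
  expect_equal(round(s$p, 3), 0.037)

  # perfectly monotone: rho 1, degenerate p
  sm <- spearman(1:10, (1:10)^3)
  expect_equal(sm$rho, 1)
  expect_true(sm$degenerate)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 2:1), "n >= 3")
})

test_that("Spearman is rank-based: monotone-invariant, midranks equal d2 form", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(9)
    y <- rnorm(9)
    s0 <- spearman(x, y)
    expect_equal(spearman(exp(x), y)$rho, s0$rho, tolerance = 1e-12)
    expect_equal(spearman(x, 5 - 2 * atan(y) * -1)$rho, s0$rho,
                 tolerance = 1e-12)
    # no ties: midrank Pearson equals 1 - 6 sum d^2 / (n(n^2-1))
    d2 <- sum((rank(x) - rank(y))^2)
    expect_equal(s0$rho, 1 - 6 * d2 / (9 * 80), tolerance = 1e-12)
    # cross-check against the base implementation
    expect_equal(s0$rho, unname(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("correlation panel mirrors rank invariance across proportional columns", {
  co <- simulate_cohort(seed = 8)
  df <- co$animals
  panel <- correlation_panel(df, outcome = "delta_kis",
                             variables = c("mp", "mp_elastic",
                                           "mp_resistive", "ppeak",
                                           "absent_column"))
  expect_equal(attr(panel, "skipped"), "absent_column")
  rows <- panel[panel$variable %in% c("mp", "mp_elastic", "mp_resistive"), ]
  expect_equal(length(unique(round(rows$rho, 12))), 1L)
  expect_equal(length(unique(round(rows$p, 12))), 1L)
  expect_error(correlation_panel(df, outcome = "nope"), "outcome")
})

test_that("null variables show near-zero median rho across seeds", {
  rhos <- vapply(1:60, function(s) {
    co <- simulate_cohort(seed = s)
    spearman(co$animals$ppeak, co$animals$delta_kis)$rho
  }, numeric(1))
  expect_lt(abs(median(rhos)), 0.15)
})
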