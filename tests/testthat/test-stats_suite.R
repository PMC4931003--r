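test_that("Mann-Whitney U uses the min-U convention and the U identity holds", {
  r1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # complete separation
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 2 / choose(6, 3))     # enumeration: 2 of 20 splits
  r2 <- mann_whitney_u(c(1, 3, 5), c(2, 4, 6))   # interleaved, 3 wins of 9
  expect_equal(r2$statistic, 3)

  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1))
    r <- mann_whitney_u(a, b)
    expect_equal(r$u_a + r$u_b, length(a) * length(b))
    expect_equal(r$statistic, min(r$u_a, r$u_b))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney enumeration matches the reference distribution", {
  # tie-free case: the exact branch must reproduce wilcox.test's exact p
  set.seed(88)
  for (i in 1:25) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1))
    ours <- mann_whitney_u(a, b)$p_value
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation branches agree at moderate n", {
  set.seed(19)
  diffs <- replicate(100, {
    a <- round(rnorm(15, 0, 2), 1)   # rounding induces ties
    b <- round(rnorm(15, 0.4, 2), 1)
    p_exact <- mann_whitney_u(a, b, method = "exact")$p_value
    p_norm <- mann_whitney_u(a, b, method = "normal")$p_value
    abs(p_exact - p_norm)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("Kruskal-Wallis matches the hand-ranked instance and rank invariance", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)   # rank-sum formula by hand, no ties
  expect_equal(r$df, 2)
  # independent route: base kruskal.test on the same data
  ref <- stats::kruskal.test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)

  # monotone transformation of the values leaves ranks, hence H, unchanged
  r2 <- kruskal_wallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6)), exp(c(7, 8, 9))))
  expect_equal(r2$statistic, r$statistic)

  r3 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r3$statistic, 0)

  expect_warning(r4 <- kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_equal(r4$statistic, 0)
  expect_equal(r4$p_value, 1)
})

test_that("Nemenyi post hoc is symmetric, calibrated on nulls, sharp on separation", {
  set.seed(55)
  same <- lapply(1:3, function(i) rep(c(5, 6, 7), 4))
  p_same <- nemenyi_posthoc(same)
  expect_true(all(p_same[upper.tri(p_same)] > 0.99))
  expect_equal(p_same, t(p_same))
  expect_true(all(diag(p_same) == 1))

  far <- list(rnorm(50, 0), rnorm(50, 10), rnorm(50, 20))
  for (m in c("chisq", "tukey")) {
    p_far <- nemenyi_posthoc(far, method = m)
    expect_true(all(p_far[upper.tri(p_far)] < 0.001))
    expect_equal(p_far, t(p_far), ignore_attr = TRUE)
  }
  # unequal group sizes route to the chi-square variant
  uneq <- list(rnorm(10), rnorm(20), rnorm(30))
  expect_identical(attr(nemenyi_posthoc(uneq), "method"), "chisq")
  expect_error(nemenyi_posthoc(list(1:3, 1:3)), ">= 3")
})

test_that("one-way ANOVA matches its F contract", {
  r0 <- oneway_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r1 <- oneway_anova(c(1, 1, 1.001), c(5, 5, 5.001))
  expect_lt(r1$p_value, 1e-8)

  expect_error(oneway_anova(c(2, 2), c(2, 2)), "undefined")

  set.seed(4)
  f_null <- replicate(500, {
    oneway_anova(rnorm(20), rnorm(20))$statistic
  })
  # under the null E[F] = dfe/(dfe-2) = 38/36
  expect_equal(mean(f_null), 38 / 36, tolerance = 0.2)
})

test_that("two-way interaction F comes from full-vs-additive model comparison", {
  # exactly additive cell means, duplicated replicates: no interaction signal
  g1 <- rep(c("t_b", "t_a", "t_s"), each = 4)
  g2 <- rep(rep(c("era1", "era2"), each = 2), times = 3)
  add_means <- c(10, 10, 13, 13, 20, 20, 23, 23, 30, 30, 33, 33)
  r_add <- twoway_interaction(add_means, g1, g2)
  expect_equal(r_add$statistic, 0)
  expect_equal(r_add$p_value, 1)

  # one cell shifted by +10 with no noise: interaction certain
  shifted <- add_means + ifelse(g1 == "t_b" & g2 == "era2", 10, 0)
  shifted <- shifted + rep(c(-0.01, 0.01), 6)   # tiny within-cell spread
  r_shift <- twoway_interaction(shifted, g1, g2)
  expect_lt(r_shift$p_value, 1e-10)

  # balanced 2x2: frozen against explicit model-comparison arithmetic
  # (cells A1 = {1,2}, A2 = {3,5}, B1 = {2,3}, B2 = {7,9}: SSE_full = 5,
  # interaction SS = 4.5, F = (4.5/1)/(5/4) = 3.6 on df (1, 4))
  val <- c(1, 2, 3, 5, 2, 3, 7, 9)
  fa <- rep(c("A", "A", "B", "B"), each = 2)
  fb <- rep(c("1", "2", "1", "2"), each = 2)
  r22 <- twoway_interaction(val, fa, fb)
  expect_equal(r22$statistic, 3.6)
  expect_equal(r22$df, c(1, 4))
  expect_equal(r22$p_value, pf(3.6, 1, 4, lower.tail = FALSE))

  expect_error(twoway_interaction(c(1, 2, 3), c("a", "a", "b"),
                                  c("x", "y", "x")),
               "empty design cell")
  expect_error(twoway_interaction(c(1, 2), c("a", "a"), c("x", "x")),
               "2 levels")
})

test_that("linear regression returns OLS slope, intercept, R2 and residual sd", {
  exact <- linear_regression(1:20, 2 + 3 * (1:20))
  expect_equal(exact$slope, 3)
  expect_equal(exact$intercept, 2)
  expect_equal(exact$r_squared, 1)

  hand <- linear_regression(c(0, 1, 2), c(0, 2, 3))
  expect_equal(hand$slope, 1.5)
  expect_equal(hand$intercept, 1 / 6, tolerance = 1e-10)
  expect_equal(hand$r_squared, 27 / 28, tolerance = 1e-10)

  set.seed(2)
  x <- rnorm(2000); y <- rnorm(2000)
  expect_lt(linear_regression(x, y)$r_squared, 0.01)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "constant x")
})

test_that("ANCOVA slope homogeneity matches explicit SSE comparison", {
  # no-lm oracle: per-group and pooled-slope SSEs from sufficient statistics
  sse_pair <- function(x, y, g) {
    stats_g <- lapply(split(seq_along(x), g), function(i) {
      xs <- x[i]; ys <- y[i]
      c(sxx = sum((xs - mean(xs))^2), sxy = sum((xs - mean(xs)) * (ys - mean(ys))),
        syy = sum((ys - mean(ys))^2))
    })
    sep <- sum(vapply(stats_g, function(s) s["syy"] - s["sxy"]^2 / s["sxx"],
                      numeric(1)))
    b <- sum(vapply(stats_g, `[[`, numeric(1), "sxy")) /
      sum(vapply(stats_g, `[[`, numeric(1), "sxx"))
    common <- sum(vapply(stats_g, function(s)
      s["syy"] - 2 * b * s["sxy"] + b^2 * s["sxx"], numeric(1)))
    n <- length(x)
    ((common - sep) / 1) / (sep / (n - 4))
  }
  set.seed(12)
  x <- c(rnorm(6, 20, 3), rnorm(7, 24, 3))
  g <- rep(c("era1", "era2"), c(6, 7))
  y <- ifelse(g == "era1", 16 + 0.55 * x, 20 + 0.42 * x) + rnorm(13, 0, 2)
  r <- ancova_slope_homogeneity(x, y, g)
  expect_equal(r$statistic, sse_pair(x, y, g), tolerance = 1e-10)
  expect_equal(r$df, c(1, 13 - 4))

  # both groups on one exact line: zero interaction evidence
  x2 <- c(1:6, 2:7); g2 <- rep(c("a", "b"), each = 6)
  r_same <- ancova_slope_homogeneity(x2, 2 + 3 * x2, g2)
  expect_equal(r_same$statistic, 0)
  expect_equal(r_same$p_value, 1)

  # opposite slopes, tiny noise: certain difference
  y3 <- ifelse(g2 == "a", 0.55 * x2, -0.55 * x2) + rep(c(-0.001, 0.001), 6)
  expect_lt(ancova_slope_homogeneity(x2, y3, g2)$p_value, 1e-10)

  expect_error(ancova_slope_homogeneity(c(1, 1, 1, 1:3), rnorm(6),
                                        rep(c("a", "b"), each = 3)),
               "constant x")
})

test_that("rank and parametric routes agree on the direction of separation", {
  set.seed(66)
  groups <- list(rnorm(30, 0), rnorm(30, 2), rnorm(30, 4))
  kw <- kruskal_wallis(groups)
  av <- oneway_anova(groups)
  expect_lt(kw$p_value, 0.001)
  expect_lt(av$p_value, 0.001)
  # group mean ranks and group means order identically
  ranks <- rank(unlist(groups))
  gi <- rep(1:3, each = 30)
  expect_equal(order(tapply(ranks, gi, mean)),
               order(vapply(groups, mean, numeric(1))))
})
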