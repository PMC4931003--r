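# Inferential machinery used by the analysis. Classical models (ANOVA,
# regression, ANCOVA, Kruskal-Wallis) delegate to base stats; the Mann-Whitney
# U convention (min(U_a, U_b), exact enumeration under ties) and the Nemenyi
# post hoc are implemented here because no installed package provides them.

test_result <- function(name, statistic, df, p_value, n, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    c(list(name = name, statistic = unname(statistic), df = unname(df),
           p_value = min(1, unname(p_value)), n = unname(n)), list(...)),
    class = "thermo_test"
  )
}

#' @export
print.thermo_test <- function(x, ...) {
  cat(x$name, ": statistic = ", format(x$statistic, digits = 6),
      ", df = ", paste(format(x$df, digits = 4), collapse = ", "),
      ", p = ", format.pval(x$p_value, digits = 4),
      " (n = ", paste(x$n, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Exact null distribution of the rank sum of group a under permutation of the
# pooled midranks. Midranks are half-integers, so doubling gives an integer
# subset-sum DP: ways[k, s] = number of size-k subsets with doubled-rank sum s.
rank_sum_distribution <- function(ranks2, n_a) {
  total <- sum(ranks2)
  ways <- matrix(0, nrow = n_a + 1L, ncol = total + 1L)
  ways[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- n_a
    for (k in kmax:1) {
      src <- ways[k, 1:(total + 1L - r)]
      if (any(src > 0)) {
        idx <- (r + 1L):(total + 1L)
        ways[k + 1L, idx] <- ways[k + 1L, idx] + src
      }
    }
  }
  counts <- ways[n_a + 1L, ]
  list(sums2 = 0:total, counts = counts, total = sum(counts))
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples using midranks for ties. The
#' statistic is reported as `min(U_a, U_b)`. For `min(n_a, n_b) <= 20` the
#' p-value is computed by exact enumeration of the permutation distribution of
#' the rank sum (a subset-sum count over the tied midranks, both tails around
#' the null mean); for larger samples the normal approximation with tie
#' correction and continuity correction is used. Two-sided throughout.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param method `"auto"` (the size rule above), or force `"exact"` /
#'   `"normal"`.
#' @return A `"thermo_test"` with `statistic` = min(U_a, U_b), `u_a`, `u_b`,
#'   and the branch used (`method`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  stopifnot(is.numeric(a), is.numeric(b), all(is.finite(c(a, b))))
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))                      # midranks
  ra <- sum(r[seq_len(n_a)])
  u_a <- ra - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  u <- min(u_a, u_b)
  if (method == "auto") {
    method <- if (min(n_a, n_b) <= 20L) "exact" else "normal"
  }

  if (method == "exact") {
    dist <- rank_sum_distribution(as.integer(round(2 * r)), n_a)
    # rank sums symmetric target: two tails around the null mean of U_a
    u_vals <- (dist$sums2 / 2) - n_a * (n_a + 1) / 2
    mu <- n_a * n_b / 2
    dev <- abs(u - mu)
    in_tail <- u_vals <= mu - dev + 1e-9 | u_vals >= mu + dev - 1e-9
    p <- sum(dist$counts[in_tail]) / dist$total
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (n_a * n_b / 12) * ((n + 1) - tie_term)
    z <- (abs(u_a - n_a * n_b / 2) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(0, z))
  }
  test_result("Mann-Whitney U", u, df = NA_real_, p_value = p,
              n = c(n_a, n_b), u_a = u_a, u_b = u_b, method = method)
}

#' Kruskal-Wallis rank test
#'
#' Omnibus rank test across k groups with tie correction (delegates to
#' [stats::kruskal.test()]). When every pooled value is identical the tie
#' correction degenerates; the test is then reported as H = 0, p = 1 with a
#' warning.
#'
#' @param groups List of numeric samples (>= 2 groups, each non-empty).
#' @return A `"thermo_test"` with H, df = k - 1 and the chi-square p-value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    warning("all pooled values identical: H defined as 0, p = 1")
    return(test_result("Kruskal-Wallis", 0, df = length(groups) - 1,
                       p_value = 1, n = lengths(groups)))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  test_result("Kruskal-Wallis", kt$statistic, df = kt$parameter,
              p_value = kt$p.value, n = lengths(groups))
}

#' Nemenyi post hoc comparisons after Kruskal-Wallis
#'
#' All-pairs comparisons on pooled mean ranks. Two variants: the chi-square
#' variant (with tie correction; valid for unequal group sizes, the default
#' when sizes differ) and the studentized-range variant (classical Nemenyi for
#' equal sizes).
#'
#' @param groups List of >= 3 non-empty numeric samples.
#' @param method `"auto"` (chi-square if sizes unequal, studentized range if
#'   equal), `"chisq"`, or `"tukey"`.
#' @return A symmetric matrix of two-sided p-values with unit diagonal;
#'   attribute `"method"` records the variant used.
#' @export
nemenyi_posthoc <- function(groups, method = c("auto", "chisq", "tukey")) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  k <- length(groups)
  ns <- lengths(groups)
  if (method == "auto") {
    method <- if (length(unique(ns)) == 1L) "tukey" else "chisq"
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), ns)
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)

  p <- matrix(1, k, k)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  dimnames(p) <- list(nm, nm)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- abs(rbar[i] - rbar[j])
      v <- (n * (n + 1) / 12) * (1 / ns[i] + 1 / ns[j])
      if (method == "chisq") {
        stat <- d^2 / v
        if (C > 0) stat <- stat / C
        pij <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
      } else {
        q <- d / sqrt(v)
        pij <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf,
                             lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  attr(p, "method") <- method
  p
}

#' One-way analysis of variance
#'
#' Classical F-test of equal group means (delegates to [stats::lm()] /
#' [stats::anova()]).
#'
#' @param ... Two or more numeric samples (each with >= 2 values), or a single
#'   list of them.
#' @return A `"thermo_test"` with F, df = (k - 1, N - k) and p.
#' @export
oneway_anova <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]]) &&
      !is.numeric(groups[[1L]])) {
    groups <- groups[[1L]]
  }
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  means <- tapply(x, g, mean)
  within_var <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (within_var == 0 && max(means) - min(means) == 0) {
    stop("zero within-group variance with equal means: F is undefined (0/0)")
  }
  fit <- stats::anova(stats::lm(x ~ g))
  f <- fit$`F value`[1L]
  p <- fit$`Pr(>F)`[1L]
  if (within_var == 0) { f <- Inf; p <- 0 }
  test_result("one-way ANOVA", f, df = c(fit$Df[1L], fit$Df[2L]),
              p_value = p, n = lengths(groups))
}

# Model-comparison F with explicit handling of numerically saturated fits:
# when the full model's residual SS is zero to machine precision the F ratio
# is pure rounding noise, so report F = 0, p = 1 unless the comparison SS is
# itself non-negligible (then the evidence is unbounded: F = Inf, p = 0).
degenerate_f <- function(cmp, total_ss) {
  f <- cmp$F[2L]; p <- cmp$`Pr(>F)`[2L]
  tol <- 1e-10 * max(total_ss, 1)
  if (cmp$RSS[2L] <= tol) {
    if (abs(cmp$`Sum of Sq`[2L]) <= tol) { f <- 0; p <- 1 }
    else { f <- Inf; p <- 0 }
  } else if (is.na(f)) { f <- 0; p <- 1 }
  c(f, p)
}

#' Two-way interaction test (temperature type x era)
#'
#' Tests the interaction between two crossed factors on a response by model
#' comparison: the full two-way linear model against the additive
#' (no-interaction) model. Model-comparison sums of squares handle unbalanced
#' cells.
#'
#' @param value Numeric response (e.g. temperature, degrees C).
#' @param factor_a,factor_b Factors or labels (e.g. temperature type and era).
#' @return A `"thermo_test"` with the interaction F, its df pair, and p.
#' @export
twoway_interaction <- function(value, factor_a, factor_b) {
  stopifnot(is.numeric(value),
            length(value) == length(factor_a),
            length(value) == length(factor_b))
  fa <- factor(factor_a); fb <- factor(factor_b)
  cells <- table(fa, fb)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop("empty design cell: ", levels(fa)[empty[1L]], " x ",
         levels(fb)[empty[2L]])
  }
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    stop("both factors need at least 2 levels for an interaction")
  }
  full <- stats::lm(value ~ fa * fb)
  add  <- stats::lm(value ~ fa + fb)
  cmp <- stats::anova(add, full)
  fp <- degenerate_f(cmp, sum((value - mean(value))^2))
  f <- fp[1L]; p <- fp[2L]
  test_result("two-way interaction", f,
              df = c(cmp$Df[2L], cmp$Res.Df[2L]), p_value = p,
              n = length(value))
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y Numeric vectors of equal length, n >= 3; `x` must vary.
#' @return An object of class `"regression_fit"`: `slope`, `intercept`,
#'   `r_squared`, `n`, `residual_sd`.
#' @examples
#' linear_regression(c(0, 1, 2), c(0, 2, 3))
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete (x, y) pairs")
  if (stats::var(x) == 0) stop("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = if (tss > 0) 1 - rss / tss else 0,
         n = length(x),
         residual_sd = sqrt(rss / (length(x) - 2L))),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.2f + %.2f x  (R2 = %.3f, n = %d, residual sd = %.2f)\n",
              x$intercept, x$slope, x$r_squared, x$n, x$residual_sd))
  invisible(x)
}

#' ANCOVA test of slope homogeneity between two groups
#'
#' Compares the separate-slopes model `y ~ x * group` against the common-slope
#' model `y ~ x + group`; the F-test on the interaction term (df = 1, n - 4
#' for two groups) asks whether the regression slopes differ between groups.
#'
#' @param x Covariate; @param y response; @param group two-level labels.
#' @return A `"thermo_test"` with the interaction F, df, p, and the per-group
#'   [linear_regression()] fits in `$fits`.
#' @export
ancova_slope_homogeneity <- function(x, y, group) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  for (lev in levels(g)) {
    xs <- x[g == lev]
    if (length(xs) < 3L) stop("group '", lev, "' has fewer than 3 observations")
    if (stats::var(xs) == 0) stop("group '", lev, "' has constant x")
  }
  full <- stats::lm(y ~ x * g)
  common <- stats::lm(y ~ x + g)
  cmp <- stats::anova(common, full)
  fp <- degenerate_f(cmp, sum((y - mean(y))^2))
  f <- fp[1L]; p <- fp[2L]
  fits <- lapply(levels(g), function(lev)
    linear_regression(x[g == lev], y[g == lev]))
  names(fits) <- levels(g)
  test_result("ANCOVA slope homogeneity", f,
              df = c(cmp$Df[2L], cmp$Res.Df[2L]), p_value = p,
              n = as.vector(table(g)), fits = fits)
}
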