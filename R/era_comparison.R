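#' Default per-variable location-test routing
#'
#' Which location test compares the two eras for each temperature variable.
#' The default mirrors the analysis design for this system: rank-based
#' Mann-Whitney for body and substrate temperature (whose field distributions
#' depart from normality), classical ANOVA for air temperature.
#' @export
default_test_routing <- function() {
  c(t_b = "mann_whitney", t_a = "anova", t_s = "mann_whitney")
}

era_var_summary <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}

#' Two-era comparison of field thermal biology
#'
#' Contrasts two sampling eras of capture records. For each of body (`t_b`),
#' air (`t_a`) and substrate (`t_s`) temperature it reports era means +/- SE
#' with n, the delta (era 2 minus era 1) and a location test routed per
#' variable (Mann-Whitney or one-way ANOVA). It then fits era-wise OLS
#' regressions of `t_b` on `t_a` and on `t_s` with ANCOVA slope-homogeneity
#' tests, runs the 3 x 2 temperature-type by era interaction on the pooled
#' long-format data, and quantifies behavioural buffering as
#' `delta(t_b) / delta(t_a)` and `delta(t_b) / delta(t_s)`.
#'
#' @param records_a,records_b Data frames of capture records for eras 1 and 2
#'   (columns `t_b`, `t_a`, `t_s`, possibly with NAs; `era` labels optional).
#' @param routing Named character map variable -> test
#'   (`"mann_whitney"`/`"anova"`), default [default_test_routing()].
#' @return An object of class `"era_comparison"`: per-variable summaries,
#'   deltas and tests; regression pairs and slope-homogeneity tests per
#'   predictor; the interaction test; buffering ratios.
#' @export
compare_eras <- function(records_a, records_b, routing = default_test_routing()) {
  vars <- c("t_b", "t_a", "t_s")
  for (df in list(records_a, records_b)) {
    miss <- setdiff(vars, names(df))
    if (length(miss)) stop("capture records missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  if (nrow(records_a) == 0L || nrow(records_b) == 0L) {
    stop("both eras must contain records")
  }
  for (v in vars) {
    for (nmdf in list(a = records_a, b = records_b)) {
      if (mean(!is.finite(nmdf[[v]])) > 0.5) {
        stop("variable ", v, " missing in more than half of an era's records")
      }
    }
  }

  era_lab <- c(
    if (!is.null(records_a$era)) as.character(records_a$era[1L]) else "era1",
    if (!is.null(records_b$era)) as.character(records_b$era[1L]) else "era2"
  )

  variables <- lapply(vars, function(v) {
    xa <- records_a[[v]][is.finite(records_a[[v]])]
    xb <- records_b[[v]][is.finite(records_b[[v]])]
    sa <- era_var_summary(xa); sb <- era_var_summary(xb)
    test <- switch(routing[[v]],
      mann_whitney = mann_whitney_u(xa, xb),
      anova = oneway_anova(xa, xb),
      stop("unknown test routing '", routing[[v]], "' for ", v)
    )
    list(variable = v, era1 = sa, era2 = sb,
         delta = sb$mean - sa$mean, test = test)
  })
  names(variables) <- vars
  deltas <- vapply(variables, `[[`, numeric(1L), "delta")

  # era-wise T_b regressions on each predictor + slope homogeneity
  regressions <- lapply(c(t_a = "t_a", t_s = "t_s"), function(pred) {
    ok_a <- is.finite(records_a$t_b) & is.finite(records_a[[pred]])
    ok_b <- is.finite(records_b$t_b) & is.finite(records_b[[pred]])
    x <- c(records_a[[pred]][ok_a], records_b[[pred]][ok_b])
    y <- c(records_a$t_b[ok_a], records_b$t_b[ok_b])
    g <- rep(era_lab, c(sum(ok_a), sum(ok_b)))
    hom <- ancova_slope_homogeneity(x, y, g)
    list(predictor = pred, fits = hom$fits, slope_homogeneity = hom)
  })

  # pooled long format for the type x era interaction
  long <- do.call(rbind, lapply(seq_along(vars), function(i) {
    v <- vars[i]
    rbind(
      data.frame(value = records_a[[v]], type = v, era = era_lab[1L]),
      data.frame(value = records_b[[v]], type = v, era = era_lab[2L])
    )
  }))
  long <- long[is.finite(long$value), , drop = FALSE]
  interaction <- twoway_interaction(long$value, long$type, long$era)

  structure(
    list(
      era_labels = era_lab,
      variables = variables,
      deltas = deltas,
      interaction = interaction,
      regressions = regressions,
      buffering_ratio = c(vs_t_a = unname(deltas["t_b"] / deltas["t_a"]),
                          vs_t_s = unname(deltas["t_b"] / deltas["t_s"]))
    ),
    class = "era_comparison"
  )
}

#' @export
print.era_comparison <- function(x, ...) {
  cat("Era comparison:", x$era_labels[1L], "vs", x$era_labels[2L], "\n")
  for (v in x$variables) {
    cat(sprintf("  %-3s  %.2f +/- %.2f (%d)  ->  %.2f +/- %.2f (%d)   delta %+ .2f   [%s, p = %s]\n",
                v$variable, v$era1$mean, v$era1$se, v$era1$n,
                v$era2$mean, v$era2$se, v$era2$n, v$delta,
                v$test$name, format.pval(v$test$p_value, digits = 3)))
  }
  cat(sprintf("  type x era interaction: F = %.3f, p = %s\n",
              x$interaction$statistic,
              format.pval(x$interaction$p_value, digits = 3)))
  for (r in x$regressions) {
    cat(sprintf("  t_b ~ %s slope homogeneity: F = %.3f, p = %s\n",
                r$predictor, r$slope_homogeneity$statistic,
                format.pval(r$slope_homogeneity$p_value, digits = 3)))
  }
  cat(sprintf("  buffering ratio delta(t_b)/delta(t_a) = %.2f, delta(t_b)/delta(t_s) = %.2f\n",
              x$buffering_ratio["vs_t_a"], x$buffering_ratio["vs_t_s"]))
  invisible(x)
}

#' Check whether the sexes can be pooled
#'
#' One-way ANOVA of body temperature by sex; a non-significant difference
#' (p > alpha) supports pooling males and females in the downstream analysis.
#'
#' @param records Capture records with `t_b` and `sex` columns (both
#'   `"male"` and `"female"` present).
#' @param alpha Significance level for the pooling recommendation.
#' @return A `"thermo_test"` with an extra logical field `pool`.
#' @export
sex_pooling_check <- function(records, alpha = 0.05) {
  stopifnot(all(c("t_b", "sex") %in% names(records)))
  records <- records[records$sex %in% c("male", "female") &
                       is.finite(records$t_b), , drop = FALSE]
  sexes <- unique(records$sex)
  if (length(sexes) < 2L) stop("both sexes must be present")
  res <- oneway_anova(split(records$t_b, records$sex))
  res$pool <- res$p_value > alpha
  res$name <- "sex pooling (one-way ANOVA of t_b)"
  res
}
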