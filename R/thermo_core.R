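#' Preferred temperature range object
#'
#' Constructs a preferred temperature range (PTR): the interval of set-point
#' body temperatures an ectotherm selects in a cost-free laboratory thermal
#' gradient. In the Hertz protocol all deviation indices (`d_b`, `d_e`) are
#' measured relative to this interval.
#'
#' @param lower Lower bound, degrees C.
#' @param upper Upper bound, degrees C (must be >= `lower`).
#' @param central_fraction Fraction of central gradient selections the interval
#'   was defined from (default 0.5, the central 50 percent).
#' @return An object of class `"ptr"` with fields `lower`, `upper`,
#'   `central_fraction`.
#' @examples
#' ptr_range(31.18, 32.50)
#' @export
ptr_range <- function(lower, upper, central_fraction = 0.5) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(upper))
  if (upper < lower) {
    stop("invalid preferred range: upper (", upper, ") < lower (", lower, ")")
  }
  if (!is.numeric(central_fraction) || central_fraction <= 0 ||
      central_fraction > 1) {
    stop("central_fraction must lie in (0, 1]")
  }
  structure(
    list(lower = lower, upper = upper, central_fraction = central_fraction),
    class = "ptr"
  )
}

#' @export
print.ptr <- function(x, ...) {
  cat(sprintf("Preferred temperature range: [%.2f, %.2f] degC (breadth %.2f, central %d%%)\n",
              x$lower, x$upper, x$upper - x$lower,
              round(100 * x$central_fraction)))
  invisible(x)
}

#' Deviation of a temperature from the preferred range
#'
#' The Hertz deviation: zero for temperatures inside the set-point range and
#' the distance to the nearer bound outside it. Applied to field body
#' temperatures it yields `d_b` (accuracy of thermoregulation); applied to
#' operative temperatures it yields `d_e` (thermal quality of habitat).
#'
#' @param t Numeric vector of temperatures, degrees C.
#' @param ptr A [ptr_range()] object.
#' @return Non-negative deviations, same length as `t`.
#' @examples
#' deviation_from_range(c(30.34, 31.8, 35), ptr_range(31.18, 32.50))
#' @export
deviation_from_range <- function(t, ptr) {
  stopifnot(inherits(ptr, "ptr"))
  if (!is.numeric(t) || length(t) == 0L) {
    stop("temperatures must be a non-empty numeric vector")
  }
  if (any(!is.finite(t))) {
    stop("non-finite temperature in input: deviations are undefined")
  }
  pmax(0, ptr$lower - t, t - ptr$upper)
}

#' Deviation set for a sample of temperatures
#'
#' Element-wise deviations of a temperature sample from the preferred range,
#' tagged with their source (`"body"` for d_b, `"operative"` for d_e).
#'
#' @param temps Non-empty numeric vector of temperatures, degrees C.
#' @inheritParams deviation_from_range
#' @param source `"body"` or `"operative"`.
#' @return An object of class `"deviation_set"`: list with `values` (ordered as
#'   the input) and `source`.
#' @export
compute_deviation_set <- function(temps, ptr, source = c("body", "operative")) {
  source <- match.arg(source)
  if (length(temps) == 0L) {
    stop("empty ", source, " temperature sample: cannot compute deviations")
  }
  structure(
    list(values = deviation_from_range(temps, ptr), source = source),
    class = "deviation_set"
  )
}

#' Effectiveness of thermoregulation
#'
#' Hertz's index E = 1 - mean(d_b) / mean(d_e). E = 1 for a perfect
#' thermoregulator (body temperatures always in the set-point range), E = 0
#' for a thermoconformer (body deviations as large as the habitat's), and
#' E < 0 for an animal that avoids thermally suitable sites.
#'
#' @param mean_db Mean body-temperature deviation (accuracy), degrees C, >= 0.
#' @param mean_de Mean operative-temperature deviation (habitat thermal
#'   quality), degrees C, > 0.
#' @return The dimensionless index, <= 1.
#' @examples
#' effectiveness_index(1.44, 9.96)  # ~0.855
#' @export
effectiveness_index <- function(mean_db, mean_de) {
  stopifnot(is.numeric(mean_db), is.numeric(mean_de),
            is.finite(mean_db), is.finite(mean_de))
  if (mean_db < 0) stop("mean_db must be non-negative")
  if (mean_de < 0) stop("mean_de must be non-negative")
  if (mean_de == 0) {
    stop("mean_de is zero: habitat matches the preferred range everywhere, ",
         "the effectiveness index is undefined")
  }
  1 - mean_db / mean_de
}

#' Bootstrap pseudo-distributions of the thermoregulation indices
#'
#' Resamples the body-deviation and operative-deviation sets independently
#' (they are unpaired by design: tens of lizards vs thousands of logger
#' readings). Each resample draws, with replacement, a sample of the original
#' size from each set and computes its mean d_b*, mean d_e* and
#' E* = 1 - mean d_b* / mean d_e*. The pseudo-distribution mean and standard
#' deviation (reported as the standard error) summarise each index.
#'
#' Resamples in which mean d_e* = 0 leave E* undefined; such resamples are
#' excluded from the E summary and counted in `n_undefined_e`.
#'
#' @param db A `"body"` [compute_deviation_set()] result.
#' @param de An `"operative"` [compute_deviation_set()] result.
#' @param n_resamples Number of bootstrap resamples (default 500).
#' @param seed Integer seed; identical seeds give identical summaries.
#' @return An object of class `"thermoreg_summary"` with the point estimates
#'   (`mean_db`, `mean_de`, `e_index`), their bootstrap standard errors
#'   (`se_db`, `se_de`, `se_e`), sample sizes, the resample count and seed.
#' @export
bootstrap_thermoreg <- function(db, de, n_resamples = 500L, seed) {
  stopifnot(inherits(db, "deviation_set"), inherits(de, "deviation_set"))
  if (length(db$values) == 0L || length(de$values) == 0L) {
    stop("deviation sets must be non-empty")
  }
  if (!is.numeric(n_resamples) || n_resamples < 1L) {
    stop("n_resamples must be >= 1")
  }
  if (missing(seed)) stop("an explicit seed is required")
  n_resamples <- as.integer(n_resamples)
  nb <- length(db$values)
  ne <- length(de$values)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  db_star <- numeric(n_resamples)
  de_star <- numeric(n_resamples)
  for (i in seq_len(n_resamples)) {
    db_star[i] <- mean(db$values[sample.int(nb, nb, replace = TRUE)])
    de_star[i] <- mean(de$values[sample.int(ne, ne, replace = TRUE)])
  }
  defined <- de_star > 0
  n_undef <- sum(!defined)
  if (n_undef > 0L) {
    message(n_undef, " resample(s) had mean d_e* = 0; E* undefined there and excluded")
  }
  e_star <- 1 - db_star[defined] / de_star[defined]

  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0

  structure(
    list(
      mean_db = mean(db_star), se_db = sd0(db_star),
      mean_de = mean(de_star), se_de = sd0(de_star),
      e_index = if (length(e_star)) mean(e_star) else NA_real_,
      se_e = sd0(e_star),
      n_resamples = n_resamples, seed = as.integer(seed),
      n_body = nb, n_operative = ne, n_undefined_e = n_undef
    ),
    class = "thermoreg_summary"
  )
}

#' @export
print.thermoreg_summary <- function(x, digits = 3, ...) {
  cat("Bootstrap thermoregulation indices (", x$n_resamples, " resamples, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  accuracy        mean d_b = %.*f +/- %.*f degC (n = %d)\n",
              digits, x$mean_db, digits, x$se_db, x$n_body))
  cat(sprintf("  thermal quality mean d_e = %.*f +/- %.*f degC (n = %d)\n",
              digits, x$mean_de, digits, x$se_de, x$n_operative))
  cat(sprintf("  effectiveness   E        = %.*f +/- %.*f\n",
              digits, x$e_index, digits, x$se_e))
  invisible(x)
}
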