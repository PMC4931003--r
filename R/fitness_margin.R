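#' Optimal temperature for physiological performance
#'
#' Container for a literature-derived optimal body temperature, used as the
#' reference point of thermal safety margins.
#'
#' @param t_opt Optimal temperature, degrees C (within \[0, 50\]).
#' @param se Standard error, degrees C.
#' @param source Free-text citation for where the value comes from.
#' @return An object of class `"optimal_temperature"`.
#' @export
optimal_temperature <- function(t_opt, se = NA_real_, source = "") {
  stopifnot(is.numeric(t_opt), is.finite(t_opt))
  if (t_opt < 0 || t_opt > 50) stop("t_opt outside the plausible [0, 50] degC window")
  structure(list(t_opt = t_opt, se = se, source = source),
            class = "optimal_temperature")
}

#' Thermal safety margin
#'
#' Distance of a mean field body temperature below the optimal performance
#' temperature: `t_opt - mean_tb`. Positive values mean the population runs
#' colder than its optimum (the safe side under warming, by Jensen's
#' asymmetry of left-skewed performance curves); negative values mean body
#' temperatures already exceed the optimum.
#'
#' @param mean_tb Mean field body temperature, degrees C.
#' @param opt An [optimal_temperature()] object (or a plain number).
#' @return Margin in degrees C.
#' @examples
#' safety_margin(30.34, optimal_temperature(34.53))  # 4.19
#' @export
safety_margin <- function(mean_tb, opt) {
  t_opt <- if (inherits(opt, "optimal_temperature")) opt$t_opt else opt
  stopifnot(is.numeric(mean_tb), is.finite(mean_tb), is.finite(t_opt))
  t_opt - mean_tb
}

#' Illustrative left-skewed thermal performance curve
#'
#' A continuous curve that is 0 at the critical limits, rises gradually to 1
#' at the optimum and falls sharply above it -- the canonical left-skewed
#' shape of ectotherm performance curves, under which overshooting the
#' optimum costs more than an equal shortfall below it. The shape is a
#' piecewise power ("beta-style") form with configurable asymmetry; it is
#' illustrative (for margin diagrams), not fitted to performance data.
#'
#' @param t Temperatures, degrees C (vectorised). Values outside
#'   `[ct_min, ct_max]` return 0.
#' @param t_opt Optimum, degrees C; performance is 1 there.
#' @param ct_min,ct_max Critical thermal minimum / maximum, degrees C
#'   (`ct_min < t_opt < ct_max`). Defaults are placeholders spanning a
#'   typical small-lacertid tolerance range, not species estimates.
#' @param rise_shape,fall_shape Power exponents of the rising and falling
#'   limbs; a convex rise (`rise_shape` > 1) with a concave fall
#'   (`fall_shape` < 1) gives the gradual-rise / sharp-fall asymmetry.
#' @return Relative performance in \[0, 1\].
#' @export
skewed_performance_curve <- function(t, t_opt = 34.53, ct_min = 5,
                                     ct_max = 42, rise_shape = 2,
                                     fall_shape = 0.8) {
  if (!(ct_min < t_opt && t_opt < ct_max)) {
    stop("require ct_min < t_opt < ct_max")
  }
  stopifnot(rise_shape > 0, fall_shape > 0)
  out <- numeric(length(t))
  below <- t >= ct_min & t <= t_opt
  above <- t > t_opt & t <= ct_max
  # each limb maps its interval onto [0, 1]; the concave falling limb makes
  # the decline above the optimum steeper than the rise below it
  out[below] <- ((t[below] - ct_min) / (t_opt - ct_min))^rise_shape
  out[above] <- ((ct_max - t[above]) / (ct_max - t_opt))^fall_shape
  out
}
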