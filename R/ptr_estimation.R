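#' Estimate the preferred temperature range from gradient selections
#'
#' The PTR is the central `central_fraction` of the pooled selected body
#' temperatures: the empirical quantile interval
#' `[(1 - f)/2, (1 + f)/2]` computed with linear interpolation between order
#' statistics (quantile type 7, the default of most scientific software).
#' Selections are pooled across individuals and hours.
#'
#' @param selections Either a numeric vector of selected temperatures
#'   (degrees C) or a data frame with a `t_sel` column (as produced by
#'   [generate_selected_temperatures()]).
#' @param central_fraction Central fraction defining the range; default 0.5
#'   (the interquartile interval).
#' @param type Quantile convention, passed to [stats::quantile()]; default 7.
#' @return A [ptr_range()] object.
#' @examples
#' compute_ptr(c(10, 20, 30, 40))          # [17.5, 32.5]
#' @export
compute_ptr <- function(selections, central_fraction = 0.5, type = 7) {
  if (is.data.frame(selections)) {
    if (!"t_sel" %in% names(selections)) {
      stop("selection data frame must have a 't_sel' column")
    }
    selections <- selections$t_sel
  }
  if (!is.numeric(selections)) stop("selections must be numeric")
  if (any(!is.finite(selections))) stop("non-finite selected temperatures rejected")
  if (length(selections) < 4L) {
    stop("need at least 4 selected temperatures to estimate quantile bounds")
  }
  if (central_fraction <= 0 || central_fraction > 1) {
    stop("central_fraction must lie in (0, 1]")
  }
  probs <- c((1 - central_fraction) / 2, (1 + central_fraction) / 2)
  q <- stats::quantile(selections, probs = probs, type = type, names = FALSE)
  ptr_range(q[1], q[2], central_fraction = central_fraction)
}

#' Breadth of a preferred temperature range
#'
#' `upper - lower`, reported in the field as the "precision of
#' thermoregulation" (narrower ranges indicate tighter set-points).
#'
#' @param ptr A [ptr_range()] object.
#' @return Breadth in degrees C.
#' @examples
#' ptr_breadth(ptr_range(31.18, 32.50))  # 1.32
#' @export
ptr_breadth <- function(ptr) {
  stopifnot(inherits(ptr, "ptr"))
  ptr$upper - ptr$lower
}
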