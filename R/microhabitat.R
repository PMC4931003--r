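#' The nine thermal microhabitat categories
#'
#' Closed set of patch types in which operative-temperature models are placed:
#' flat rock, moss, soil, grass, the four rock orientations, and under rock.
#' @export
MICROHABITATS <- c("flat_rock", "moss", "soil", "grass", "rock_south",
                   "rock_east", "rock_north", "rock_west", "under_rock")

validate_operative <- function(records) {
  req <- c("model_id", "microhabitat", "date", "time_gmt", "t_e")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("operative records missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !records$microhabitat %in% MICROHABITATS
  if (any(bad)) {
    message(sum(bad), " record(s) with unknown microhabitat rejected: ",
            paste(unique(records$microhabitat[bad]), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  records
}

in_window <- function(time_gmt, hours) {
  hr <- time_gmt %/% 60
  hr >= hours[1] & hr < hours[2]
}

#' Per-microhabitat, per-hour operative temperature profile
#'
#' Summarises operative-temperature logger records by (microhabitat, GMT hour):
#' n, mean, sd, min, max and the fraction of readings inside the preferred
#' range. Hour assignment truncates the timestamp to its GMT hour. A global
#' mean +/- sd over the activity window is attached as attributes.
#'
#' @param records Data frame of operative records (`model_id`, `microhabitat`,
#'   `date`, `time_gmt` in minutes since midnight GMT, `t_e` in degrees C).
#' @param ptr A [ptr_range()] object.
#' @param hours Activity window as `c(first_hour, last_hour)` GMT; readings
#'   with hour in `[first, last)` are kept. Default `c(9, 18)`.
#' @return A data frame of class `"microhabitat_profile"` with one row per
#'   (microhabitat, hour) cell; attributes `global_mean`, `global_sd`,
#'   `global_n`, `ptr`, `hours`.
#' @export
summarize_operative <- function(records, ptr, hours = c(9, 18)) {
  stopifnot(inherits(ptr, "ptr"))
  records <- validate_operative(records)
  if (nrow(records) == 0L) stop("no valid operative records")
  records <- records[in_window(records$time_gmt, hours), , drop = FALSE]
  if (nrow(records) == 0L) stop("no operative records inside the activity window")
  hr <- records$time_gmt %/% 60

  key <- split(seq_len(nrow(records)),
               list(micro = records$microhabitat, hour = hr), drop = TRUE)
  rows <- lapply(names(key), function(k) {
    idx <- key[[k]]
    te <- records$t_e[idx]
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    data.frame(
      microhabitat = parts[1L],
      hour = as.integer(parts[2L]),
      n = length(te),
      mean_te = mean(te),
      sd_te = if (length(te) > 1L) stats::sd(te) else 0,
      min_te = min(te),
      max_te = max(te),
      frac_in_ptr = mean(te >= ptr$lower & te <= ptr$upper),
      stringsAsFactors = FALSE
    )
  })
  prof <- do.call(rbind, rows)
  prof <- prof[order(prof$microhabitat, prof$hour), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "global_mean") <- mean(records$t_e)
  attr(prof, "global_sd") <- stats::sd(records$t_e)
  attr(prof, "global_n") <- nrow(records)
  attr(prof, "ptr") <- ptr
  attr(prof, "hours") <- hours
  class(prof) <- c("microhabitat_profile", class(prof))
  prof
}

#' Hourly thermal-suitability availability
#'
#' For each hour of the activity window, asks whether at least one microhabitat
#' offered a thermally suitable site (operative temperature inside the
#' preferred range). Two criteria: `"any"` (default) flags an hour if any
#' reading fell inside the PTR; `"mean"` requires some microhabitat's hourly
#' mean to lie inside it.
#'
#' @param profile A [summarize_operative()] result.
#' @param ptr A [ptr_range()] object (defaults to the profile's).
#' @param criterion `"any"` or `"mean"`.
#' @return A data frame (`hour`, `suitable`) with attribute
#'   `all_hours_covered`.
#' @export
hourly_suitability <- function(profile, ptr = attr(profile, "ptr"),
                               criterion = c("any", "mean")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(profile, "microhabitat_profile"), inherits(ptr, "ptr"))
  hours_win <- attr(profile, "hours")
  hours <- seq.int(hours_win[1], hours_win[2] - 1L)
  suitable <- vapply(hours, function(h) {
    cell <- profile[profile$hour == h, , drop = FALSE]
    if (nrow(cell) == 0L) return(FALSE)
    if (criterion == "any") {
      any(cell$frac_in_ptr > 0)
    } else {
      any(cell$mean_te >= ptr$lower & cell$mean_te <= ptr$upper)
    }
  }, logical(1L))
  out <- data.frame(hour = hours, suitable = suitable)
  attr(out, "all_hours_covered") <- all(suitable)
  out
}

#' Thermal quality of the habitat (d_e deviations)
#'
#' Deviations of every operative-temperature reading from the preferred range,
#' pooled unweighted across microhabitats, restricted to the activity window.
#' The mean of this set is the Hertz mean d_e.
#'
#' @inheritParams summarize_operative
#' @return An `"operative"` [compute_deviation_set()].
#' @export
thermal_quality <- function(records, ptr, hours = c(9, 18)) {
  records <- validate_operative(records)
  records <- records[in_window(records$time_gmt, hours), , drop = FALSE]
  if (nrow(records) == 0L) stop("no operative records inside the activity window")
  compute_deviation_set(records$t_e, ptr, source = "operative")
}

#' Compare operative-temperature distributions across microhabitats
#'
#' Kruskal-Wallis omnibus test over microhabitat groups, Nemenyi all-pairs
#' post hoc matrix, and a ranking of microhabitats by mean deviation from the
#' preferred range (closest to the set-point range first).
#'
#' @inheritParams summarize_operative
#' @return List with `omnibus` (a `"thermo_test"`), `nemenyi` (p-value
#'   matrix), and `ranking` (data frame: microhabitat, mean_te, mean_dev,
#'   ordered by increasing mean deviation).
#' @export
compare_microhabitats <- function(records, ptr, hours = c(9, 18)) {
  stopifnot(inherits(ptr, "ptr"))
  records <- validate_operative(records)
  records <- records[in_window(records$time_gmt, hours), , drop = FALSE]
  groups <- split(records$t_e, records$microhabitat, drop = TRUE)
  if (length(groups) < 3L) stop("need >= 3 microhabitats present")
  groups <- groups[order(names(groups))]   # order-stable under record shuffles

  omnibus <- kruskal_wallis(groups)
  nem <- nemenyi_posthoc(groups)
  ranking <- data.frame(
    microhabitat = names(groups),
    n = lengths(groups),
    mean_te = vapply(groups, mean, numeric(1L)),
    mean_dev = vapply(groups, function(te)
      mean(deviation_from_range(te, ptr)), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ranking <- ranking[order(ranking$mean_dev, ranking$microhabitat), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  list(omnibus = omnibus, nemenyi = nem, ranking = ranking)
}
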