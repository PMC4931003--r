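# CSV interchange for the three input tables, the run configuration, and the
# end-to-end pipeline. Times are GMT minutes-since-midnight; dates ISO-8601.

num_or_na <- function(x) suppressWarnings(as.numeric(x))

reject_rows <- function(df, bad, what, path) {
  if (any(bad)) {
    # +1 for the header row so reported numbers match file line numbers
    message(sum(bad), " malformed row(s) rejected in ", path, " (", what,
            "), line(s): ", paste(utils::head(which(bad) + 1L, 20L),
                                  collapse = ", "))
  }
  df[!bad, , drop = FALSE]
}

read_checked_csv <- function(path, mandatory) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) stop("missing mandatory column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  df
}

#' Read capture records from CSV
#'
#' Expected columns: `lizard_id`, `sex`, `svl_mm`, `mass_g`, `date`,
#' `time_gmt`, `era`, `t_b`, `t_a`, `t_s` (`svl_mm` / `mass_g` optional,
#' `t_a` / `t_s` may be blank for unmeasured records). Rows with unparseable
#' body temperature or time, out-of-window temperatures (outside \[-10, 70\]
#' degC) or times outside \[0, 1440) are rejected and logged with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return Data frame of capture records.
#' @export
read_capture_csv <- function(path) {
  df <- read_checked_csv(path, c("lizard_id", "sex", "date", "time_gmt",
                                 "era", "t_b", "t_a", "t_s"))
  for (opt in c("svl_mm", "mass_g")) if (!opt %in% names(df)) df[[opt]] <- NA
  for (v in c("svl_mm", "mass_g", "time_gmt", "t_b", "t_a", "t_s")) {
    df[[v]] <- num_or_na(df[[v]])
  }
  bad <- !is.finite(df$t_b) | !is.finite(df$time_gmt) |
    df$time_gmt < 0 | df$time_gmt >= 1440 |
    df$t_b < -10 | df$t_b > 70 |
    (is.finite(df$t_a) & (df$t_a < -10 | df$t_a > 70)) |
    (is.finite(df$t_s) & (df$t_s < -10 | df$t_s > 70)) |
    !nzchar(df$era)
  df <- reject_rows(df, bad, "invalid temperature, time or era", path)
  if (nrow(df) == 0L) stop("no valid capture records in ", path)
  rownames(df) <- NULL
  df[c("lizard_id", "sex", "svl_mm", "mass_g", "date", "time_gmt", "era",
       "t_b", "t_a", "t_s")]
}

#' Write capture records to CSV
#' @param records Capture-record data frame.
#' @param path Output path.
#' @export
write_capture_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read gradient selected temperatures from CSV
#'
#' Expected columns: `lizard_id`, `sex`, `hour`, `t_sel`. Selections outside
#' the gradient span are rejected and logged.
#'
#' @param path CSV file path.
#' @param bounds Gradient span used for validation, degrees C.
#' @return Data frame of selections.
#' @export
read_selected_csv <- function(path, bounds = c(20, 60)) {
  df <- read_checked_csv(path, c("lizard_id", "sex", "hour", "t_sel"))
  df$hour <- num_or_na(df$hour)
  df$t_sel <- num_or_na(df$t_sel)
  bad <- !is.finite(df$t_sel) | df$t_sel < bounds[1] | df$t_sel > bounds[2] |
    !is.finite(df$hour)
  df <- reject_rows(df, bad, "invalid selection", path)
  if (nrow(df) == 0L) stop("no valid selections in ", path)
  rownames(df) <- NULL
  df
}

#' @rdname read_selected_csv
#' @param selections Selection data frame to write.
#' @export
write_selected_csv <- function(selections, path) {
  utils::write.csv(selections, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read operative-temperature logger records from CSV
#'
#' Long format (default): columns `model_id`, `microhabitat`, `date`,
#' `time_gmt`, `t_e`. Wide format: columns `date`, `time_gmt` plus one column
#' per model id; `model_map` (named character, model id -> microhabitat) is
#' then required. Records with an unknown microhabitat or an implausible
#' temperature are rejected and logged.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @param model_map Named character vector for the wide dialect.
#' @return Data frame of operative records (long layout).
#' @export
read_logger_csv <- function(path, format = c("long", "wide"),
                            model_map = NULL) {
  format <- match.arg(format)
  if (format == "long") {
    df <- read_checked_csv(path, c("model_id", "microhabitat", "date",
                                   "time_gmt", "t_e"))
    df$time_gmt <- num_or_na(df$time_gmt)
    df$t_e <- num_or_na(df$t_e)
  } else {
    if (is.null(model_map)) stop("wide dialect requires model_map")
    w <- read_checked_csv(path, c("date", "time_gmt"))
    models <- setdiff(names(w), c("date", "time_gmt"))
    unknown <- setdiff(models, names(model_map))
    if (length(unknown)) stop("wide columns without microhabitat mapping: ",
                              paste(unknown, collapse = ", "))
    df <- do.call(rbind, lapply(models, function(m) {
      data.frame(model_id = m,
                 microhabitat = unname(model_map[[m]]),
                 date = w$date,
                 time_gmt = num_or_na(w$time_gmt),
                 t_e = num_or_na(w[[m]]),
                 stringsAsFactors = FALSE)
    }))
  }
  bad <- !is.finite(df$t_e) | df$t_e < -10 | df$t_e > 70 |
    !is.finite(df$time_gmt) | df$time_gmt < 0 | df$time_gmt >= 1440
  df <- reject_rows(df, bad, "invalid reading", path)
  badm <- !df$microhabitat %in% MICROHABITATS
  if (any(badm)) {
    message(sum(badm), " record(s) with unknown microhabitat rejected in ",
            path, ": ", paste(unique(df$microhabitat[badm]), collapse = ", "))
    df <- df[!badm, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid logger records in ", path)
  rownames(df) <- NULL
  df[c("model_id", "microhabitat", "date", "time_gmt", "t_e")]
}

#' @rdname read_logger_csv
#' @param records Operative-record data frame to write (long layout).
#' @export
write_logger_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param capture_csv CSV of capture records for both eras (`era` column
#'   distinguishes them).
#' @param selected_csv CSV of gradient selections.
#' @param logger_csv CSV of operative logger records (long format).
#' @param era_labels Character pair: first and second era label.
#' @param central_fraction PTR central fraction (default 0.5).
#' @param n_resamples Bootstrap resamples (default 500).
#' @param seed Integer seed for the bootstrap.
#' @param hours Activity window, GMT hours.
#' @param routing Location-test routing map ([default_test_routing()]).
#' @param suitability `"any"` or `"mean"` hourly-suitability criterion.
#' @param t_opt Optimal performance temperature, degrees C.
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(capture_csv, selected_csv, logger_csv,
                       era_labels = c("1983-1989", "2012"),
                       central_fraction = 0.5, n_resamples = 500L, seed = 1L,
                       hours = c(9, 18), routing = default_test_routing(),
                       suitability = "any", t_opt = 34.53, out_dir = NULL) {
  stopifnot(n_resamples >= 1, length(era_labels) == 2L)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full thermoregulation analysis pipeline
#'
#' Orchestrates every stage: read the three input tables, estimate the
#' preferred range from gradient selections, compute deviation sets and the
#' bootstrap thermoregulation summary for the later era, profile microhabitat
#' operative temperatures and hourly suitability, compare the two eras, and
#' compute safety margins against the optimal temperature. When `out_dir` is
#' set, writes `summary.json` (machine-readable bundle) and per-stage CSV
#' tables. Identical configuration and seed give byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisible list (the report bundle): `ptr`, `thermoreg`,
#'   `profile`, `suitability`, `microhabitat_tests`, `era_comparison`,
#'   `margins`, `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c(cfg$capture_csv, cfg$selected_csv, cfg$logger_csv)) {
    if (!file.exists(p)) stop("pipeline input missing: ", p)
  }
  log_stage <- function(...) message("[thermoreg] ", ...)

  log_stage("reading inputs")
  captures <- read_capture_csv(cfg$capture_csv)
  selections <- read_selected_csv(cfg$selected_csv)
  loggers <- read_logger_csv(cfg$logger_csv)

  log_stage("estimating preferred range (central fraction ",
            cfg$central_fraction, ")")
  ptr <- compute_ptr(selections, central_fraction = cfg$central_fraction)

  era_a <- captures[captures$era == cfg$era_labels[1L], , drop = FALSE]
  era_b <- captures[captures$era == cfg$era_labels[2L], , drop = FALSE]
  if (nrow(era_a) == 0L || nrow(era_b) == 0L) {
    stop("an era label matched no capture records: ",
         paste(cfg$era_labels, collapse = " / "))
  }

  log_stage("thermoregulation indices (bootstrap n = ", cfg$n_resamples,
            ", seed ", cfg$seed, ")")
  db <- compute_deviation_set(era_b$t_b, ptr, source = "body")
  de <- thermal_quality(loggers, ptr, hours = cfg$hours)
  thermoreg <- bootstrap_thermoreg(db, de, n_resamples = cfg$n_resamples,
                                   seed = cfg$seed)

  log_stage("microhabitat profiling")
  profile <- summarize_operative(loggers, ptr, hours = cfg$hours)
  suit <- hourly_suitability(profile, ptr, criterion = cfg$suitability)
  micro_tests <- compare_microhabitats(loggers, ptr, hours = cfg$hours)

  log_stage("era comparison: ", cfg$era_labels[1L], " vs ", cfg$era_labels[2L])
  eras <- compare_eras(era_a, era_b, routing = cfg$routing)

  opt <- optimal_temperature(cfg$t_opt, source = "configured optimum")
  margins <- c(
    era1 = safety_margin(eras$variables$t_b$era1$mean, opt),
    era2 = safety_margin(eras$variables$t_b$era2$mean, opt)
  )

  bundle <- list(ptr = ptr, thermoreg = thermoreg, profile = profile,
                 suitability = suit, microhabitat_tests = micro_tests,
                 era_comparison = eras, margins = margins, config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_stage("writing results to ", cfg$out_dir)
    write_report_bundle(bundle, cfg$out_dir)
  }
  invisible(bundle)
}

#' Write the machine-readable report bundle
#'
#' `summary.json` plus CSV tables (`microhabitat_profile.csv`,
#' `hourly_suitability.csv`, `era_table.csv`).
#'
#' @param bundle A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  eras <- bundle$era_comparison
  era_table <- do.call(rbind, lapply(eras$variables, function(v) {
    data.frame(variable = v$variable,
               era1_mean = v$era1$mean, era1_se = v$era1$se, era1_n = v$era1$n,
               era2_mean = v$era2$mean, era2_se = v$era2$se, era2_n = v$era2$n,
               delta = v$delta, test = v$test$name,
               statistic = v$test$statistic, p_value = v$test$p_value)
  }))
  utils::write.csv(era_table, file.path(out_dir, "era_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$profile),
                   file.path(out_dir, "microhabitat_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$suitability,
                   file.path(out_dir, "hourly_suitability.csv"),
                   row.names = FALSE)
  s <- bundle$thermoreg
  json <- list(
    ptr = list(lower = bundle$ptr$lower, upper = bundle$ptr$upper,
               breadth = ptr_breadth(bundle$ptr)),
    thermoreg = list(mean_db = s$mean_db, se_db = s$se_db,
                     mean_de = s$mean_de, se_de = s$se_de,
                     e_index = s$e_index, se_e = s$se_e,
                     n_resamples = s$n_resamples, seed = s$seed,
                     n_body = s$n_body, n_operative = s$n_operative),
    operative = list(mean = attr(bundle$profile, "global_mean"),
                     sd = attr(bundle$profile, "global_sd"),
                     n = attr(bundle$profile, "global_n")),
    all_hours_covered = attr(bundle$suitability, "all_hours_covered"),
    deltas = as.list(eras$deltas),
    buffering_ratio = as.list(eras$buffering_ratio),
    margins = as.list(bundle$margins)
  )
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
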