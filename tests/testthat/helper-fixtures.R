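# Shared fixtures. The reference set-point range used throughout is the
# published summer range of the study population.
ref_ptr <- function() ptr_range(31.18, 32.50)

# Tiny operative-record table built in code (3 microhabitats, 2 hours).
tiny_operative <- function() {
  data.frame(
    model_id = rep(c("CU01", "CU02", "CU03"), each = 4L),
    microhabitat = rep(c("flat_rock", "moss", "under_rock"), each = 4L),
    date = "2012-08-01",
    time_gmt = rep(c(545, 550, 605, 610), times = 3L),
    t_e = c(20, 21, 22, 23, 31.5, 32, 31.8, 31.2, 12, 13, 12.5, 14),
    stringsAsFactors = FALSE
  )
}

# Closed-form window mean of the configured diel sinusoids, averaged over the
# exact sampling grid (independent oracle for the generator's mean).
operative_expected_mean <- function(cfg, hours = c(9, 18)) {
  per_day <- 1440 %/% cfg$interval
  minutes <- seq(0, by = cfg$interval, length.out = per_day)
  minutes <- minutes[minutes >= hours[1] * 60 & minutes < hours[2] * 60]
  mean(vapply(seq_len(nrow(cfg$params)), function(i) {
    p <- cfg$params[i, ]
    mean(p$baseline + p$amplitude * cos(2 * pi * (minutes - p$peak_hour * 60) / 1440))
  }, numeric(1L)))
}

# Closed-form expectation of the PTR deviation of N(m, s) (oracle for d_e):
# E[(L - X)+] + E[(X - U)+] for a normal variable.
normal_dev_expectation <- function(m, s, lower, upper) {
  dl <- (lower - m) / s
  du <- (m - upper) / s
  s * (stats::dnorm(dl) + dl * stats::pnorm(dl)) +
    s * (stats::dnorm(du) + du * stats::pnorm(du))
}
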