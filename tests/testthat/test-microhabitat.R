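test_that("operative summaries aggregate by microhabitat and hour", {
  ptr <- ref_ptr()
  prof <- summarize_operative(tiny_operative(), ptr)
  cell <- prof[prof$microhabitat == "flat_rock" & prof$hour == 9, ]
  expect_equal(cell$n, 2)
  expect_equal(cell$mean_te, 20.5)
  expect_equal(cell$sd_te, sd(c(20, 21)))
  moss9 <- prof[prof$microhabitat == "moss" & prof$hour == 9, ]
  expect_equal(moss9$frac_in_ptr, 1)   # 31.5, 32 both inside the range
  expect_equal(attr(prof, "global_n"), 12)
  expect_equal(attr(prof, "global_mean"), mean(tiny_operative()$t_e))

  # three readings in one cell: textbook mean/sd/n
  one_cell <- data.frame(model_id = "CU01", microhabitat = "soil",
                         date = "2012-08-01", time_gmt = c(600, 610, 620),
                         t_e = c(20, 21, 22))
  p1 <- summarize_operative(one_cell, ptr)
  expect_equal(as.data.frame(p1)[, c("n", "mean_te", "sd_te")],
               data.frame(n = 3L, mean_te = 21, sd_te = 1),
               ignore_attr = TRUE)

  # unknown labels are rejected with a log message, not an error
  with_unknown <- rbind(tiny_operative(),
                        data.frame(model_id = "CU09", microhabitat = "lava",
                                   date = "2012-08-01", time_gmt = 600,
                                   t_e = 25))
  expect_message(p2 <- summarize_operative(with_unknown, ptr), "lava")
  expect_equal(attr(p2, "global_n"), 12)
})

test_that("hourly suitability flags hours with an in-range microhabitat", {
  ptr <- ref_ptr()
  # constructed coverage: flat_rock suits the morning, rock_south midday
  hours <- 9:17
  rec <- rbind(
    data.frame(model_id = "CU01", microhabitat = "flat_rock",
               date = "2012-08-01", time_gmt = hours * 60 + 10,
               t_e = ifelse(hours < 13, 31.5, 25)),
    data.frame(model_id = "CU02", microhabitat = "rock_south",
               date = "2012-08-01", time_gmt = hours * 60 + 20,
               t_e = ifelse(hours >= 13, 32.0, 24))
  )
  prof <- summarize_operative(rec, ptr)
  suit <- hourly_suitability(prof, ptr)
  expect_true(all(suit$suitable))
  expect_true(attr(suit, "all_hours_covered"))

  # everything far below the range: no suitable hour under either criterion
  cold <- rec; cold$t_e <- ptr$lower - 10
  prof_cold <- summarize_operative(cold, ptr)
  for (crit in c("any", "mean")) {
    s <- hourly_suitability(prof_cold, ptr, criterion = crit)
    expect_false(any(s$suitable))
    expect_false(attr(s, "all_hours_covered"))
  }

  # widening the range can never turn a suitable hour unsuitable
  wide <- ptr_range(ptr$lower - 2, ptr$upper + 2)
  prof_w <- summarize_operative(rec, wide)
  s_narrow <- hourly_suitability(prof, ptr)
  s_wide <- hourly_suitability(prof_w, wide)
  expect_true(all(s_wide$suitable >= s_narrow$suitable))
})

test_that("thermal quality pools deviations of all readings in the window", {
  ptr <- ref_ptr()
  rec <- data.frame(model_id = "CU01", microhabitat = "grass",
                    date = "2012-08-01", time_gmt = c(600, 660),
                    t_e = c(21.60, 31.5))
  de <- thermal_quality(rec, ptr)
  expect_equal(de$values, c(9.58, 0))
  expect_identical(de$source, "operative")

  all_in <- rec; all_in$t_e <- c(31.5, 32.0)
  expect_equal(mean(thermal_quality(all_in, ptr)$values), 0)

  # conservation under partition: pooled mean equals the n-weighted mean of
  # per-microhabitat means
  op <- generate_operative_series(microhabitat_config(n_days = 2), seed = 3)
  pooled <- thermal_quality(op, ptr)
  win <- op[op$time_gmt >= 9 * 60 & op$time_gmt < 18 * 60, ]
  per <- tapply(deviation_from_range(win$t_e, ptr), win$microhabitat, mean)
  wts <- table(win$microhabitat)[names(per)]
  expect_equal(mean(pooled$values),
               sum(per * as.numeric(wts)) / sum(wts))
})

test_that("microhabitat comparison is stable under record shuffles and shifts", {
  ptr <- ref_ptr()
  op <- generate_operative_series(microhabitat_config(n_days = 2), seed = 8)
  res <- compare_microhabitats(op, ptr)
  expect_s3_class(res$omnibus, "thermo_test")
  expect_equal(res$omnibus$df, 8)
  expect_equal(dim(res$nemenyi), c(9, 9))

  set.seed(1)
  shuffled <- op[sample(nrow(op)), ]
  res2 <- compare_microhabitats(shuffled, ptr)
  expect_equal(res2$omnibus$statistic, res$omnibus$statistic)
  expect_equal(res2$nemenyi, res$nemenyi)
  expect_equal(res2$ranking, res$ranking)

  # ranking invariant to a common shift of temperatures and range bounds
  shifted <- op; shifted$t_e <- shifted$t_e + 4.2
  res3 <- compare_microhabitats(shifted,
                                ptr_range(ptr$lower + 4.2, ptr$upper + 4.2))
  expect_equal(res3$ranking$microhabitat, res$ranking$microhabitat)
  expect_equal(res3$ranking$mean_dev, res$ranking$mean_dev)
})

test_that("identical-distribution microhabitats yield a calibrated null omnibus", {
  set.seed(202)
  rejections <- replicate(500, {
    groups <- lapply(1:9, function(i) rnorm(25, 20, 3))
    kruskal_wallis(groups)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.03 - 0.02)
  expect_lte(mean(rejections), 0.07 + 0.02)
})

test_that("generator defaults reproduce the published microhabitat structure", {
  ptr <- ref_ptr()
  cfg <- microhabitat_config()
  op <- generate_operative_series(cfg, seed = 404)
  prof <- summarize_operative(op, ptr)

  # pooled window mean against the closed-form mean of the generating model
  expected <- operative_expected_mean(cfg)
  se <- attr(prof, "global_sd") / sqrt(attr(prof, "global_n"))
  expect_lt(abs(attr(prof, "global_mean") - expected), 2 * se)

  # a thermally suitable site exists at every activity hour
  expect_true(attr(hourly_suitability(prof, ptr), "all_hours_covered"))

  # sun-exposed trio similar to each other and ranked nearest the range
  res <- compare_microhabitats(op, ptr)
  warm <- c("flat_rock", "moss", "rock_south")
  expect_setequal(res$ranking$microhabitat[1:3], warm)
  pw <- res$nemenyi[warm, warm]
  expect_true(all(pw[upper.tri(pw)] > 0.05))
  expect_lt(res$omnibus$p_value, 1e-6)

  # mean habitat deviation close to its closed-form expectation
  de <- thermal_quality(op, ptr)
  minutes <- seq(0, 1439, by = cfg$interval)
  minutes <- minutes[minutes >= 540 & minutes < 1080]
  exp_dev <- mean(vapply(seq_len(nrow(cfg$params)), function(i) {
    p <- cfg$params[i, ]
    m <- p$baseline + p$amplitude * cos(2 * pi * (minutes - p$peak_hour * 60) / 1440)
    mean(normal_dev_expectation(m, p$noise_sd, ptr$lower, ptr$upper))
  }, numeric(1)))
  expect_lt(abs(mean(de$values) - exp_dev) / exp_dev, 0.10)
})
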