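#!/usr/bin/env Rscript
# The 25-year warming contrast: sex-pooling check, per-variable era deltas
# with routed location tests, the temperature-type x era interaction, and
# slope homogeneity of the body-on-environment regressions.

suppressMessages(library(thermoreg))
captures <- read_capture_csv("results/data/captures.csv")
era1 <- captures[captures$era == "1983-1989", ]
era2 <- captures[captures$era == "2012", ]

for (e in list(era1, era2)) {
  chk <- sex_pooling_check(e)
  cat(sprintf("%s: sexes pooled? %s (F = %.3f, p = %.3f)\n",
              e$era[1], chk$pool, chk$statistic, chk$p_value))
}

rep <- compare_eras(era1, era2)
print(rep)

tab <- do.call(rbind, lapply(rep$variables, function(v)
  data.frame(variable = v$variable,
             era1_mean = v$era1$mean, era1_se = v$era1$se, era1_n = v$era1$n,
             era2_mean = v$era2$mean, era2_se = v$era2$se, era2_n = v$era2$n,
             delta = v$delta, p_value = v$test$p_value)))
write.csv(tab, "results/era_table.csv", row.names = FALSE)
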