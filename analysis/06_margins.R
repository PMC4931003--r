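#!/usr/bin/env Rscript
# Thermal safety margins of each era's mean body temperature below the
# optimal performance temperature (34.53 degC), and a grid of the
# illustrative left-skewed performance curve for plotting.

suppressMessages(library(thermoreg))
tab <- read.csv("results/era_table.csv")
tb <- tab[tab$variable == "t_b", ]

opt <- optimal_temperature(34.53, se = 0.50, source = "locomotor performance")
margins <- data.frame(
  era = c("era1", "era2"),
  mean_tb = c(tb$era1_mean, tb$era2_mean),
  t_opt = opt$t_opt,
  margin = c(safety_margin(tb$era1_mean, opt),
             safety_margin(tb$era2_mean, opt))
)
print(margins)
write.csv(margins, "results/safety_margins.csv", row.names = FALSE)

curve_grid <- data.frame(t = seq(5, 42, by = 0.1))
curve_grid$performance <- skewed_performance_curve(curve_grid$t)
write.csv(curve_grid, "results/performance_curve.csv", row.names = FALSE)
cat(sprintf("safety margins: %.2f degC (era 1), %.2f degC (era 2)\n",
            margins$margin[1], margins$margin[2]))
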