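#!/usr/bin/env Rscript
# Estimate the preferred temperature range (the central 50% of gradient
# selections) and report its breadth, the "precision of thermoregulation".

suppressMessages(library(thermoreg))
sel <- read_selected_csv("results/data/selections.csv")
ptr <- compute_ptr(sel)
print(ptr)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(lower = ptr$lower, upper = ptr$upper,
                     breadth = ptr_breadth(ptr), n = nrow(sel)),
          "results/ptr.csv", row.names = FALSE)
cat(sprintf("PTR breadth %.2f degC from %d selections\n",
            ptr_breadth(ptr), nrow(sel)))
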