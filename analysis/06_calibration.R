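#!/usr/bin/env Rscript

# Step 6: calibration of two-year absolute risk.
#
# Per bootstrap replicate the selected model is fitted on the training
# persons and absolute risk at 730 days (Breslow baseline) is predicted for
# the out-of-bag persons; observed risk is the Kaplan-Meier complement
# within deciles of predicted risk.

library(landshap)

data <- read_landmark("results/super_landmark.tsv")
selected <- readLines("results/selected_terms.txt")

set.seed(20260303)
tab <- calibration_deciles_boot(data, selected, B = 50)
print(tab, digits = 3)
message(sprintf("observed-vs-predicted slope: %.2f",
                unname(coef(lm(observed ~ mean_predicted, tab))[2])))

write.table(tab, "results/calibration.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message("wrote results/calibration.tsv")
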