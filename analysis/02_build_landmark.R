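#!/usr/bin/env Rscript

# Step 2: build the super-landmark dataset.
#
# One row per eligible (person, landmark age) pair for ages 60-64: index
# date on the first of the month of the landmark birthday, predictors
# derived from records strictly before the index date, outcome = first CRC
# diagnosis within two years with censoring at other cancers, death, two
# years after the records end, or 730 days.

library(landshap)

cohort <- read_cohort("results/cohort")
data <- build_super_landmark(cohort, ages = 60:64)

message(sprintf("rows: %d from %d persons; events: %d (%.2f%%)",
                nrow(data), length(unique(data$person_id)),
                sum(data$event), 100 * mean(data$event)))
message(sprintf("complete-case rows dropped: %d",
                attr(data, "n_dropped_missing")))
print(table(data$censor_reason))

write_landmark(data, "results/super_landmark.tsv")
message("wrote results/super_landmark.tsv")
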