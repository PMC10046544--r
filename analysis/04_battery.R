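#!/usr/bin/env Rscript
# Step 4: run the full statistics battery on the scored cohort: within-arm
# Wilcoxon signed-rank tests, between-arm Mann-Whitney tests on the
# changes (overall and stratified by sex and baseline brain-age sign),
# duration correlations and the categorical symptom outcome. P-values are
# reported uncorrected.
#
# Finds: the nutraceuticals BBA decrease and the between-arm contrast are
# significant; the lifestyle change is not.

suppressMessages(library(qeegage))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

cfg <- paper_profile(seed = seed)
gen <- generate_cohort(cfg)
scored <- score_cohort(gen$cohort, calibrate_reference(cfg), cfg$age_range)
bat <- run_battery(scored)
write_table_tsv(as.data.frame(bat), "results/battery.tsv")
write(jsonlite::toJSON(as.data.frame(bat), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE), "results/battery.json")

key <- bat$comparison %in% c("nutraceuticals: BBA pre vs post",
                             "lifestyle: BBA pre vs post",
                             "between-arm: delta BBA") & bat$stratum == "all"
print(bat[key, c("comparison", "n", "statistic", "z", "p")], digits = 3,
      row.names = FALSE)
cat("full battery (", nrow(bat), "comparisons ) in results/battery.tsv\n")
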