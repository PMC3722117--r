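#!/usr/bin/env Rscript
# Step 4: cohort summary table and paired statistics.
#
# Medians per algorithm (whole cohort and per tumour site) and the paired
# two-sided Wilcoxon signed-rank test of each algorithm's BTV volume against
# the manual GTV volume (alpha 0.05, no multiplicity correction), laid out
# as algorithm rows x cohort/lung/oesophageal/pelvic column blocks.

library(btvseg)

records <- read_cohort_csv("results/cohort_records.csv")
summary <- summarize_cohort(records)

utils::write.csv(summary, "results/table_cohort_summary.csv",
                 row.names = FALSE)
lines <- utils::capture.output(format_cohort_table(summary))
writeLines(lines, "results/table_cohort_summary.txt")

cat("Cohort summary (median volumes, paired Wilcoxon p vs GTV, median CI):\n\n")
cat(lines, sep = "\n")
sig <- summary$cohort_p_vs_gtv[-1] < 0.05
cat(sprintf("\n%d of %d algorithms differ significantly from the GTV volume\n",
            sum(sig), length(sig)))
cat("Wrote results/table_cohort_summary.{csv,txt}\n")
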