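#!/usr/bin/env Rscript
# Internal-identity checks against the published reference values:
# (1) LR+ recomputed from each published sensitivity/specificity pair must
#     reproduce the published likelihood ratio on every internally
#     consistent row;
# (2) prevalence percentages recomputed from the published counts must
#     reproduce the published percentages.
# Writes results/reference_checks.csv.

suppressPackageStartupMessages(library(metsdx))
dir.create("results", showWarnings = FALSE)

ref <- reference_operating_points()
ref$lr_recomputed <- round(vapply(seq_len(nrow(ref)), function(i)
  unname(likelihood_ratios(ref$sensitivity[i],
                           ref$specificity[i])["lr_pos"]),
  numeric(1)), 2)
ref$identity_holds <- ref$lr_recomputed == ref$lr_printed

counts <- reference_counts()
counts$pct_recomputed <- round(100 * counts$numerator / counts$denominator, 1)
counts$identity_holds <- counts$pct_recomputed == counts$printed_pct

utils::write.csv(ref, "results/reference_checks.csv", row.names = FALSE)
utils::write.csv(counts, "results/reference_prevalence_checks.csv",
                 row.names = FALSE)

message(sprintf("LR+ identity: %d/%d rows reproduce the published value (of which %d flagged consistent a priori)",
                sum(ref$identity_holds), nrow(ref), sum(ref$lr_consistent)))
message(sprintf("prevalence arithmetic: %d/%d published percentages reproduced",
                sum(counts$identity_holds), nrow(counts)))
print(ref[!ref$identity_holds,
          c("stratum", "index", "sensitivity", "specificity",
            "lr_printed", "lr_recomputed")])
message("wrote results/reference_checks.csv, results/reference_prevalence_checks.csv")
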