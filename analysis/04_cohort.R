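#!/usr/bin/env Rscript
# Step 4: cohort biomarker evaluation on the synthetic patient cohort.
#
# Evaluates promoter methylation as a resistance-monitoring marker the
# way the clinical analysis does: unpaired and paired pre/post
# comparisons, low/high dichotomization at 20%, ROC of post-treatment
# non-responder samples against pre-treatment samples with a DeLong
# interval, univariate logistic calibration with the Hosmer-Lemeshow
# test, and the covariate association scan. Writes the association
# table and ROC points under results/.

suppressPackageStartupMessages(library(methscreen))

fix <- read_fixture_bundle("results/fixtures")
report <- run_cohort(fix$cohort)

print(report)
print(report$dichotomized)

if (!is.null(report$association)) {
  write.table(report$association, "results/association_scan.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("wrote results/association_scan.tsv\n")
}
if (!is.null(report$roc)) {
  write.table(report$roc$curve, "results/roc_points.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("wrote results/roc_points.tsv\n")
}
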