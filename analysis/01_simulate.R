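#!/usr/bin/env Rscript
# Step 1: generate the synthetic study.
#
# Emulates the inputs of the trastuzumab-resistance methylome screen at
# desk scale: a two-condition 450K-style beta matrix with 10 planted
# promoter-island hypermethylated genes, an expression table coupled to
# the planted silencing, and a 14-patient cohort (4 complete responders
# with pre-treatment samples, 10 non-responders with paired pre/post
# samples) carrying a +24 percentage-point post-treatment methylation
# shift. Writes the fixture bundle and its ground-truth manifest under
# results/fixtures/.

suppressPackageStartupMessages(library(methscreen))

config <- synth_config(seed = 20260930L)
bundle <- make_fixtures(config, "results/fixtures")

cat("Synthetic study written to results/fixtures/\n")
cat(sprintf("  probes: %d (%d on X/Y), genes: %d, planted: %d\n",
            config$n_probes, length(bundle$truth$xy_probes),
            config$n_genes, length(bundle$truth$planted_genes)))
cat(sprintf("  planted genes: %s\n",
            paste(bundle$truth$planted_genes, collapse = ", ")))
cat(sprintf("  cohort: %d samples from %d patients\n",
            nrow(bundle$cohort), length(unique(bundle$cohort$patient_id))))
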