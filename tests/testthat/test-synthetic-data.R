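test_that("identical configurations generate identical data", {
  b1 <- generate_study(synth_config(n_probes = 300, n_genes = 50,
                                    n_planted_hyper_down = 3, seed = 11))
  b2 <- generate_study(synth_config(n_probes = 300, n_genes = 50,
                                    n_planted_hyper_down = 3, seed = 11))
  expect_identical(b1$beta$values, b2$beta$values)
  expect_identical(b1$expr$values, b2$expr$values)
  expect_identical(b1$cohort, b2$cohort)
  b3 <- generate_study(synth_config(n_probes = 300, n_genes = 50,
                                    n_planted_hyper_down = 3, seed = 12))
  expect_false(identical(b1$beta$values, b3$beta$values))
})

test_that("generated values respect their ranges", {
  b <- generate_study(synth_config(n_probes = 500, n_genes = 80,
                                   n_planted_hyper_down = 5,
                                   beta_noise_sd = 0.6, seed = 2))
  expect_true(all(b$beta$values >= 0 & b$beta$values <= 1))
  expect_true(all(b$expr$values > 0))
  expect_true(all(b$cohort$methylation_pct >= 0 &
                    b$cohort$methylation_pct <= 100))
})

test_that("planted probes map only to planted genes and are stringent at zero noise", {
  cfg <- synth_config(n_probes = 200, n_genes = 40,
                      n_planted_hyper_down = 1, beta_noise_sd = 0, seed = 5)
  m <- generate_methylome(cfg)
  expect_setequal(unique(unname(m$truth$probe_gene)), m$truth$planted_genes)
  rec <- diffmeth_records(m$beta)
  planted_rec <- rec[rec$probe_id %in% m$truth$planted_probes, ]
  expect_true(all(planted_rec$stringent_class == "hypermethylated"))
  # spec'd planted means: 0.10 sensitive, 0.70 resistant
  expect_equal(planted_rec$beta_sens, rep(0.10, nrow(planted_rec)))
  expect_equal(planted_rec$beta_res, rep(0.70, nrow(planted_rec)))
})

test_that("planted genes get 3-5 promoter-island probes and X/Y probes exist", {
  cfg <- synth_config(n_probes = 800, n_genes = 100,
                      n_planted_hyper_down = 8, seed = 7)
  m <- generate_methylome(cfg)
  counts <- table(m$truth$probe_gene)
  expect_true(all(counts >= 3 & counts <= 5))
  planted_ann <- m$annotation[m$annotation$TargetID %in% m$truth$planted_probes, ]
  expect_true(all(planted_ann$Island_Relation == "Island"))
  expect_true(all(planted_ann$Gene_Region %in%
                    c("TSS200", "TSS1500", "5'UTR", "1stExon")))
  expect_true(all(!planted_ann$Chr %in% c("X", "Y")))
  expect_gt(length(m$truth$xy_probes), 0)
})

test_that("zero-noise expression fold change equals the planted effect exactly", {
  cfg <- synth_config(n_probes = 200, n_genes = 40, n_planted_hyper_down = 4,
                      expr_log2fc_planted = 1, expr_noise_sd = 0, seed = 9)
  m <- generate_methylome(cfg)
  ex <- generate_expression(m$truth, cfg)
  fc <- fold_change(ex$expr)
  planted_fc <- fc[fc$gene %in% m$truth$planted_genes, ]
  expect_equal(planted_fc$fold_change, rep(2, nrow(planted_fc)))
  expect_true(all(planted_fc$direction == "down_in_resistant"))
  null_fc <- fc[!fc$gene %in% m$truth$planted_genes, ]
  expect_equal(null_fc$fold_change, rep(1, nrow(null_fc)))
})

test_that("zero effect with zero noise yields no DE genes", {
  cfg <- synth_config(n_probes = 200, n_genes = 40, n_planted_hyper_down = 4,
                      expr_log2fc_planted = 0, expr_noise_sd = 0, seed = 9)
  m <- generate_methylome(cfg)
  ex <- generate_expression(m$truth, cfg)
  de <- classify_de(fold_change(ex$expr), fc_min = 1.5)
  expect_length(de$up, 0)
  expect_length(de$down, 0)
})

test_that("null-gene DE count matches a direct filter on the same draws", {
  cfg <- synth_config(n_probes = 200, n_genes = 500,
                      n_planted_hyper_down = 4,
                      expr_log2fc_planted = log2(1.5), expr_noise_sd = 0.2,
                      seed = 7)
  m <- generate_methylome(cfg)
  ex <- generate_expression(m$truth, cfg)
  de <- classify_de(fold_change(ex$expr), fc_min = 1.5)
  # direct filter: ratio of condition means of the raw table
  sens <- rowMeans(ex$expr$values[, ex$expr$condition == "sensitive"])
  res <- rowMeans(ex$expr$values[, ex$expr$condition == "resistant"])
  direct <- rownames(ex$expr$values)[pmax(sens / res, res / sens) >= 1.5]
  null_direct <- setdiff(direct, m$truth$planted_genes)
  null_called <- setdiff(c(de$up, de$down), m$truth$planted_genes)
  expect_setequal(null_called, null_direct)
})

test_that("cohort structure follows the study design", {
  cfg <- synth_config(seed = 4)
  coh <- generate_cohort(cfg)$cohort
  responders <- coh[coh$response == "complete", ]
  expect_true(all(responders$timepoint == "pre"))
  non <- coh[coh$response == "non_response", ]
  expect_equal(sum(non$timepoint == "pre"), cfg$n_patients_nonresponder)
  expect_equal(sum(non$timepoint == "post"), cfg$n_patients_nonresponder)
  expect_true(all(c("age", "menopause", "er", "stage", "grade", "surgery")
                  %in% names(coh)))
})

test_that("a large planted cohort shift forces post > pre in every pair", {
  cfg <- synth_config(cohort_effect_pct = 24, cohort_noise_sd = 0.1, seed = 6)
  coh <- generate_cohort(cfg)$cohort
  res <- compare_pre_post(coh, paired_only = TRUE)
  expect_equal(res$fraction_increased, 1)
})

test_that("zero cohort effect leaves pre and post centred together", {
  shifts <- vapply(1:20, function(s) {
    cfg <- synth_config(cohort_effect_pct = 0, cohort_noise_sd = 5,
                        n_patients_nonresponder = 20, seed = s)
    coh <- generate_cohort(cfg)$cohort
    mean(compare_pre_post(coh, paired_only = TRUE)$deltas)
  }, 0)
  expect_lt(abs(mean(shifts)), 1)
})

test_that("cohort rank-sum p agrees with the permutation oracle", {
  # baseline far from 0 so no value clips to the boundary (clipped
  # values create ties, which route to the approximate test)
  cfg <- synth_config(cohort_effect_pct = 24, cohort_noise_sd = 5,
                      cohort_baseline_pct = 20,
                      n_patients_nonresponder = 5, seed = 3)
  coh <- generate_cohort(cfg)$cohort
  non <- coh[coh$response == "non_response", ]
  pre <- non$methylation_pct[non$timepoint == "pre"]
  post <- non$methylation_pct[non$timepoint == "post"]
  expect_equal(mann_whitney(pre, post)$p_value,
               perm_mann_whitney_p(pre, post))
})

test_that("fixture bundles round-trip losslessly and echo the manifest", {
  dir <- withr::local_tempdir()
  for (s in c(1, 21)) {
    cfg <- synth_config(n_probes = 150, n_genes = 30,
                        n_planted_hyper_down = 2, seed = s)
    bundle <- make_fixtures(cfg, file.path(dir, s))
    back <- read_fixture_bundle(file.path(dir, s))
    expect_equal(back$beta$values, bundle$beta$values)
    expect_equal(back$beta$condition, bundle$beta$condition)
    expect_equal(back$annotation, bundle$annotation)
    expect_equal(back$expr$values, bundle$expr$values)
    expect_equal(back$cohort, bundle$cohort)
    expect_setequal(back$manifest$planted_genes, bundle$truth$planted_genes)
    expect_setequal(back$manifest$planted_probes, bundle$truth$planted_probes)
    expect_identical(back$config, cfg)
  }
})

test_that("an empty cohort writes a header-only file", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_probes = 150, n_genes = 30,
                      n_planted_hyper_down = 2,
                      n_patients_responder = 0, n_patients_nonresponder = 0,
                      seed = 1)
  make_fixtures(cfg, dir)
  lines <- readLines(file.path(dir, "cohort.csv"))
  expect_length(lines, 1)
  expect_match(lines, "patient_id")
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_probes = 0))
  expect_error(synth_config(beta_noise_sd = -0.1))
  expect_error(synth_config(promoter_fraction = 1.2))
  expect_error(synth_config(n_genes = 5, n_planted_hyper_down = 6))
})
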