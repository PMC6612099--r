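test_that("dichotomization assigns the boundary to the high class", {
  expect_equal(dichotomize(c(6.08, 30.26, 20, 19.99)),
               c("low", "high", "high", "low"))
  expect_error(dichotomize(120), "\\[0, 100\\]")
  # the high class shrinks monotonically as the cutoff rises
  set.seed(5)
  vals <- runif(50, 0, 100)
  highs <- vapply(c(10, 20, 30, 50),
                  function(ct) sum(dichotomize(vals, ct) == "high"), 0L)
  expect_true(all(diff(highs) <= 0))
})

test_that("pre/post comparison reports deltas and the increased fraction", {
  cohort <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3"),
    timepoint = c("pre", "post", "pre", "post", "pre"),
    response = "non_response",
    methylation_pct = c(5, 30, 8, 25, 6),
    stringsAsFactors = FALSE)
  res <- compare_pre_post(cohort, paired_only = TRUE)
  expect_equal(unname(res$deltas), c(25, 17))
  expect_equal(res$fraction_increased, 1)
  expect_equal(res$n_pre, 2)
  # unpaired mode uses all samples
  expect_equal(compare_pre_post(cohort)$n_pre, 3)

  # no change at all: fraction 0 and p = 1
  flat <- data.frame(patient_id = rep(c("p1", "p2"), each = 2),
                     timepoint = rep(c("pre", "post"), 2),
                     response = "non_response",
                     methylation_pct = c(5, 5, 8, 8),
                     stringsAsFactors = FALSE)
  res_flat <- compare_pre_post(flat, paired_only = TRUE)
  expect_equal(res_flat$fraction_increased, 0)
  expect_equal(res_flat$test$p_value, 1)

  single <- data.frame(patient_id = "p1", timepoint = c("pre", "post"),
                       response = "non_response",
                       methylation_pct = c(5, 30), stringsAsFactors = FALSE)
  expect_equal(compare_pre_post(single, paired_only = TRUE)$fraction_increased, 1)
  expect_error(compare_pre_post(single[1, ], paired_only = TRUE),
               "no patients")
})

test_that("ROC AUC equals pair counting and perfect separation gives 1", {
  labels <- rep(c("pre", "post"), each = 4)
  r_perfect <- roc_eval(c(1, 2, 3, 4, 10, 11, 12, 13), labels, "post")
  expect_equal(r_perfect$auc, 1)

  # the worked 4-point case: one swap gives AUC 0.75
  r_swap <- roc_eval(c(1, 2, 3, 4), c("n", "p", "n", "p"), "p")
  expect_equal(r_swap$auc, 0.75)
  expect_equal(r_swap$auc,
               pair_count_auc(c(1, 2, 3, 4), c("n", "p", "n", "p"), "p"))

  # random scores with ties: identity still holds
  set.seed(11)
  for (i in 1:10) {
    scores <- sample(1:8, 30, replace = TRUE)
    labels <- sample(c("a", "b"), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_eval(scores, labels, "b")$auc,
                 pair_count_auc(scores, labels, "b"))
  }
})

test_that("ROC complement: negating scores flips the AUC", {
  set.seed(21)
  scores <- rnorm(40)
  labels <- rep(c("x", "y"), 20)
  a <- roc_eval(scores, labels, "y")$auc
  b <- roc_eval(-scores, labels, "y")$auc
  expect_equal(a + b, 1)
})

test_that("AUC agrees with the rank-sum concordance identity across modules", {
  set.seed(31)
  for (i in 1:5) {
    pos <- rnorm(12, 1)
    neg <- rnorm(15)
    auc <- roc_eval(c(pos, neg),
                    rep(c("p", "n"), c(12, 15)), "p")$auc
    u <- mann_whitney(pos, neg, mode = "approx")$statistic
    expect_equal(auc, u / (12 * 15))
  }
})

test_that("ROC validates labels and reports a DeLong interval around the AUC", {
  expect_error(roc_eval(1:4, rep("a", 4), "a"), "both classes")
  expect_error(roc_eval(1:4, rep("a", 4), "b"), "not present")
  set.seed(41)
  r <- roc_eval(c(rnorm(30), rnorm(30, 1.5)),
                rep(c("n", "p"), each = 30), "p")
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_true(r$ci_low >= 0 && r$ci_high <= 1)
})

test_that("logistic fit matches an independent damped Newton optimizer", {
  x <- c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- fit_univariate_logistic(x, y)
  ref <- newton_logistic(x, y)
  expect_lt(abs(fit$intercept - ref[1]), 1e-6)
  expect_lt(abs(fit$slope - ref[2]), 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separated)

  # mirror-symmetric data (x, y) <-> (-x, 1 - y): intercept 0 by symmetry
  expect_lt(abs(fit_univariate_logistic(c(-2, -1, -1, 1, 1, 2),
                                        c(0, 1, 0, 1, 0, 1))$intercept),
            1e-8)

  # response balanced at every x level: every fitted value is the event rate
  fit_flat <- fit_univariate_logistic(c(1, 1, 4, 4), c(1, 0, 1, 0))
  expect_equal(fit_flat$fitted, rep(0.5, 4), tolerance = 1e-6)
})

test_that("complete separation is flagged but probabilities are returned", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_univariate_logistic(x, y), "separation")
  expect_true(fit$separated)
  expect_length(fit$fitted, 6)
  expect_true(all(fit$fitted >= 0 & fit$fitted <= 1))
})

test_that("hosmer-lemeshow is zero for exactly calibrated bins", {
  # five distinct probability levels, each observed at its own rate
  p <- rep(c(0.1, 0.2, 0.5, 0.8, 0.9), each = 10)
  y <- unlist(lapply(c(0.1, 0.2, 0.5, 0.8, 0.9), function(pp)
    c(rep(1, round(10 * pp)), rep(0, 10 - round(10 * pp)))))
  hl <- hosmer_lemeshow(p, y, n_groups = 5)
  expect_equal(hl$chi_square, 0)
  expect_equal(hl$df, 3)
  expect_equal(hl$p_value, 1)
  expect_equal(sum(hl$bins$expected), sum(p))
})

test_that("hosmer-lemeshow statistic is invariant to monotone score relabeling", {
  set.seed(51)
  p <- runif(200, 0.05, 0.95)
  y <- rbinom(200, 1, p)
  a <- hosmer_lemeshow(p, y)
  # a strictly monotone transform preserving bin membership: identical
  # grouping, identical observed/expected, identical statistic
  ord <- order(p)
  b <- hosmer_lemeshow(p[ord], y[ord])
  expect_equal(a$chi_square, b$chi_square)
  expect_equal(a$p_value, b$p_value)
})

test_that("hosmer-lemeshow rejects miscalibrated probabilities", {
  set.seed(61)
  x <- rnorm(500)
  p_true <- plogis(-0.5 + 1.2 * x)
  y <- rbinom(500, 1, p_true)
  p_shift <- pmin(pmax(p_true + 0.3, 1e-6), 1 - 1e-6)
  expect_lt(hosmer_lemeshow(p_shift, y)$p_value, 0.05)
})

test_that("hosmer-lemeshow validates its inputs", {
  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)), "strictly")
  expect_error(hosmer_lemeshow(runif(20, 0.1, 0.9), rbinom(20, 1, 0.5),
                               n_groups = 2), "at least 3")
  expect_error(hosmer_lemeshow(runif(5, 0.1, 0.9), rbinom(5, 1, 0.5),
                               n_groups = 10), "fewer observations")
})

test_that("association scan picks the documented test per covariate type", {
  set.seed(71)
  n <- 40
  meth <- runif(n, 0, 60)
  covars <- data.frame(
    age = rnorm(n, 55, 8),
    er = sample(c("negative", "positive"), n, replace = TRUE),
    stage = sample(c("IIB", "IIIA", "IIIB"), n, replace = TRUE),
    constant = "same",
    stringsAsFactors = FALSE)
  expect_message(res <- association_scan(covars, meth), "single level")
  expect_equal(res$test[res$covariate == "age"], "spearman")
  expect_true(any(res$test[res$covariate == "er"] %in%
                    c("mann_whitney_exact", "mann_whitney_normal_approx")))
  expect_true("kruskal_wallis" %in% res$test[res$covariate == "stage"])
  expect_false("constant" %in% res$covariate)
  # categorical rows carry a contingency test against dichotomized levels
  expect_true(any(res$test[res$covariate == "er"] %in%
                    c("chi_square", "fisher_exact")))
})

test_that("the 3-0/0-3 contingency case gives the Fisher exact p of 0.1", {
  meth <- c(30, 35, 40, 5, 8, 10)  # dichotomizes to high,high,high,low,low,low
  covars <- data.frame(er = c("pos", "pos", "pos", "neg", "neg", "neg"),
                       stringsAsFactors = FALSE)
  res <- association_scan(covars, meth)
  fisher_row <- res[res$test == "fisher_exact", ]
  expect_equal(nrow(fisher_row), 1)
  expect_equal(fisher_row$p_value, 0.1)
})

test_that("association p-values are roughly uniform under independence", {
  set.seed(81)
  p_vals <- vapply(1:40, function(i) {
    meth <- runif(30, 0, 60)
    covars <- data.frame(age = rnorm(30))
    association_scan(covars, meth)$p_value[1]
  }, 0)
  expect_gt(mean(p_vals), 0.3)
  expect_lt(mean(p_vals), 0.7)
  expect_gt(min(p_vals), 0)
})

test_that("cohort reader validates the schema", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cohort.csv")
  write.csv(data.frame(patient_id = "p1", timepoint = "mid",
                       response = "complete", methylation_pct = 10),
            path, row.names = FALSE)
  expect_error(read_cohort_table(path), "timepoint")
  write.csv(data.frame(patient_id = "p1", timepoint = "post",
                       response = "complete", methylation_pct = 10),
            path, row.names = FALSE)
  expect_warning(read_cohort_table(path), "pre-treatment only")
})
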