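# Patient-cohort biomarker evaluation: methylation dichotomization,
# pre/post treatment comparison, empirical ROC with DeLong confidence
# intervals, univariate logistic calibration with the Hosmer-Lemeshow
# test, and the clinical covariate association scan.

COHORT_COLS <- c("patient_id", "timepoint", "response", "methylation_pct")

#' Read and validate a patient cohort table
#'
#' @param path CSV with columns `patient_id`, `timepoint`
#'   (`pre`/`post`), `response` (`complete`/`non_response`),
#'   `methylation_pct` in `[0, 100]`, plus any clinical covariate
#'   columns. Complete responders are expected to carry pre-treatment
#'   samples only; violations raise a warning, not an error.
#' @return The validated data frame.
#' @export
read_cohort_table <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(COHORT_COLS, names(cohort))
  if (length(missing) > 0L)
    stop("cohort table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(cohort) > 0L) {
    if (!all(cohort$timepoint %in% c("pre", "post")))
      stop("timepoint must be 'pre' or 'post'")
    if (!all(cohort$response %in% c("complete", "non_response")))
      stop("response must be 'complete' or 'non_response'")
    if (any(cohort$methylation_pct < 0 | cohort$methylation_pct > 100))
      stop("methylation_pct outside [0, 100]")
    if (any(cohort$timepoint == "post" & cohort$response == "complete"))
      warning("post-treatment sample(s) for complete responders; ",
              "the study design expects pre-treatment only")
  }
  cohort
}

#' Dichotomize percent methylation into low/high
#'
#' Values at or above the cutoff are `"high"` (ties assigned to the
#' risk class), values below are `"low"`.
#'
#' @param methylation_pct Numeric vector in `[0, 100]`.
#' @param cutoff Dichotomization cutoff in percent.
#' @return Character vector in `{"low", "high"}`.
#' @export
#' @examples
#' dichotomize(c(6.08, 30.26, 20))  # low, high, high
dichotomize <- function(methylation_pct, cutoff = 20) {
  if (any(!is.finite(methylation_pct)) ||
      any(methylation_pct < 0 | methylation_pct > 100))
    stop("methylation_pct must be finite and in [0, 100]")
  ifelse(methylation_pct >= cutoff, "high", "low")
}

#' Compare pre- and post-treatment methylation
#'
#' Unpaired mode compares all pre-treatment against all post-treatment
#' values with [mann_whitney()]. Paired mode restricts to patients with
#' both timepoints and additionally reports per-patient deltas
#' (post - pre), the fraction of patients whose methylation increased,
#' and a Wilcoxon signed-rank test alongside the rank-sum test.
#'
#' @param cohort Cohort data frame (see [read_cohort_table()]).
#' @param paired_only Restrict to patients with both timepoints.
#' @return List with `test` (rank-sum `ms_test`), `n_pre`, `n_post`,
#'   and in paired mode `deltas` (named by patient),
#'   `fraction_increased` and `signed_rank` (an `ms_test`).
#' @export
compare_pre_post <- function(cohort, paired_only = FALSE) {
  pre <- cohort[cohort$timepoint == "pre", , drop = FALSE]
  post <- cohort[cohort$timepoint == "post", , drop = FALSE]
  if (paired_only) {
    paired_ids <- intersect(pre$patient_id, post$patient_id)
    if (length(paired_ids) == 0L)
      stop("no patients with both timepoints")
    pre <- pre[match(paired_ids, pre$patient_id), , drop = FALSE]
    post <- post[match(paired_ids, post$patient_id), , drop = FALSE]
  }
  if (nrow(pre) == 0L || nrow(post) == 0L)
    stop("need at least one pre and one post value")
  out <- list(test = mann_whitney(pre$methylation_pct, post$methylation_pct),
              n_pre = nrow(pre), n_post = nrow(post))
  if (paired_only) {
    deltas <- post$methylation_pct - pre$methylation_pct
    names(deltas) <- pre$patient_id
    out$deltas <- deltas
    out$fraction_increased <- mean(deltas > 0)
    sr <- suppressWarnings(
      wilcox.test(post$methylation_pct, pre$methylation_pct, paired = TRUE))
    out$signed_rank <- structure(
      list(statistic = unname(sr$statistic), p_value = min(sr$p.value, 1),
           method = "wilcoxon_signed_rank",
           n = c(n_pairs = length(deltas))),
      class = "ms_test")
  }
  out
}

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' Empirical ROC over all distinct score thresholds; AUC by the
#' Mann-Whitney concordance identity (ties counted one half); 95%
#' confidence interval by the DeLong variance estimator (the default of
#' the MedCalc-style analysis) or by stratified bootstrap; the
#' Youden-optimal threshold is reported.
#'
#' @param scores Numeric marker values (here, percent methylation).
#' @param labels Class labels; both classes must be present.
#' @param positive_label The label treated as positive (higher scores
#'   expected).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return List of class `roc_eval` with `auc`, `ci_low`, `ci_high`,
#'   `youden_threshold`, `curve` (data frame `threshold`,
#'   `sensitivity`, `specificity`), `n_pos`, `n_neg`.
#' @export
roc_eval <- function(scores, labels, positive_label,
                     ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  if (!positive_label %in% labels)
    stop("positive_label not present in labels")
  is_pos <- labels == positive_label
  if (all(is_pos) || !any(is_pos))
    stop("both classes must be present")
  response <- factor(ifelse(is_pos, "pos", "neg"), levels = c("neg", "pos"))
  r <- pROC::roc(response = response, predictor = scores,
                 levels = c("neg", "pos"), direction = "<", quiet = TRUE)
  # a degenerate CI at AUC == 1 is still a valid report; keep it quiet
  ci <- suppressWarnings(
    if (ci_method == "delong")
      pROC::ci.auc(r, method = "delong")
    else
      pROC::ci.auc(r, method = "bootstrap", boot.n = 2000, progress = "none"))
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = "threshold", transpose = FALSE)
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 youden_threshold = as.numeric(best$threshold[1]),
                 curve = as.data.frame(co),
                 n_pos = sum(is_pos), n_neg = sum(!is_pos)),
            class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (95%% CI %.4f-%.4f), %d pos / %d neg, Youden threshold %.4g\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg,
              x$youden_threshold))
  invisible(x)
}

#' Univariate logistic regression fit
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence when the deviance change is below `1e-10`, at most 100
#' iterations). Complete or quasi-complete separation is detected and
#' flagged with a warning; the coefficients of the last iterate and the
#' fitted probabilities are still returned.
#'
#' @param x Finite numeric predictor.
#' @param y Binary outcome (0/1, logical, or two-level factor).
#' @return List with `intercept`, `slope`, `fitted`, `converged`,
#'   `separated`.
#' @export
fit_univariate_logistic <- function(x, y) {
  if (any(!is.finite(x)))
    stop("predictor must be finite")
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary")
  if (length(unique(y)) < 2L)
    stop("both outcomes must be present")
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- unname(fitted(fit))
  separated <- warned && (max(abs(coef(fit))) > 15 ||
                          all(p < 1e-8 | p > 1 - 1e-8))
  if (separated)
    warning("separation detected: coefficients diverge; ",
            "probabilities from the last stable iterate")
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       fitted = p, converged = fit$converged, separated = separated)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Observations are sorted by predicted probability and split into
#' `n_groups` quantile bins (tied probabilities stay together; empty
#' bins arising from ties collapse into their neighbours). The
#' statistic is `sum((O - E)^2 / (E * (1 - E / n_g)))` over bins, with
#' `df = G - 2` and an upper-tail chi-square p-value, where `G` is the
#' number of bins actually formed.
#'
#' @param pred_prob Predicted probabilities in `(0, 1)`.
#' @param outcomes Binary outcomes (0/1).
#' @param n_groups Number of quantile bins (deciles by default).
#' @return List of class `hl_test` with `chi_square`, `df`, `p_value`,
#'   `n_groups` and a per-bin `bins` data frame (`n`, `observed`,
#'   `expected`, `mean_pred`).
#' @export
hosmer_lemeshow <- function(pred_prob, outcomes, n_groups = 10) {
  if (any(pred_prob <= 0 | pred_prob >= 1))
    stop("predicted probabilities must lie strictly in (0, 1)")
  outcomes <- as.numeric(outcomes)
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary")
  if (n_groups < 3L)
    stop("need at least 3 groups")
  if (length(pred_prob) < n_groups)
    stop("fewer observations than groups")
  breaks <- unique(quantile(pred_prob, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(breaks) < 4L)
    stop("fewer than 3 distinct bins after collapsing ties")
  bin <- cut(pred_prob, breaks = breaks, include.lowest = TRUE)
  n_g <- tabulate(bin, nbins = nlevels(bin))
  keep <- n_g > 0L
  obs <- vapply(split(outcomes, bin), sum, 0)[keep]
  exp_ <- vapply(split(pred_prob, bin), sum, 0)[keep]
  n_g <- n_g[keep]
  g <- length(n_g)
  if (g < 3L)
    stop("fewer than 3 non-empty bins")
  chi_square <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / n_g)))
  df <- g - 2L
  structure(list(chi_square = chi_square, df = df,
                 p_value = pchisq(chi_square, df, lower.tail = FALSE),
                 n_groups = g,
                 bins = data.frame(n = n_g, observed = obs,
                                   expected = exp_,
                                   mean_pred = exp_ / n_g,
                                   row.names = NULL)),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi-square = %.4f on %d df, p = %.4f (%d bins)\n",
              x$chi_square, x$df, x$p_value, x$n_groups))
  invisible(x)
}

#' Scan clinical covariates for association with methylation
#'
#' One row per covariate: Spearman correlation for continuous
#' covariates, rank-sum for two-level categorical, Kruskal-Wallis for
#' more levels. Categorical covariates are additionally cross-tabulated
#' against dichotomized methylation and tested with the chi-square
#' test, switching to the Fisher exact test when any expected cell
#' count is below 5. Covariates with a single observed level are
#' skipped with a message.
#'
#' @param covariates Data frame of clinical covariates, one row per
#'   patient.
#' @param methylation_pct Numeric vector aligned with `covariates`.
#' @param cutoff Dichotomization cutoff passed to [dichotomize()].
#' @return Data frame with columns `covariate`, `test`, `statistic`,
#'   `p_value`.
#' @export
association_scan <- function(covariates, methylation_pct, cutoff = 20) {
  stopifnot(nrow(covariates) == length(methylation_pct))
  meth_group <- dichotomize(methylation_pct, cutoff)
  rows <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    ok <- !is.na(v) & !is.na(methylation_pct)
    v_ok <- v[ok]
    m_ok <- methylation_pct[ok]
    if (length(unique(v_ok)) < 2L) {
      message("skipping covariate '", nm, "': single level")
      next
    }
    if (is.numeric(v_ok)) {
      ct <- suppressWarnings(cor.test(v_ok, m_ok, method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = nm, test = "spearman",
        statistic = unname(ct$estimate), p_value = ct$p.value,
        stringsAsFactors = FALSE)
    } else {
      groups <- split(m_ok, v_ok)
      groups <- groups[lengths(groups) > 0L]
      mt <- kruskal_wallis(groups)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = nm, test = mt$method,
        statistic = mt$statistic, p_value = mt$p_value,
        stringsAsFactors = FALSE)
      tab <- table(v_ok, meth_group[ok])
      if (all(dim(tab) >= 2L)) {
        expected <- suppressWarnings(chisq.test(tab)$expected)
        if (any(expected < 5)) {
          ft <- fisher.test(tab)
          rows[[length(rows) + 1L]] <- data.frame(
            covariate = nm, test = "fisher_exact",
            statistic = NA_real_, p_value = ft$p.value,
            stringsAsFactors = FALSE)
        } else {
          xt <- suppressWarnings(chisq.test(tab))
          rows[[length(rows) + 1L]] <- data.frame(
            covariate = nm, test = "chi_square",
            statistic = unname(xt$statistic), p_value = xt$p.value,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(covariate = character(), test = character(),
                      statistic = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
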