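# Candidate-validation numerics: pyrosequencing window averaging,
# 2^-ddCt relative expression, rank tests with explicit exact/approximate
# mode selection, and the demethylating-agent restoration comparison.

#' Mean percent methylation across a pyrosequencing window
#'
#' The per-assay summary value: the arithmetic mean of the per-CpG
#' percent-methylation calls in the sequenced window.
#'
#' @param per_cpg_pct Numeric vector of per-CpG percentages in
#'   `[0, 100]`, at least one value.
#' @return The mean percentage.
#' @export
pyro_mean <- function(per_cpg_pct) {
  if (length(per_cpg_pct) == 0L)
    stop("need at least one CpG value")
  if (any(!is.finite(per_cpg_pct)) ||
      any(per_cpg_pct < 0 | per_cpg_pct > 100))
    stop("percent methylation must be finite and in [0, 100]")
  mean(per_cpg_pct)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per-sample `dCt = ct_target - ct_reference` (the reference being an
#' endogenous control such as GAPDH), group-mean dCt, then
#' `ddCt = mean dCt(group) - mean dCt(calibrator)` and relative
#' expression `2^-ddCt`. The calibrator group's relative expression is
#' exactly 1 by construction.
#'
#' @param measurements Data frame with columns `sample_id`, `group`,
#'   `ct_target`, `ct_reference`.
#' @param calibrator_group Group label used as calibrator.
#' @return Data frame with columns `group`, `n`, `mean_dct`, `ddct`,
#'   `rel_expr`.
#' @export
relative_expression <- function(measurements, calibrator_group) {
  needed <- c("sample_id", "group", "ct_target", "ct_reference")
  missing <- setdiff(needed, names(measurements))
  if (length(missing) > 0L)
    stop("measurements missing column(s): ", paste(missing, collapse = ", "))
  if (!calibrator_group %in% measurements$group)
    stop("calibrator group '", calibrator_group, "' not present")
  ct <- measurements[, c("ct_target", "ct_reference")]
  if (any(!is.finite(as.matrix(ct))) || any(as.matrix(ct) <= 0))
    stop("Ct values must be finite and positive")
  dct <- measurements$ct_target - measurements$ct_reference
  mean_dct <- tapply(dct, measurements$group, mean)
  ddct <- mean_dct - mean_dct[[calibrator_group]]
  data.frame(group = names(mean_dct),
             n = as.integer(table(measurements$group)[names(mean_dct)]),
             mean_dct = unname(mean_dct),
             ddct = unname(ddct),
             rel_expr = unname(2^(-ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample Mann-Whitney U test
#'
#' Two-sided rank-sum test. In `"auto"` mode the exact null
#' distribution is used when `length(x) + length(y) <= 12` and there
#' are no ties across the pooled sample; otherwise the normal
#' approximation with tie and continuity correction is used. The
#' reported statistic is U for `x`, i.e. the number of (x, y) pairs
#' with `x > y` counting ties one half.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List of class `ms_test` with elements `statistic`,
#'   `p_value`, `method`, `n` (per-group sizes).
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value  # exact two-sided 1/3
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    # all pooled values identical: no evidence either way
    return(structure(list(statistic = length(x) * length(y) / 2,
                          p_value = 1,
                          method = "mann_whitney_degenerate",
                          n = c(n_x = length(x), n_y = length(y))),
                     class = "ms_test"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = length(x) + length(y) <= 12L && !ties,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties)
    stop("exact mode is unavailable with ties")
  ht <- wilcox.test(x, y, exact = exact, correct = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 p_value = min(ht$p.value, 1),
                 method = if (exact) "mann_whitney_exact"
                          else "mann_whitney_normal_approx",
                 n = c(n_x = length(x), n_y = length(y))),
            class = "ms_test")
}

#' @export
print.ms_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), ", n = ",
      paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis rank test for three or more groups
#'
#' H statistic with tie correction and a chi-square p-value on `k - 1`
#' degrees of freedom. With exactly two groups the comparison falls
#' back to [mann_whitney()].
#'
#' @param groups List of non-empty numeric vectors.
#' @return An `ms_test` list (see [mann_whitney()]).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(lengths(groups) == 0L))
    stop("empty group")
  if (length(groups) == 2L)
    return(mann_whitney(groups[[1]], groups[[2]]))
  ht <- kruskal.test(groups)
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = "kruskal_wallis",
                 n = lengths(groups)),
            class = "ms_test")
}

#' Expression-restoration comparison across demethylating-agent doses
#'
#' For each dose group, compares relative-expression values against the
#' untreated group with [mann_whitney()] and flags restoration when the
#' dose median exceeds the untreated median and `p < alpha`.
#'
#' @param untreated Numeric vector of relative-expression values in the
#'   untreated condition.
#' @param dose_groups Named list of numeric vectors, one per dose.
#' @param alpha Significance level.
#' @return Data frame with columns `dose`, `n`, `statistic`, `p_value`,
#'   `increased`, `restored`.
#' @export
restoration_test <- function(untreated, dose_groups, alpha = 0.05) {
  if (length(untreated) == 0L)
    stop("untreated group is empty")
  if (!is.list(dose_groups) || length(dose_groups) == 0L)
    stop("need at least one dose group")
  if (is.null(names(dose_groups)))
    names(dose_groups) <- paste0("dose_", seq_along(dose_groups))
  rows <- lapply(names(dose_groups), function(nm) {
    dose <- dose_groups[[nm]]
    if (length(dose) == 0L)
      stop("dose group '", nm, "' is empty")
    mt <- mann_whitney(dose, untreated)
    increased <- median(dose) > median(untreated)
    data.frame(dose = nm, n = length(dose),
               statistic = mt$statistic, p_value = mt$p_value,
               increased = increased,
               restored = increased && mt$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a pyrosequencing per-CpG table
#'
#' @param path CSV with columns `sample_id`, `gene`, `cpg_index`, `pct`.
#' @return Data frame with per-assay rows `sample_id`, `gene`,
#'   `n_cpgs`, `mean_pct`.
#' @export
read_pyro_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "gene", "cpg_index", "pct")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L)
    stop("pyro table missing column(s): ", paste(missing, collapse = ", "))
  key <- interaction(tab$sample_id, tab$gene, drop = TRUE)
  rows <- lapply(split(tab, key), function(a) {
    data.frame(sample_id = a$sample_id[1], gene = a$gene[1],
               n_cpgs = nrow(a), mean_pct = pyro_mean(a$pct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
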