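# Orchestration: threshold configuration, the discovery filter chain in
# the published order, and the cohort biomarker run.

#' Pipeline configuration with the published thresholds as defaults
#'
#' @param delta_min Gain/loss and clustering delta-beta threshold.
#' @param stringent_low,stringent_high Stringent classification
#'   thresholds.
#' @param stringent_tol Rounding tolerance for stringent comparisons
#'   (0 for raw data; 0.005 when validating tables printed at two
#'   decimals).
#' @param fc_min Inclusive expression fold-change threshold.
#' @param min_cpgs Minimum stringent CpGs for a shortlisted candidate.
#' @param cutoff_pct Methylation dichotomization cutoff, percent.
#' @param detection_p_max Detection p-value threshold.
#' @param alpha Significance level.
#' @param exclude_chromosomes Chromosomes removed before analysis.
#' @param regulatory_policy `"island_and_promoter"` or
#'   `"island_or_promoter"`.
#' @param seed Integer seed used by stochastic downstream steps.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(delta_min = 0.20, stringent_low = 0.20,
                            stringent_high = 0.60, stringent_tol = 0,
                            fc_min = 1.5, min_cpgs = 3, cutoff_pct = 20,
                            detection_p_max = 0.01, alpha = 0.05,
                            exclude_chromosomes = c("X", "Y"),
                            regulatory_policy = "island_and_promoter",
                            seed = 1L) {
  config <- list(delta_min = delta_min, stringent_low = stringent_low,
                 stringent_high = stringent_high,
                 stringent_tol = stringent_tol, fc_min = fc_min,
                 min_cpgs = as.integer(min_cpgs), cutoff_pct = cutoff_pct,
                 detection_p_max = detection_p_max, alpha = alpha,
                 exclude_chromosomes = as.character(exclude_chromosomes),
                 regulatory_policy = match.arg(
                   regulatory_policy,
                   c("island_and_promoter", "island_or_promoter")),
                 seed = as.integer(seed))
  with(config, {
    stopifnot(delta_min > 0, delta_min <= 1,
              stringent_low >= 0, stringent_low < stringent_high,
              stringent_high <= 1, stringent_tol >= 0,
              fc_min >= 1, min_cpgs >= 1,
              cutoff_pct >= 0, cutoff_pct <= 100,
              detection_p_max > 0, detection_p_max <= 1,
              alpha > 0, alpha < 1)
  })
  structure(config, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the published defaults.
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the discovery cascade
#'
#' Executes the published filter chain in order: detection-p filter and
#' sex-chromosome exclusion, regulatory (promoter-island) restriction,
#' stringent hyper/hypomethylation classification, gene-level
#' aggregation, intersection with the expression fold-change sets, and
#' candidate ranking. The report records the count surviving each
#' stage, which is monotone non-increasing along the chain.
#'
#' @param beta A [beta_matrix()].
#' @param annotation Probe annotation data frame.
#' @param expr An [expr_table()]; may contain zero genes.
#' @param config A [pipeline_config()].
#' @return List of class `discovery_report`: `stage_counts`,
#'   `records`, `summaries`, `venn_counts`, `candidates`,
#'   `concordance_r2`, `config`, `version`.
#' @export
run_discovery <- function(beta, annotation, expr,
                          config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  filtered <- filter_probes(beta, annotation,
                            exclude_chromosomes = config$exclude_chromosomes,
                            detection_p_max = config$detection_p_max)
  records <- diffmeth_records(filtered, threshold = config$delta_min,
                              low = config$stringent_low,
                              high = config$stringent_high,
                              tol = config$stringent_tol)
  assignments <- select_regulatory(annotation,
                                   policy = config$regulatory_policy)
  assignments <- assignments[assignments$probe_id %in% records$probe_id, ,
                             drop = FALSE]
  regulatory_records <- records[records$probe_id %in% assignments$probe_id, ,
                                drop = FALSE]
  summaries <- summarize_genes(regulatory_records, assignments)
  n_stringent <- sum(regulatory_records$stringent_class != "none")

  if (nrow(expr$values) > 0L) {
    de <- classify_de(fold_change(expr), fc_min = config$fc_min)
  } else {
    de <- list(up = character(), down = character(),
               calls = data.frame(gene = character(),
                                  fold_change = numeric(),
                                  direction = character(),
                                  stringsAsFactors = FALSE))
  }
  venn <- intersect_meth_expr(summaries, de)
  shortlist <- rank_candidates(venn$candidates, min_cpgs = config$min_cpgs)

  stage_counts <- c(
    probes_input = nrow(beta$values),
    probes_after_filter = nrow(filtered$values),
    probes_regulatory = length(unique(assignments$probe_id)),
    probes_stringent = n_stringent,
    genes_stringent = nrow(summaries),
    genes_hyper_down = unname(venn$counts["hyper_down"]),
    candidates_final = nrow(shortlist))

  structure(list(stage_counts = stage_counts,
                 records = records,
                 summaries = summaries,
                 venn_counts = venn$counts,
                 candidates = shortlist,
                 concordance_r2 = if (nrow(filtered$values) >= 2L &&
                                      stats::sd(records$beta_sens) > 0 &&
                                      stats::sd(records$beta_res) > 0)
                   global_concordance(filtered) else NA_real_,
                 config = config,
                 version = as.character(packageVersion("methscreen"))),
            class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("Discovery run (methscreen", x$version, ")\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-22s %d\n", nm, x$stage_counts[[nm]]))
  cat(sprintf("  concordance r^2        %.4f\n", x$concordance_r2))
  if (nrow(x$candidates) > 0L) {
    cat("  shortlist:\n")
    print(x$candidates, row.names = FALSE)
  }
  invisible(x)
}

#' Run the cohort biomarker evaluation
#'
#' Runs the pre/post comparison (unpaired and paired), the low/high
#' dichotomization summary, ROC of post-treatment non-responder samples
#' (positives) against pre-treatment samples (negatives), univariate
#' logistic calibration with the Hosmer-Lemeshow test, and the clinical
#' covariate association scan on post-treatment non-responder
#' methylation. Analyses that the cohort cannot support (single-class
#' labels, too few observations) are skipped and listed in `skipped`
#' with a reason; the rest still runs.
#'
#' @param cohort Cohort data frame (see [read_cohort_table()]).
#' @param config A [pipeline_config()].
#' @return List of class `cohort_report`.
#' @export
run_cohort <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  skipped <- character()
  report <- list(config = config,
                 version = as.character(packageVersion("methscreen")))

  report$dichotomized <- table(
    timepoint = cohort$timepoint,
    methylation = dichotomize(cohort$methylation_pct, config$cutoff_pct))

  report$pre_post <- tryCatch(compare_pre_post(cohort, paired_only = FALSE),
                              error = function(e) {
                                skipped <<- c(skipped,
                                              paste("pre_post:", conditionMessage(e)))
                                NULL
                              })
  report$pre_post_paired <- tryCatch(compare_pre_post(cohort, paired_only = TRUE),
                                     error = function(e) {
                                       skipped <<- c(skipped,
                                                     paste("pre_post_paired:",
                                                           conditionMessage(e)))
                                       NULL
                                     })

  # resistance labelling: post-treatment non-responder samples are the
  # positives, all pre-treatment samples the negatives
  roc_rows <- cohort[cohort$timepoint == "pre" |
                       (cohort$timepoint == "post" &
                          cohort$response == "non_response"), , drop = FALSE]
  labels <- ifelse(roc_rows$timepoint == "post", "resistant_post", "pre")
  report$roc <- tryCatch(
    roc_eval(roc_rows$methylation_pct, labels, "resistant_post"),
    error = function(e) {
      skipped <<- c(skipped, paste("roc:", conditionMessage(e)))
      NULL
    })

  report$logistic <- tryCatch({
    y <- as.integer(labels == "resistant_post")
    fit <- suppressWarnings(
      fit_univariate_logistic(roc_rows$methylation_pct, y))
    hl <- tryCatch(
      hosmer_lemeshow(pmin(pmax(fit$fitted, 1e-12), 1 - 1e-12), y,
                      n_groups = min(10L, max(3L, floor(length(y) / 2)))),
      error = function(e) {
        skipped <<- c(skipped,
                      paste("hosmer_lemeshow:", conditionMessage(e)))
        NULL
      })
    list(fit = fit, hosmer_lemeshow = hl)
  }, error = function(e) {
    skipped <<- c(skipped, paste("logistic:", conditionMessage(e)))
    NULL
  })

  post_non <- cohort[cohort$timepoint == "post" &
                       cohort$response == "non_response", , drop = FALSE]
  covar_cols <- setdiff(names(cohort), c(COHORT_COLS))
  report$association <- if (nrow(post_non) >= 3L && length(covar_cols) > 0L) {
    suppressMessages(
      association_scan(post_non[, covar_cols, drop = FALSE],
                       post_non$methylation_pct, cutoff = config$cutoff_pct))
  } else {
    skipped <- c(skipped, "association: fewer than 3 post-treatment non-responder samples")
    NULL
  }

  report$skipped <- skipped
  structure(report, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort run (methscreen", x$version, ")\n")
  if (!is.null(x$pre_post))
    cat(sprintf("  pre vs post (unpaired): p = %.4g (n = %d/%d)\n",
                x$pre_post$test$p_value, x$pre_post$n_pre, x$pre_post$n_post))
  if (!is.null(x$pre_post_paired))
    cat(sprintf("  paired: %d/%d increased (%.0f%%), rank-sum p = %.4g, signed-rank p = %.4g\n",
                sum(x$pre_post_paired$deltas > 0),
                length(x$pre_post_paired$deltas),
                100 * x$pre_post_paired$fraction_increased,
                x$pre_post_paired$test$p_value,
                x$pre_post_paired$signed_rank$p_value))
  if (!is.null(x$roc))
    print(x$roc)
  if (!is.null(x$logistic) && !is.null(x$logistic$hosmer_lemeshow))
    print(x$logistic$hosmer_lemeshow)
  if (length(x$skipped) > 0L)
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Generate and write the synthetic fixture bundle
#'
#' Thin wrapper tying the synthetic-data generator to the fixture
#' writer.
#'
#' @param config A [synth_config()].
#' @param directory Output directory.
#' @return The study bundle, invisibly.
#' @export
make_fixtures <- function(config = synth_config(), directory) {
  bundle <- generate_study(config)
  write_fixture_bundle(bundle, directory)
  invisible(bundle)
}
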