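# Seeded synthetic study generator. Emulates the five study inputs —
# two-condition 450K-style beta values with planted promoter-island
# hypermethylated genes, expression coupled to the planted silencing,
# pyrosequencing-scale cohort methylation with a planted post-treatment
# shift in non-responders — and carries a ground-truth manifest so
# recovery by the discovery cascade can be scored exactly.

#' Synthetic study configuration
#'
#' Defaults emulate the magnitudes of the study being modelled: planted
#' promoter-island probes at beta 0.10 (sensitive) vs 0.70 (resistant),
#' logit-scale beta noise, a planted 4-fold expression knockdown, and a
#' cohort with a +24 percentage-point post-treatment methylation shift
#' in non-responders over a 6% baseline.
#'
#' @param n_probes Total number of array probes.
#' @param n_genes Number of genes in the study universe.
#' @param n_planted_hyper_down Number of genes planted as
#'   hypermethylated-and-downregulated (each receives 3-5
#'   promoter-island probes).
#' @param promoter_fraction Fraction of non-planted probes annotated to
#'   promoter-class regions.
#' @param island_fraction Fraction of non-planted probes located in CpG
#'   islands.
#' @param replicates_per_condition Arrays per condition (>= 1).
#' @param beta_noise_sd Standard deviation of logit-scale measurement
#'   noise (>= 0).
#' @param planted_beta_sens,planted_beta_res True beta of planted
#'   probes in the sensitive / resistant condition.
#' @param expr_log2fc_planted Planted log2 downregulation of planted
#'   genes in the resistant condition (>= 0).
#' @param expr_noise_sd Log2-scale expression noise sd (>= 0).
#' @param n_patients_responder Complete responders (pre-treatment
#'   samples only).
#' @param n_patients_nonresponder Non-responders (paired pre/post
#'   samples).
#' @param cohort_baseline_pct Pre-treatment methylation baseline in
#'   percent.
#' @param cohort_effect_pct Planted post-treatment methylation increase
#'   in non-responders, percentage points (>= 0).
#' @param cohort_noise_sd Cohort methylation noise sd in percentage
#'   points.
#' @param xy_fraction Fraction of non-planted probes placed on
#'   chromosomes X/Y so the sex-chromosome filter is always exercised.
#' @param seed Integer seed; identical configurations generate
#'   bit-identical data.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_probes = 2000, n_genes = 300,
                         n_planted_hyper_down = 10,
                         promoter_fraction = 0.4, island_fraction = 0.35,
                         replicates_per_condition = 3,
                         beta_noise_sd = 0.3,
                         planted_beta_sens = 0.10, planted_beta_res = 0.70,
                         expr_log2fc_planted = 2, expr_noise_sd = 0.25,
                         n_patients_responder = 4,
                         n_patients_nonresponder = 10,
                         cohort_baseline_pct = 6, cohort_effect_pct = 24,
                         cohort_noise_sd = 5,
                         xy_fraction = 0.05, seed = 1L) {
  config <- list(n_probes = as.integer(n_probes),
                 n_genes = as.integer(n_genes),
                 n_planted_hyper_down = as.integer(n_planted_hyper_down),
                 promoter_fraction = promoter_fraction,
                 island_fraction = island_fraction,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 beta_noise_sd = beta_noise_sd,
                 planted_beta_sens = planted_beta_sens,
                 planted_beta_res = planted_beta_res,
                 expr_log2fc_planted = expr_log2fc_planted,
                 expr_noise_sd = expr_noise_sd,
                 n_patients_responder = as.integer(n_patients_responder),
                 n_patients_nonresponder = as.integer(n_patients_nonresponder),
                 cohort_baseline_pct = cohort_baseline_pct,
                 cohort_effect_pct = cohort_effect_pct,
                 cohort_noise_sd = cohort_noise_sd,
                 xy_fraction = xy_fraction,
                 seed = as.integer(seed))
  with(config, {
    stopifnot(n_probes > 0, n_genes > 0, n_planted_hyper_down >= 0,
              n_planted_hyper_down <= n_genes,
              promoter_fraction >= 0, promoter_fraction <= 1,
              island_fraction >= 0, island_fraction <= 1,
              xy_fraction >= 0, xy_fraction <= 1,
              replicates_per_condition >= 1,
              beta_noise_sd >= 0, expr_noise_sd >= 0, cohort_noise_sd >= 0,
              planted_beta_sens > 0, planted_beta_sens < 1,
              planted_beta_res > 0, planted_beta_res < 1,
              expr_log2fc_planted >= 0, cohort_effect_pct >= 0,
              n_patients_responder >= 0, n_patients_nonresponder >= 0)
  })
  if (config$n_probes < 5L * config$n_planted_hyper_down + 2L)
    stop("n_probes too small for the planted probes (3-5 per planted gene)")
  structure(config, class = "synth_config")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a synthetic two-condition methylome
#'
#' Planted genes receive 3-5 promoter CpG-island probes on autosomes
#' with true beta `planted_beta_sens` / `planted_beta_res`; all other
#' probes share a common per-probe baseline across conditions. Noise is
#' Gaussian on the logit scale (inverse-transformed and clipped to
#' `[0, 1]`), so with `beta_noise_sd = 0` the planted probes are
#' stringently hypermethylated by construction. A fixed fraction of
#' non-planted probes lies on chromosomes X and Y.
#'
#' @param config A [synth_config()].
#' @return List with `beta` (a [beta_matrix()]), `annotation` (data
#'   frame) and `truth` (list of class `ground_truth`: `planted_genes`,
#'   `planted_probes`, `probe_gene` map, `beta_means`, `xy_probes`).
#' @export
generate_methylome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  planted <- sort(sample(genes, config$n_planted_hyper_down))
  n_pp <- if (length(planted) > 0L)
    sample(3:5, length(planted), replace = TRUE) else integer()
  n_planted_probes <- sum(n_pp)
  n_rest <- config$n_probes - n_planted_probes

  probe_ids <- sprintf("cg%08d", sample.int(99999999L, config$n_probes))
  planted_probe_ids <- probe_ids[seq_len(n_planted_probes)]
  rest_ids <- probe_ids[seq_len(n_rest) + n_planted_probes]

  planted_gene_of_probe <- rep(planted, n_pp)
  planted_ann <- data.frame(
    TargetID = planted_probe_ids,
    Chr = as.character(sample(1:22, n_planted_probes, replace = TRUE)),
    Position = sample.int(2e8L, n_planted_probes),
    Gene_Name = planted_gene_of_probe,
    Gene_Region = sample(PROMOTER_REGIONS, n_planted_probes, replace = TRUE),
    Island_Relation = "Island",
    stringsAsFactors = FALSE)

  n_xy <- round(config$xy_fraction * n_rest)
  rest_chr <- c(sample(c("X", "Y"), n_xy, replace = TRUE),
                as.character(sample(1:22, n_rest - n_xy, replace = TRUE)))
  rest_chr <- sample(rest_chr)
  rest_genes <- setdiff(genes, planted)
  rest_promoter <- stats::runif(n_rest) < config$promoter_fraction
  rest_region <- ifelse(rest_promoter,
                        sample(PROMOTER_REGIONS, n_rest, replace = TRUE),
                        sample(c("Body", "3'UTR"), n_rest, replace = TRUE))
  rest_island <- stats::runif(n_rest) < config$island_fraction
  rest_relation <- ifelse(rest_island, "Island",
                          sample(c("N_Shore", "S_Shore", "N_Shelf",
                                   "S_Shelf", "OpenSea"),
                                 n_rest, replace = TRUE))
  rest_ann <- data.frame(
    TargetID = rest_ids,
    Chr = rest_chr,
    Position = sample.int(2e8L, n_rest),
    Gene_Name = sample(rest_genes, n_rest, replace = TRUE),
    Gene_Region = rest_region,
    Island_Relation = rest_relation,
    stringsAsFactors = FALSE)
  annotation <- rbind(planted_ann, rest_ann)

  # true logit means: planted probes differ by condition, others do not;
  # island background is mostly unmethylated, open sea mostly methylated
  rest_base <- rnorm(n_rest, mean = ifelse(rest_island, -2, 1.5), sd = 1)
  true_sens <- c(rep(qlogis(config$planted_beta_sens), n_planted_probes),
                 rest_base)
  true_res <- c(rep(qlogis(config$planted_beta_res), n_planted_probes),
                rest_base)

  r <- config$replicates_per_condition
  sample_ids <- c(paste0("sens_", seq_len(r)), paste0("res_", seq_len(r)))
  condition <- setNames(rep(CONDITIONS, each = r), sample_ids)
  true_logit <- cbind(matrix(true_sens, config$n_probes, r),
                      matrix(true_res, config$n_probes, r))
  noise <- matrix(rnorm(length(true_logit), sd = config$beta_noise_sd),
                  nrow = config$n_probes)
  values <- clip01(plogis(true_logit + noise))
  dimnames(values) <- list(probe_ids, sample_ids)

  truth <- structure(list(
    planted_genes = planted,
    planted_probes = planted_probe_ids,
    probe_gene = setNames(planted_gene_of_probe, planted_probe_ids),
    beta_means = data.frame(gene = planted,
                            beta_sens = config$planted_beta_sens,
                            beta_res = config$planted_beta_res,
                            n_probes = n_pp,
                            stringsAsFactors = FALSE),
    xy_probes = annotation$TargetID[annotation$Chr %in% c("X", "Y")],
    genes = genes,
    config = config), class = "ground_truth")

  list(beta = beta_matrix(values, condition),
       annotation = annotation,
       truth = truth)
}

#' Generate expression coupled to the planted silencing
#'
#' Planted genes are downregulated in the resistant condition by
#' `expr_log2fc_planted` on the log2 scale; all other genes share a
#' common mean across conditions. Values are `2^(log2 mean + noise)`,
#' hence strictly positive.
#'
#' @param truth Ground truth from [generate_methylome()] (same run).
#' @param config The same [synth_config()].
#' @return List with `expr` (an [expr_table()]) and the updated
#'   `truth` carrying `expr_means` (per-gene true log2 levels).
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "synth_config"))
  if (!identical(truth$config$seed, config$seed))
    stop("truth and config come from different runs")
  set.seed(config$seed + 1L)
  genes <- truth$genes
  base <- rnorm(length(genes), mean = 5, sd = 1.5)
  log2_sens <- base
  log2_res <- base - ifelse(genes %in% truth$planted_genes,
                            config$expr_log2fc_planted, 0)
  r <- config$replicates_per_condition
  sample_ids <- c(paste0("sens_", seq_len(r)), paste0("res_", seq_len(r)))
  condition <- setNames(rep(CONDITIONS, each = r), sample_ids)
  true_log2 <- cbind(matrix(log2_sens, length(genes), r),
                     matrix(log2_res, length(genes), r))
  noise <- matrix(rnorm(length(true_log2), sd = config$expr_noise_sd),
                  nrow = length(genes))
  values <- 2^(true_log2 + noise)
  dimnames(values) <- list(genes, sample_ids)
  truth$expr_means <- data.frame(gene = genes, log2_sens = log2_sens,
                                 log2_res = log2_res,
                                 stringsAsFactors = FALSE)
  list(expr = expr_table(values, condition), truth = truth)
}

#' Generate a synthetic patient cohort
#'
#' Complete responders contribute pre-treatment samples only;
#' non-responders contribute paired pre/post samples. Pre-treatment
#' methylation is drawn near a common low baseline for both groups;
#' non-responder post-treatment values are shifted upward by
#' `cohort_effect_pct`. Percentages are clipped to `[0, 100]`. Clinical
#' covariates (age, menopause, ER, stage, grade, surgery) are drawn
#' from fixed categorical distributions.
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (data frame, one row per sample) and
#'   `truth` (data frame, one row per patient with the true planted
#'   shift).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  n_r <- config$n_patients_responder
  n_n <- config$n_patients_nonresponder
  ids <- c(sprintf("R%02d", seq_len(n_r)), sprintf("N%02d", seq_len(n_n)))
  response <- c(rep("complete", n_r), rep("non_response", n_n))
  covars <- data.frame(
    patient_id = ids,
    age = round(rnorm(n_r + n_n, 55, 10)),
    menopause = sample(c("premenopausal", "postmenopausal"), n_r + n_n,
                       replace = TRUE),
    er = sample(c("negative", "positive"), n_r + n_n, replace = TRUE,
                prob = c(0.3, 0.7)),
    stage = sample(c("IIB", "IIIA", "IIIB"), n_r + n_n, replace = TRUE),
    grade = sample(c("G1-2", "G3"), n_r + n_n, replace = TRUE),
    surgery = sample(c("lumpectomy", "mastectomy"), n_r + n_n,
                     replace = TRUE, prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE)
  clip_pct <- function(x) pmin(pmax(x, 0), 100)
  pre <- clip_pct(rnorm(n_r + n_n, config$cohort_baseline_pct,
                        config$cohort_noise_sd))
  rows <- data.frame(patient_id = ids,
                     timepoint = rep("pre", length(ids)),
                     response = response, methylation_pct = pre,
                     stringsAsFactors = FALSE)
  non_ids <- ids[response == "non_response"]
  if (length(non_ids) > 0L) {
    post <- clip_pct(rnorm(length(non_ids),
                           config$cohort_baseline_pct + config$cohort_effect_pct,
                           config$cohort_noise_sd))
    rows <- rbind(rows,
                  data.frame(patient_id = non_ids,
                             timepoint = rep("post", length(non_ids)),
                             response = rep("non_response", length(non_ids)),
                             methylation_pct = post,
                             stringsAsFactors = FALSE))
  }
  cohort <- merge(rows, covars, by = "patient_id", sort = FALSE)
  cohort <- cohort[order(match(cohort$patient_id, ids),
                         match(cohort$timepoint, c("pre", "post"))), ,
                   drop = FALSE]
  rownames(cohort) <- NULL
  truth <- data.frame(patient_id = ids, response = response,
                      true_shift = ifelse(response == "non_response",
                                          config$cohort_effect_pct, 0),
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Generate the full synthetic study bundle
#'
#' @param config A [synth_config()].
#' @return List of class `study_bundle` with `beta`, `annotation`,
#'   `expr`, `cohort`, `cohort_truth`, `truth`, `config`.
#' @export
generate_study <- function(config = synth_config()) {
  meth <- generate_methylome(config)
  ex <- generate_expression(meth$truth, config)
  coh <- generate_cohort(config)
  structure(list(beta = meth$beta, annotation = meth$annotation,
                 expr = ex$expr, cohort = coh$cohort,
                 cohort_truth = coh$truth, truth = ex$truth,
                 config = config),
            class = "study_bundle")
}

#' Write a study bundle to plain-text fixture files
#'
#' Writes `probe_annotation.tsv`, `beta_matrix.tsv`,
#' `beta_sample_sheet.csv`, `expression.tsv`,
#' `expression_sample_sheet.csv`, `cohort.csv`, `ground_truth.json` and
#' `config.yaml` into `directory`. The tables round-trip losslessly
#' through the package readers.
#'
#' @param bundle A `study_bundle` from [generate_study()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  p <- function(f) file.path(directory, f)

  write.table(bundle$annotation, p("probe_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  beta_df <- data.frame(TargetID = rownames(bundle$beta$values),
                        bundle$beta$values, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write.table(beta_df, p("beta_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(data.frame(sample_id = names(bundle$beta$condition),
                       condition = unname(bundle$beta$condition)),
            p("beta_sample_sheet.csv"), row.names = FALSE, quote = FALSE)
  expr_df <- data.frame(Gene = rownames(bundle$expr$values),
                        bundle$expr$values, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write.table(expr_df, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(data.frame(sample_id = names(bundle$expr$condition),
                       condition = unname(bundle$expr$condition)),
            p("expression_sample_sheet.csv"), row.names = FALSE, quote = FALSE)
  write.csv(bundle$cohort, p("cohort.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(
    planted_genes = bundle$truth$planted_genes,
    planted_probes = bundle$truth$planted_probes,
    probe_gene = as.list(bundle$truth$probe_gene),
    xy_probes = bundle$truth$xy_probes,
    cohort_truth = bundle$cohort_truth,
    seed = bundle$config$seed)
  jsonlite::write_json(manifest, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(bundle$config), p("config.yaml"))
  invisible(vapply(c("probe_annotation.tsv", "beta_matrix.tsv",
                     "beta_sample_sheet.csv", "expression.tsv",
                     "expression_sample_sheet.csv", "cohort.csv",
                     "ground_truth.json", "config.yaml"), p, ""))
}

#' Read a fixture bundle back from disk
#'
#' Inverse of [write_fixture_bundle()] for the tabular members (the
#' ground-truth manifest is returned as parsed JSON).
#'
#' @param directory Directory written by [write_fixture_bundle()].
#' @return List with `beta`, `annotation`, `expr`, `cohort`,
#'   `manifest`, `config`.
#' @export
read_fixture_bundle <- function(directory) {
  p <- function(f) file.path(directory, f)
  list(beta = read_beta_matrix(p("beta_matrix.tsv"), p("beta_sample_sheet.csv")),
       annotation = read_probe_annotation(p("probe_annotation.tsv")),
       expr = read_expression_table(p("expression.tsv"),
                                    p("expression_sample_sheet.csv")),
       cohort = read_cohort_table(p("cohort.csv")),
       manifest = jsonlite::read_json(p("ground_truth.json"),
                                      simplifyVector = TRUE),
       config = do.call(synth_config, yaml::read_yaml(p("config.yaml"))))
}
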