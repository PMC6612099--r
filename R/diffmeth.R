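# The differential-methylation cascade: per-probe condition means and
# delta-beta, gain/loss calls, regulatory (promoter-island) restriction,
# stringent hyper/hypomethylation classification, gene-level summaries,
# global concordance and supervised clustering.

#' Per-probe condition means and delta-beta
#'
#' Averages beta values over the replicates of each condition and
#' returns the resistant-minus-sensitive difference.
#'
#' @param matrix A [beta_matrix()] with at least one sample per
#'   condition.
#' @return Data frame with columns `probe_id`, `beta_sens`, `beta_res`,
#'   `delta_beta`, in input probe order.
#' @export
#' @examples
#' vals <- matrix(c(0.06, 0.61), 1, 2,
#'                dimnames = list("cg14120129", c("s1", "r1")))
#' bm <- beta_matrix(vals, c(s1 = "sensitive", r1 = "resistant"))
#' delta_beta(bm)  # delta 0.55
delta_beta <- function(matrix) {
  stopifnot(inherits(matrix, "beta_matrix"))
  sens <- matrix$condition == "sensitive"
  res <- matrix$condition == "resistant"
  if (!any(sens) || !any(res))
    stop("both conditions need at least one sample")
  beta_sens <- rowMeans(matrix$values[, sens, drop = FALSE])
  beta_res <- rowMeans(matrix$values[, res, drop = FALSE])
  data.frame(probe_id = rownames(matrix$values),
             beta_sens = unname(beta_sens),
             beta_res = unname(beta_res),
             delta_beta = unname(beta_res - beta_sens),
             stringsAsFactors = FALSE)
}

#' Gain/loss methylation call
#'
#' A probe gains methylation when `delta >= threshold`, loses it when
#' `delta <= -threshold` (boundary inclusive on both sides).
#'
#' @param delta Numeric vector of delta-beta values.
#' @param threshold Positive call threshold in `(0, 1]`.
#' @return Character vector in `{"gained", "lost", "none"}`.
#' @export
classify_gain_loss <- function(delta, threshold = 0.20) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  ifelse(delta >= threshold, "gained",
         ifelse(delta <= -threshold, "lost", "none"))
}

#' Stringent hyper/hypomethylation classification
#'
#' A probe is hypermethylated when the sensitive-condition mean beta is
#' below `low` and the resistant-condition mean beta is above `high`;
#' hypomethylated under the mirrored rule. Both comparisons are strict,
#' as the thresholds are stated (`< 0.20`, `> 0.60`). `tol` loosens the
#' comparisons by a rounding tolerance, for validating tables printed at
#' two decimals (half an ulp of two decimals is 0.005).
#'
#' @param beta_sens,beta_res Condition mean beta values.
#' @param low,high Classification thresholds, `0 <= low < high <= 1`.
#' @param tol Non-negative rounding tolerance applied to both
#'   comparisons.
#' @return Character vector in `{"hypermethylated", "hypomethylated",
#'   "none"}`.
#' @export
#' @examples
#' classify_stringent(0.11, 0.61)            # hypermethylated
#' classify_stringent(0.16, 0.60)            # none: 0.60 not > 0.60
#' classify_stringent(0.16, 0.60, tol = 0.005)  # hypermethylated
classify_stringent <- function(beta_sens, beta_res, low = 0.20, high = 0.60,
                               tol = 0) {
  stopifnot(low >= 0, low < high, high <= 1, tol >= 0)
  hyper <- beta_sens < low + tol & beta_res > high - tol
  hypo <- beta_res < low + tol & beta_sens > high - tol
  ifelse(hyper, "hypermethylated", ifelse(hypo, "hypomethylated", "none"))
}

#' Build the full per-probe differential-methylation table
#'
#' Convenience wrapper combining [delta_beta()], [classify_gain_loss()]
#' and [classify_stringent()].
#'
#' @inheritParams delta_beta
#' @inheritParams classify_gain_loss
#' @inheritParams classify_stringent
#' @return Data frame with columns `probe_id`, `beta_sens`, `beta_res`,
#'   `delta_beta`, `gainloss`, `stringent_class`.
#' @export
diffmeth_records <- function(matrix, threshold = 0.20, low = 0.20,
                             high = 0.60, tol = 0) {
  rec <- delta_beta(matrix)
  rec$gainloss <- classify_gain_loss(rec$delta_beta, threshold)
  rec$stringent_class <- classify_stringent(rec$beta_sens, rec$beta_res,
                                            low, high, tol)
  rec
}

#' Restrict probes to regulatory regions and assign them to genes
#'
#' Under the default `"island_and_promoter"` policy a probe qualifies
#' when it lies in a CpG island *and* at least one of its (gene, region)
#' entries is a promoter-class region (`TSS200`, `TSS1500`, `5'UTR`,
#' `1stExon`); it is assigned to every gene for which it has a
#' qualifying entry. Under `"island_or_promoter"` a probe in an island
#' is assigned to all its genes, and any probe is additionally assigned
#' to genes with a promoter-class entry.
#'
#' @param annotation Annotation data frame.
#' @param policy `"island_and_promoter"` (default) or
#'   `"island_or_promoter"`.
#' @param promoter_regions Region tokens counted as promoter-class.
#' @return Data frame with columns `probe_id`, `gene`: one row per
#'   (probe, gene) assignment.
#' @export
select_regulatory <- function(annotation, policy = "island_and_promoter",
                              promoter_regions = PROMOTER_REGIONS) {
  policy <- match.arg(policy, c("island_and_promoter", "island_or_promoter"))
  pairs <- probe_gene_pairs(annotation)
  island <- annotation$Island_Relation[
    match(pairs$probe_id, annotation$TargetID)] == "Island"
  promoter <- pairs$region %in% promoter_regions
  keep <- if (policy == "island_and_promoter") island & promoter
          else island | promoter
  out <- pairs[keep, c("probe_id", "gene"), drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-level summary of stringent differential methylation
#'
#' Aggregates per-probe records over the probe-to-gene assignments and
#' keeps every gene with at least one stringent call.
#'
#' @param records Per-probe records from [diffmeth_records()] (restricted
#'   to regulatory probes for the published cascade).
#' @param assignments Probe-to-gene assignments from
#'   [select_regulatory()].
#' @return Data frame with columns `gene`, `n_probes`, `n_hyper`,
#'   `n_hypo`, `probe_ids`, sorted by gene symbol.
#' @export
summarize_genes <- function(records, assignments) {
  merged <- merge(assignments, records, by = "probe_id", sort = FALSE)
  if (nrow(merged) == 0L)
    return(data.frame(gene = character(), n_probes = integer(),
                      n_hyper = integer(), n_hypo = integer(),
                      probe_ids = character(), stringsAsFactors = FALSE))
  split_by_gene <- split(merged, merged$gene)
  out <- do.call(rbind, lapply(split_by_gene, function(g) {
    data.frame(gene = g$gene[1],
               n_probes = length(unique(g$probe_id)),
               n_hyper = sum(g$stringent_class == "hypermethylated"),
               n_hypo = sum(g$stringent_class == "hypomethylated"),
               probe_ids = paste(
                 g$probe_id[g$stringent_class != "none"], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_hyper + out$n_hypo >= 1L, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global methylation concordance between conditions
#'
#' Squared Pearson correlation of per-probe condition means, the
#' scatter-plot summary statistic of a two-condition methylome
#' comparison.
#'
#' @inheritParams delta_beta
#' @return The squared correlation, a scalar in `[0, 1]`.
#' @export
global_concordance <- function(matrix) {
  rec <- delta_beta(matrix)
  if (nrow(rec) < 2L)
    stop("need at least 2 probes")
  if (stats::sd(rec$beta_sens) == 0 || stats::sd(rec$beta_res) == 0)
    stop("zero variance in a condition; correlation undefined")
  stats::cor(rec$beta_sens, rec$beta_res)^2
}

#' Supervised clustering of the most variable CpGs
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of
#' samples and probes restricted to probes with `|delta beta| >=
#' delta_min`. Deterministic for a fixed input: ties are resolved by
#' input order, as in [stats::hclust()].
#'
#' @inheritParams delta_beta
#' @param records Per-probe records from [diffmeth_records()]; computed
#'   from `matrix` when `NULL`.
#' @param delta_min Minimum absolute delta-beta for a probe to enter the
#'   clustering.
#' @return List with elements `probe_ids`, `sample_hclust`,
#'   `probe_hclust` (both [stats::hclust] objects), `sample_order`,
#'   `probe_order`.
#' @export
cluster_top_cpgs <- function(matrix, records = NULL, delta_min = 0.20) {
  stopifnot(inherits(matrix, "beta_matrix"))
  if (is.null(records))
    records <- delta_beta(matrix)
  qualifying <- records$probe_id[abs(records$delta_beta) >= delta_min]
  if (length(qualifying) < 2L)
    stop("fewer than 2 probes with |delta beta| >= ", delta_min)
  sub <- matrix$values[qualifying, , drop = FALSE]
  sample_hc <- hclust(dist(t(sub), method = "euclidean"), method = "average")
  probe_hc <- hclust(dist(sub, method = "euclidean"), method = "average")
  list(probe_ids = qualifying,
       sample_hclust = sample_hc,
       probe_hclust = probe_hc,
       sample_order = colnames(sub)[sample_hc$order],
       probe_order = qualifying[probe_hc$order])
}
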