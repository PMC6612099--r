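# Methylome x transcriptome integration: expression fold changes, DE
# partition at FC >= 1.5, the four-way intersection with the stringent
# methylation calls, candidate ranking and gene-set enrichment.

#' Per-gene expression fold change between conditions
#'
#' Computes condition means and reports the ratio oriented so that
#' `fold_change >= 1`, with a direction flag. When either condition mean
#' is zero the pseudocount is added to both means before forming the
#' ratio, so that tables without zeros are untouched.
#'
#' @param expr An [expr_table()].
#' @param pseudocount Guard against zero means.
#' @return Data frame with columns `gene`, `expr_sens`, `expr_res`,
#'   `fold_change`, `direction` (`"up_in_resistant"`,
#'   `"down_in_resistant"` or `"none"` for equal means).
#' @export
fold_change <- function(expr, pseudocount = 0.5) {
  stopifnot(inherits(expr, "expr_table"))
  sens <- expr$condition == "sensitive"
  res <- expr$condition == "resistant"
  if (!any(sens) || !any(res))
    stop("both conditions need at least one sample")
  m_sens <- rowMeans(expr$values[, sens, drop = FALSE])
  m_res <- rowMeans(expr$values[, res, drop = FALSE])
  zero <- m_sens == 0 | m_res == 0
  m_sens[zero] <- m_sens[zero] + pseudocount
  m_res[zero] <- m_res[zero] + pseudocount
  fc <- pmax(m_res / m_sens, m_sens / m_res)
  direction <- ifelse(m_res > m_sens, "up_in_resistant",
                      ifelse(m_res < m_sens, "down_in_resistant", "none"))
  data.frame(gene = rownames(expr$values),
             expr_sens = unname(m_sens), expr_res = unname(m_res),
             fold_change = unname(fc), direction = unname(direction),
             stringsAsFactors = FALSE)
}

#' Partition genes into differential-expression sets
#'
#' @param calls Fold-change calls from [fold_change()].
#' @param fc_min Inclusive fold-change threshold (`>= 1`).
#' @return List with character vectors `up` and `down` (gene symbols
#'   with `fold_change >= fc_min` in the respective direction) and the
#'   annotated `calls` table.
#' @export
classify_de <- function(calls, fc_min = 1.5) {
  stopifnot(fc_min >= 1)
  de <- calls$fold_change >= fc_min & calls$direction != "none"
  list(up = calls$gene[de & calls$direction == "up_in_resistant"],
       down = calls$gene[de & calls$direction == "down_in_resistant"],
       calls = calls)
}

#' Intersect stringent methylation calls with expression calls
#'
#' The four-way intersection of a methylome/transcriptome comparison:
#' hypermethylated-and-downregulated genes (the silencing candidates),
#' hypermethylated only, downregulated only, and the mirrored
#' hypomethylated-and-overexpressed set.
#'
#' @param summaries Gene summaries from [summarize_genes()].
#' @param de DE sets from [classify_de()].
#' @return List with `counts` (named integer vector `hyper_down`,
#'   `hyper_only`, `down_only`, `hypo_up`) and `candidates`, a data
#'   frame (`gene`, `n_hyper_cpgs`, `fold_change`, `direction`) of the
#'   hypermethylated-and-downregulated genes.
#' @export
intersect_meth_expr <- function(summaries, de) {
  hyper <- summaries$gene[summaries$n_hyper >= 1L]
  hypo <- summaries$gene[summaries$n_hypo >= 1L]
  hyper_down <- intersect(hyper, de$down)
  hypo_up <- intersect(hypo, de$up)
  counts <- c(hyper_down = length(hyper_down),
              hyper_only = length(setdiff(hyper, de$down)),
              down_only = length(setdiff(de$down, hyper)),
              hypo_up = length(hypo_up))
  candidates <- data.frame(gene = hyper_down, stringsAsFactors = FALSE)
  candidates$n_hyper_cpgs <-
    summaries$n_hyper[match(hyper_down, summaries$gene)]
  candidates$fold_change <-
    de$calls$fold_change[match(hyper_down, de$calls$gene)]
  candidates$direction <-
    de$calls$direction[match(hyper_down, de$calls$gene)]
  list(counts = counts, candidates = candidates)
}

#' Rank and shortlist silencing candidates
#'
#' Keeps candidates supported by at least `min_cpgs` stringently
#' hypermethylated CpGs and orders them by CpG support (descending),
#' then fold change (descending), then gene symbol.
#'
#' @param candidates Candidate table from [intersect_meth_expr()].
#' @param min_cpgs Minimum number of supporting stringent CpGs.
#' @return The filtered, ordered candidate table with a `rank` column.
#' @export
rank_candidates <- function(candidates, min_cpgs = 3) {
  stopifnot(min_cpgs >= 1)
  kept <- candidates[candidates$n_hyper_cpgs >= min_cpgs, , drop = FALSE]
  ord <- order(-kept$n_hyper_cpgs, -kept$fold_change, kept$gene)
  kept <- kept[ord, , drop = FALSE]
  kept$rank <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  kept
}

#' Read gene sets in GMT format
#'
#' @param path Tab-separated GMT file: set name, description, then
#'   member genes.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Hypergeometric gene-set enrichment with FDR control
#'
#' One-sided hypergeometric tail test of candidate over-representation
#' in each gene set, with Benjamini-Hochberg adjustment across sets.
#' Set membership is intersected with the universe before testing.
#'
#' @param candidates Character vector of candidate gene symbols; must be
#'   a subset of `universe`.
#' @param universe Character vector, the gene universe.
#' @param gene_sets Named list of character vectors, or a path to a GMT
#'   file.
#' @return Data frame with columns `set`, `n_set`, `n_overlap`,
#'   `p_value`, `q_value`, ordered by `p_value`.
#' @export
enrich_gene_sets <- function(candidates, universe, gene_sets) {
  if (is.character(gene_sets) && length(gene_sets) == 1L)
    gene_sets <- read_gmt(gene_sets)
  universe <- unique(universe)
  if (length(universe) == 0L)
    stop("empty gene universe")
  outside <- setdiff(candidates, universe)
  if (length(outside) > 0L)
    stop("candidate(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  candidates <- unique(candidates)
  n_univ <- length(universe)
  n_cand <- length(candidates)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], universe)
    overlap <- length(intersect(members, candidates))
    # P(X >= overlap) for X ~ Hypergeom(m = |set|, n = N - |set|, k = |cand|)
    p <- phyper(overlap - 1L, length(members), n_univ - length(members),
                n_cand, lower.tail = FALSE)
    data.frame(set = nm, n_set = length(members), n_overlap = overlap,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
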