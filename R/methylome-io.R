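# Readers and filters for 450K-style annotation, beta and expression tables.
#
# File contracts:
#   annotation TSV:  TargetID, Chr, Position, Gene_Name, Gene_Region,
#                    Island_Relation; Gene_Name/Gene_Region are
#                    semicolon-delimited parallel lists.
#   beta TSV:        first column TargetID, remaining columns sample IDs.
#   sample sheet:    CSV sample_id,condition with condition in
#                    {sensitive, resistant}.

ANNOTATION_COLS <- c("TargetID", "Chr", "Position", "Gene_Name",
                     "Gene_Region", "Island_Relation")

# normalize the typographic prime occasionally found in published tables
normalize_region <- function(x) gsub("′", "'", x)

validate_annotation <- function(annotation) {
  missing <- setdiff(ANNOTATION_COLS, names(annotation))
  if (length(missing) > 0L)
    stop("annotation table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(annotation$TargetID))
    stop("duplicate probe IDs in annotation: ",
         paste(unique(annotation$TargetID[duplicated(annotation$TargetID)]),
               collapse = ", "))
  if (any(annotation$Position < 1))
    stop("probe positions must be 1-based (>= 1)")
  bad_island <- setdiff(unique(annotation$Island_Relation), ISLAND_TOKENS)
  if (length(bad_island) > 0L)
    stop("unknown island relation token(s): ", paste(bad_island, collapse = ", "))
  invisible(annotation)
}

#' Read a 450K-style probe annotation table
#'
#' Reads a tab-separated annotation table with semicolon-delimited,
#' positionally paired gene-symbol and gene-region lists (the layout of
#' the Illumina 450K manifest columns `UCSC_RefGene_Name` /
#' `UCSC_RefGene_Group`). Symbol and region lists must have equal
#' length per probe; region tokens must be one of `TSS200`, `TSS1500`,
#' `5'UTR`, `1stExon`, `Body`, `3'UTR`.
#'
#' @param path Path to a TSV with columns `TargetID`, `Chr`, `Position`,
#'   `Gene_Name`, `Gene_Region`, `Island_Relation`.
#' @return The annotation data frame, validated.
#' @seealso [probe_gene_pairs()] for the parsed (symbol, region) pairs.
#' @export
read_probe_annotation <- function(path) {
  annotation <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  annotation$Gene_Region <- normalize_region(annotation$Gene_Region)
  validate_annotation(annotation)
  # force full parse so malformed rows fail at read time
  probe_gene_pairs(annotation)
  annotation
}

#' Parse (gene, region) pairs out of an annotation table
#'
#' Splits the semicolon-delimited `Gene_Name` and `Gene_Region` columns,
#' zips them pairwise, and deduplicates identical (symbol, region)
#' pairs per probe. Distinct regions for the same symbol are all kept.
#'
#' @param annotation An annotation data frame (see
#'   [read_probe_annotation()]).
#' @return A data frame with columns `probe_id`, `gene`, `region`, one
#'   row per deduplicated pair, in input probe order.
#' @export
#' @examples
#' ann <- data.frame(TargetID = "cg09327770", Chr = "12",
#'                   Position = 46663270,
#'                   Gene_Name = "SLC38A1;SLC38A1",
#'                   Gene_Region = "TSS200;TSS200",
#'                   Island_Relation = "Island")
#' probe_gene_pairs(ann)  # one pair after dedup
probe_gene_pairs <- function(annotation) {
  genes <- strsplit(as.character(annotation$Gene_Name), ";", fixed = TRUE)
  regions <- strsplit(normalize_region(as.character(annotation$Gene_Region)),
                      ";", fixed = TRUE)
  n_g <- lengths(genes)
  n_r <- lengths(regions)
  bad <- which(n_g != n_r)
  if (length(bad) > 0L)
    stop("gene/region list length mismatch for probe(s): ",
         paste(annotation$TargetID[bad], collapse = ", "))
  pairs <- data.frame(
    probe_id = rep(annotation$TargetID, n_g),
    gene = unlist(genes, use.names = FALSE),
    region = unlist(regions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  bad_region <- setdiff(unique(pairs$region), REGION_TOKENS)
  if (length(bad_region) > 0L)
    stop("malformed region token(s): ", paste(bad_region, collapse = ", "))
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Construct a two-condition beta-value matrix
#'
#' @param values Numeric matrix, probes x samples, with probe IDs as row
#'   names and sample IDs as column names; entries in `[0, 1]` or `NA`.
#' @param condition Named character vector mapping every sample ID to
#'   `"sensitive"` or `"resistant"`.
#' @param detection_p Optional detection p-value matrix of the same
#'   shape.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, condition, detection_p = NULL) {
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("beta matrix needs probe row names and sample column names")
  if (is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs in beta matrix")
  out_of_range <- values < 0 | values > 1
  if (any(out_of_range, na.rm = TRUE))
    stop("beta values outside [0, 1]")
  missing_samples <- setdiff(colnames(values), names(condition))
  if (length(missing_samples) > 0L)
    stop("sample(s) missing from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  condition <- condition[colnames(values)]
  bad_cond <- setdiff(unique(condition), CONDITIONS)
  if (length(bad_cond) > 0L)
    stop("condition labels must be in {", paste(CONDITIONS, collapse = ", "),
         "}; got: ", paste(bad_cond, collapse = ", "))
  if (!all(CONDITIONS %in% condition))
    stop("every condition needs at least one sample")
  if (!is.null(detection_p) &&
      !identical(dim(detection_p), dim(values)))
    stop("detection_p must have the same shape as the beta values")
  structure(list(values = values, condition = condition,
                 detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples (",
      sum(x$condition == "sensitive"), "sensitive /",
      sum(x$condition == "resistant"), "resistant )\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

read_sample_sheet <- function(path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(sheet)))
    stop("sample sheet needs columns sample_id, condition")
  setNames(sheet$condition, sheet$sample_id)
}

#' Read a beta-value matrix with its sample sheet
#'
#' Empty cells are preserved as missing values; out-of-range values,
#' duplicate probe IDs, and samples absent from the sheet are errors.
#'
#' @param path TSV with first column `TargetID` and one column per
#'   sample.
#' @param sample_sheet Path to a CSV `sample_id,condition`, or a named
#'   character vector of conditions.
#' @param detection_p_path Optional TSV of detection p-values with the
#'   same layout.
#' @return A [beta_matrix()] object.
#' @export
read_beta_matrix <- function(path, sample_sheet, detection_p_path = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "TargetID")
    stop("first column of a beta matrix must be TargetID")
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- tab$TargetID
  condition <- if (is.character(sample_sheet) && length(sample_sheet) == 1L &&
                   file.exists(sample_sheet))
    read_sample_sheet(sample_sheet) else sample_sheet
  detection_p <- NULL
  if (!is.null(detection_p_path)) {
    ptab <- read.delim(detection_p_path, stringsAsFactors = FALSE,
                       check.names = FALSE)
    detection_p <- as.matrix(ptab[, -1, drop = FALSE])
    rownames(detection_p) <- ptab$TargetID
    detection_p <- detection_p[rownames(values), colnames(values), drop = FALSE]
  }
  beta_matrix(values, condition, detection_p)
}

#' Filter probes by chromosome, detection quality and missingness
#'
#' Removes probes on excluded chromosomes (sex chromosomes by default),
#' probes whose detection p-value is at or above `detection_p_max` in
#' any sample (when a detection matrix is present), and probes with any
#' missing beta value. Filtering is stable (input order preserved) and
#' idempotent.
#'
#' @param matrix A [beta_matrix()].
#' @param annotation Annotation data frame covering every probe in
#'   `matrix`.
#' @param exclude_chromosomes Chromosome labels to drop.
#' @param detection_p_max Detection p-value threshold; a probe is kept
#'   only if `p < detection_p_max` in every sample.
#' @return A filtered [beta_matrix()].
#' @export
filter_probes <- function(matrix, annotation,
                          exclude_chromosomes = c("X", "Y"),
                          detection_p_max = 0.01) {
  stopifnot(inherits(matrix, "beta_matrix"))
  probes <- rownames(matrix$values)
  unknown <- setdiff(probes, annotation$TargetID)
  if (length(unknown) > 0L)
    stop("probe(s) in matrix absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  chr <- as.character(annotation$Chr)[match(probes, annotation$TargetID)]
  keep <- !(chr %in% as.character(exclude_chromosomes))
  if (!is.null(matrix$detection_p))
    keep <- keep & apply(matrix$detection_p < detection_p_max, 1, all)
  keep <- keep & complete.cases(matrix$values)
  if (!any(keep))
    warning("no probes survive filtering")
  beta_matrix(matrix$values[keep, , drop = FALSE], matrix$condition,
              if (is.null(matrix$detection_p)) NULL
              else matrix$detection_p[keep, , drop = FALSE])
}

#' Read a normalized expression table with its sample sheet
#'
#' @param path TSV with first column `Gene` and one column per sample.
#' @param sample_sheet Path to a CSV `sample_id,condition`, or a named
#'   character vector of conditions.
#' @param pseudocount Added to every value when zeros are present so the
#'   table is strictly positive.
#' @return An object of class `expr_table` with elements `values`
#'   (genes x samples matrix) and `condition`.
#' @export
read_expression_table <- function(path, sample_sheet, pseudocount = 0.5) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "Gene")
    stop("first column of an expression table must be Gene")
  dup <- unique(tab$Gene[duplicated(tab$Gene)])
  if (length(dup) > 0L)
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "))
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- tab$Gene
  if (any(values < 0, na.rm = TRUE))
    stop("negative expression values")
  if (any(values == 0, na.rm = TRUE))
    values <- values + pseudocount
  condition <- if (is.character(sample_sheet) && length(sample_sheet) == 1L &&
                   file.exists(sample_sheet))
    read_sample_sheet(sample_sheet) else sample_sheet
  expr_table(values, condition)
}

#' Construct an expression table object
#'
#' @param values Genes x samples matrix of strictly positive normalized
#'   expression values.
#' @param condition Named character vector mapping samples to
#'   `"sensitive"` / `"resistant"`.
#' @return An object of class `expr_table`.
#' @export
expr_table <- function(values, condition) {
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("expression table needs gene row names and sample column names")
  if (is.null(rownames(values)))
    rownames(values) <- character(0)
  missing_samples <- setdiff(colnames(values), names(condition))
  if (length(missing_samples) > 0L)
    stop("sample(s) missing from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  condition <- condition[colnames(values)]
  bad_cond <- setdiff(unique(condition), CONDITIONS)
  if (length(bad_cond) > 0L)
    stop("condition labels must be in {", paste(CONDITIONS, collapse = ", "),
         "}")
  if (any(values <= 0, na.rm = TRUE))
    stop("expression values must be strictly positive")
  structure(list(values = values, condition = condition), class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat("expr_table:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  invisible(x)
}
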