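#' Reference (signature matrix) construction and marker selection
#'
#' The external reference is always built from the training partition only:
#' per-type arithmetic means of bulk training samples, or per-type means of
#' (optionally depth-normalized) single cells. Signature genes are selected
#' by a specificity-ratio scheme: for each type, genes are ranked by their
#' expression in that type relative to the maximum expression in any other
#' type.
#'
#' @name reference-builder
NULL

#' Signature gene selection settings
#'
#' @param k_per_type top genes kept per cell type; default 50.
#' @param method `"specificity_ratio"` (default), `"top_variance"`, or
#'   `"none"` (passthrough: all genes).
#' @param min_expression minimum within-type mean expression a candidate
#'   marker must reach; default 1.
#' @return a `signature_spec` list.
#' @export
signature_spec <- function(k_per_type = 50L,
                           method = c("specificity_ratio", "top_variance",
                                      "none"),
                           min_expression = 1.0) {
  method <- match.arg(method)
  if (k_per_type < 1) stop("k_per_type must be >= 1")
  list(k_per_type = as.integer(k_per_type), method = method,
       min_expression = min_expression)
}

#' Build a reference from labeled bulk training samples
#'
#' Column `c` of the reference is the gene-wise arithmetic mean of the
#' training samples labeled `c`.
#'
#' @param train an `expression_matrix` of training samples.
#' @param sample_types named character vector mapping sample id -> cell
#'   type; every training sample must be labeled.
#' @return a `reference_profile`.
#' @export
build_reference_bulk <- function(train, sample_types) {
  stopifnot(inherits(train, "expression_matrix"))
  ids <- colnames(train$values)
  unlabeled <- setdiff(ids, names(sample_types))
  if (length(unlabeled))
    stop("unlabeled sample(s): ", paste(unlabeled, collapse = ", "))
  labels <- sample_types[ids]
  types <- unique(labels)
  ref <- vapply(types, function(ct)
    rowMeans(train$values[, labels == ct, drop = FALSE]),
    numeric(nrow(train$values)))
  reference_profile(ref, gene_ids = rownames(train$values),
                    cell_type_ids = types)
}

#' Build a reference from single-cell training data
#'
#' @param sc_train a `single_cell_dataset` (the training partition).
#' @param normalize `"cpm_mean"` (default): scale each cell to
#'   counts-per-million, then average within type, so deep cells do not
#'   dominate the profile; `"raw_mean"`: plain average of raw counts.
#' @return a `reference_profile`.
#' @export
build_reference_sc <- function(sc_train,
                               normalize = c("cpm_mean", "raw_mean")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(sc_train, "single_cell_dataset"))
  counts <- sc_train$counts
  if (normalize == "cpm_mean") {
    depth <- colSums(counts)
    if (any(depth == 0)) stop("cell(s) with zero total counts cannot be CPM-scaled")
    counts <- sweep(counts, 2, depth / 1e6, "/")
  }
  types <- unique(sc_train$cell_types)
  ref <- vapply(types, function(ct)
    rowMeans(counts[, sc_train$cell_types == ct, drop = FALSE]),
    numeric(nrow(counts)))
  reference_profile(ref, gene_ids = rownames(counts), cell_type_ids = types)
}

#' Select signature genes from a reference
#'
#' Under `specificity_ratio`, each gene's score for type `c` is
#' `expr[g, c] / (max over other types + 1e-8)`; the top `k_per_type` genes
#' per type with within-type expression >= `min_expression` are kept, and
#' the union over types is returned deduplicated in stable (first-type,
#' then rank) order. The score is a ratio, so the selection is invariant
#' under global positive rescaling of the reference.
#'
#' @param reference a `reference_profile`.
#' @param spec a [signature_spec()].
#' @return character vector of selected gene ids.
#' @export
select_signature_genes <- function(reference, spec = signature_spec()) {
  stopifnot(inherits(reference, "reference_profile"))
  vals <- reference$values
  genes <- rownames(vals)
  if (spec$method == "none") return(genes)
  if (spec$k_per_type >= nrow(vals))
    warning("k_per_type >= number of genes; returning all passing genes")
  selected <- character(0)
  if (spec$method == "top_variance") {
    v <- apply(vals, 1, stats::var)
    keep <- genes[order(v, decreasing = TRUE)]
    k <- min(spec$k_per_type * ncol(vals), length(keep))
    return(keep[seq_len(k)])
  }
  for (ct in colnames(vals)) {
    own <- vals[, ct]
    other_max <- if (ncol(vals) > 1)
      apply(vals[, colnames(vals) != ct, drop = FALSE], 1, max)
    else rep(0, nrow(vals))
    score <- own / (other_max + 1e-8)
    ok <- own >= spec$min_expression
    ranked <- genes[ok][order(score[ok], decreasing = TRUE)]
    selected <- c(selected, utils::head(ranked, spec$k_per_type))
  }
  unique(selected)
}
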