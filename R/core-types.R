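#' Validated data containers
#'
#' deconbench passes expression data between modules in four light S3
#' containers built on base matrices with dimnames:
#' \describe{
#'   \item{`expression_matrix`}{nonnegative genes x samples values with a
#'     `space` tag (`"counts"` or `"normalized"`).}
#'   \item{`single_cell_dataset`}{nonnegative integer genes x cells counts
#'     plus one cell-type label per cell.}
#'   \item{`reference_profile`}{genes x cell-types signature matrix
#'     (per-type expected expression).}
#'   \item{`proportion_matrix`}{cell-types x samples matrix with every
#'     column on the probability simplex; holds both ground truth and
#'     predictions.}
#' }
#' Constructors validate their invariants and fail loudly; downstream code
#' can therefore assume well-formed objects.
#'
#' @name core-types
NULL

.check_ids <- function(ids, what, n) {
  ids <- as.character(ids)
  if (length(ids) != n)
    stop(sprintf("%s: expected %d identifiers, got %d", what, n, length(ids)))
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate identifiers: %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  ids
}

#' Construct an expression matrix
#'
#' @param values nonnegative numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids unique character identifiers; default to the
#'   dimnames of `values`.
#' @param space value space of the matrix: raw `"counts"` or `"normalized"`
#'   (TPM-like). The library size of sample j is its column sum when
#'   `space = "counts"`.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              space = c("counts", "normalized")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be nonnegative")
  gene_ids <- .check_ids(gene_ids, "gene_ids", nrow(values))
  sample_ids <- .check_ids(sample_ids, "sample_ids", ncol(values))
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, space = space),
            class = "expression_matrix")
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' Per-sample library sizes
#'
#' Column sums of an expression matrix; for count-space data this is the
#' sequencing depth of each sample.
#'
#' @param x an `expression_matrix`.
#' @return named numeric vector, one entry per sample.
#' @export
library_sizes <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  colSums(x$values)
}

#' Construct a single-cell dataset
#'
#' @param counts nonnegative integer matrix, genes x cells (base or
#'   `Matrix` sparse; stored dense).
#' @param gene_ids,cell_ids unique identifiers; default to dimnames.
#' @param cell_types character vector, one label per cell. Every label must
#'   annotate at least one cell.
#' @return a `single_cell_dataset` object.
#' @export
single_cell_dataset <- function(counts, gene_ids = rownames(counts),
                                cell_ids = colnames(counts), cell_types) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  gene_ids <- .check_ids(gene_ids, "gene_ids", nrow(counts))
  cell_ids <- .check_ids(cell_ids, "cell_ids", ncol(counts))
  cell_types <- as.character(cell_types)
  if (length(cell_types) != ncol(counts))
    stop("cell_types must have one label per cell")
  if (anyNA(cell_types)) stop("cell_types may not contain NA")
  dimnames(counts) <- list(gene_ids, cell_ids)
  names(cell_types) <- cell_ids
  structure(list(counts = counts, cell_types = cell_types),
            class = "single_cell_dataset")
}

#' @exportS3Method base::print
print.single_cell_dataset <- function(x, ...) {
  tab <- table(x$cell_types)
  cat(sprintf("single_cell_dataset: %d genes x %d cells, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(tab)))
  print(tab)
  invisible(x)
}

#' Construct a reference (signature) profile
#'
#' The genes x cell-types matrix of expected expression used as the design
#' matrix for deconvolution. A cell type with an all-zero profile carries no
#' signal and is rejected.
#'
#' @param values nonnegative numeric matrix, genes x cell types.
#' @param gene_ids,cell_type_ids unique identifiers; default to dimnames.
#' @return a `reference_profile` object.
#' @export
reference_profile <- function(values, gene_ids = rownames(values),
                              cell_type_ids = colnames(values)) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("reference values must be finite and nonnegative")
  gene_ids <- .check_ids(gene_ids, "gene_ids", nrow(values))
  cell_type_ids <- .check_ids(cell_type_ids, "cell_type_ids", ncol(values))
  zero <- colSums(values) == 0
  if (any(zero))
    stop("all-zero reference column(s): ",
         paste(cell_type_ids[zero], collapse = ", "))
  dimnames(values) <- list(gene_ids, cell_type_ids)
  structure(list(values = values), class = "reference_profile")
}

#' @exportS3Method base::print
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile: %d genes x %d cell types\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a cell-type proportion matrix
#'
#' Cell-types x samples matrix whose columns live on the probability
#' simplex. In strict mode (the default) a column whose sum deviates from 1
#' by more than `tol` is rejected; in lenient mode it is renormalized with a
#' warning, which is what the external-method adapter uses since many tools
#' return unnormalized weights.
#'
#' @param values numeric matrix, cell types x samples, entries in \[0, 1\]
#'   (lenient mode accepts any nonnegative entries before renormalization).
#' @param cell_type_ids,sample_ids unique identifiers; default to dimnames.
#' @param strict reject (`TRUE`) or renormalize (`FALSE`) off-simplex columns.
#' @param tol simplex tolerance for strict mode.
#' @return a `proportion_matrix` object.
#' @export
proportion_matrix <- function(values, cell_type_ids = rownames(values),
                              sample_ids = colnames(values),
                              strict = TRUE, tol = 1e-8) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("proportions must be finite")
  cell_type_ids <- .check_ids(cell_type_ids, "cell_type_ids", nrow(values))
  sample_ids <- .check_ids(sample_ids, "sample_ids", ncol(values))
  if (any(values < 0)) {
    if (strict) stop("proportions must be nonnegative")
    values[values < 0] <- 0
    warning("negative proportions clipped to 0 (lenient mode)")
  }
  cs <- colSums(values)
  off <- abs(cs - 1) > tol
  if (any(off)) {
    if (strict)
      stop(sprintf("column(s) not on the simplex (|sum-1| > %g): %s",
                   tol, paste(sample_ids[off], collapse = ", ")))
    if (any(cs == 0)) stop("cannot renormalize all-zero proportion column(s)")
    values <- sweep(values, 2, cs, "/")
    warning(sprintf("%d column(s) renormalized to the simplex (lenient mode)",
                    sum(off)))
  }
  if (any(values > 1 + 1e-12)) stop("proportions must be <= 1")
  values[values > 1] <- 1
  dimnames(values) <- list(cell_type_ids, sample_ids)
  structure(list(values = values), class = "proportion_matrix")
}

#' @exportS3Method base::print
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("proportion_matrix: %d cell types x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Metrics known to the evaluation suite
#' @export
METRIC_NAMES <- c("PCC", "RMSE", "MAPE", "sMAPE", "SSIM", "JS", "AS")

#' Construct a tidy results table
#'
#' The common currency of the evaluation protocols: one row per
#' (method, scenario, noise_level, cell_type, metric, replicate) with a
#' numeric value. `cell_type` uses the sentinel `"ALL"` for metrics computed
#' over the flattened matrix and `"SPIKED"` for rare-component restrictions.
#'
#' @param method,scenario,noise_level,cell_type character columns.
#' @param metric one of `r paste(METRIC_NAMES, collapse = ", ")`.
#' @param value numeric metric values (NaN marks a failed method run).
#' @param replicate integer replicate index.
#' @return a `data.frame` with class `results_table`.
#' @export
results_table <- function(method = character(), scenario = character(),
                          noise_level = character(), cell_type = character(),
                          metric = character(), value = numeric(),
                          replicate = integer()) {
  df <- data.frame(method = as.character(method),
                   scenario = as.character(scenario),
                   noise_level = as.character(noise_level),
                   cell_type = as.character(cell_type),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$metric), METRIC_NAMES)
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "))
  key <- do.call(paste, c(df[c("method", "scenario", "noise_level",
                               "cell_type", "metric", "replicate")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (method, scenario, noise_level, cell_type, metric, replicate) keys")
  class(df) <- c("results_table", "data.frame")
  df
}

#' Bind results tables, revalidating the key uniqueness invariant
#' @param ... `results_table` objects.
#' @return a `results_table`.
#' @export
bind_results <- function(...) {
  pieces <- list(...)
  pieces <- pieces[vapply(pieces, NROW, 1L) > 0]
  if (!length(pieces)) return(results_table())
  df <- do.call(rbind, lapply(pieces, as.data.frame))
  do.call(results_table, df)
}

#' Align a reference and a mixture on their shared genes
#'
#' Restricts both inputs to the intersection of their gene identifiers, in a
#' common (reference) order, and reports how many genes each side dropped.
#' Gene identifiers are matched as case-sensitive exact strings.
#'
#' @param reference a `reference_profile`.
#' @param mixture an `expression_matrix`.
#' @return list with the aligned `reference`, `mixture`, and the counts
#'   `dropped_reference` / `dropped_mixture`.
#' @export
validate_pair <- function(reference, mixture) {
  stopifnot(inherits(reference, "reference_profile"),
            inherits(mixture, "expression_matrix"))
  rg <- rownames(reference$values)
  mg <- rownames(mixture$values)
  common <- intersect(rg, mg)
  if (!length(common))
    stop(sprintf(
      "no shared genes between reference (e.g. %s) and mixture (e.g. %s)",
      paste(utils::head(rg, 3), collapse = ", "),
      paste(utils::head(mg, 3), collapse = ", ")))
  ref2 <- reference_profile(reference$values[common, , drop = FALSE])
  mix2 <- expression_matrix(mixture$values[common, , drop = FALSE],
                            space = mixture$space)
  list(reference = ref2, mixture = mix2,
       dropped_reference = length(rg) - length(common),
       dropped_mixture = length(mg) - length(common))
}
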