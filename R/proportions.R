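#' Train/test splitting and ground-truth proportion generators
#'
#' Evaluation data are built in two steps: the input dataset is split into a
#' training partition (used only to build the external reference) and a test
#' partition (used only to synthesize mixtures), and ground-truth cell-type
#' proportions are drawn from one of three generators: normalized-uniform,
#' Dirichlet, or a rare-component gradient.
#'
#' @name proportions
NULL

#' Specification of a train/test split
#'
#' @param train_frac fraction of units assigned to training, in (0, 1\];
#'   default 0.7 (a 70/30 split).
#' @param seed integer RNG seed; the split is deterministic given the seed.
#' @param unit `"samples"` (bulk) or `"cells"` (single-cell, stratified
#'   within each cell-type label).
#' @return a `split_spec` list.
#' @export
split_spec <- function(train_frac = 0.7, seed = 1L,
                       unit = c("samples", "cells")) {
  unit <- match.arg(unit)
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac > 1)
    stop("train_frac must be in (0, 1]")
  list(train_frac = train_frac, seed = as.integer(seed), unit = unit)
}

#' Split a dataset into training and test partitions
#'
#' Bulk expression matrices are split over samples; single-cell datasets are
#' split over cells, stratified within each cell-type label so every type
#' keeps its 70/30 ratio. The per-stratum training size is
#' `round_half_up(train_frac * n)`, with at least one training unit per
#' nonempty stratum. The partition is disjoint, exhaustive, and
#' deterministic given `spec$seed`.
#'
#' @param data an `expression_matrix` or `single_cell_dataset`.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` of the same class as `data` (`test`
#'   may have zero columns when `train_frac = 1`).
#' @export
split_train_test <- function(data, spec = split_spec()) {
  UseMethod("split_train_test")
}

.split_indices <- function(n, frac, seed) {
  k <- round_half_up(frac * n)
  k <- max(1L, min(n, as.integer(k)))
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(k)]),
       test = sort(perm[setdiff(seq_len(n), seq_len(k))]))
}

#' @export
split_train_test.expression_matrix <- function(data, spec = split_spec()) {
  idx <- .split_indices(ncol(data$values), spec$train_frac, spec$seed)
  list(train = expression_matrix(data$values[, idx$train, drop = FALSE],
                                 space = data$space),
       test = expression_matrix(data$values[, idx$test, drop = FALSE],
                                space = data$space))
}

#' @export
split_train_test.single_cell_dataset <- function(data, spec = split_spec()) {
  types <- unique(data$cell_types)
  sizes <- table(data$cell_types)
  if (spec$train_frac < 1 && any(sizes < 2))
    stop("cell type(s) with < 2 cells cannot be split: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  train_cols <- integer(0)
  for (i in seq_along(types)) {
    cols <- which(data$cell_types == types[i])
    idx <- .split_indices(length(cols), spec$train_frac,
                          derive_seed(spec$seed, i))
    train_cols <- c(train_cols, cols[idx$train])
  }
  train_cols <- sort(train_cols)
  test_cols <- setdiff(seq_along(data$cell_types), train_cols)
  subset_sc <- function(cols) single_cell_dataset(
    data$counts[, cols, drop = FALSE],
    cell_types = data$cell_types[cols])
  list(train = subset_sc(train_cols), test = subset_sc(test_cols))
}

#' Uniform ground-truth proportions
#'
#' Each sample's proportions are iid U(0,1) draws divided by their sum --
#' the scheme used for training-data generation by methods that sample
#' proportions without prior knowledge.
#'
#' @param n_samples number of columns to generate.
#' @param cell_type_ids cell-type identifiers (rows).
#' @param seed integer RNG seed.
#' @return a `proportion_matrix`.
#' @export
gen_proportions_uniform <- function(n_samples, cell_type_ids, seed = 1L) {
  stopifnot(n_samples >= 1, length(cell_type_ids) >= 1)
  k <- length(cell_type_ids)
  u <- with_seed(seed, matrix(stats::runif(k * n_samples), nrow = k))
  p <- sweep(u, 2, colSums(u), "/")
  proportion_matrix(p, cell_type_ids = cell_type_ids,
                    sample_ids = paste0("S", seq_len(n_samples)))
}

#' Dirichlet ground-truth proportions
#'
#' Columns are Dirichlet(alpha) draws (via normalized Gamma variables),
#' allowing prior-informed simulation of mixture proportions: small alpha
#' concentrates mass on few types, large alpha concentrates columns around
#' alpha / sum(alpha).
#'
#' @param n_samples number of columns.
#' @param alpha positive concentration parameters, one per cell type; names
#'   are used as cell-type ids when present.
#' @param cell_type_ids optional cell-type ids (default `names(alpha)` or
#'   `CT1..CTk`).
#' @param seed integer RNG seed.
#' @return a `proportion_matrix`.
#' @export
gen_proportions_dirichlet <- function(n_samples, alpha,
                                      cell_type_ids = NULL, seed = 1L) {
  if (any(alpha <= 0)) stop("all alpha must be > 0")
  k <- length(alpha)
  if (is.null(cell_type_ids))
    cell_type_ids <- if (!is.null(names(alpha))) names(alpha)
    else paste0("CT", seq_len(k))
  g <- with_seed(seed, matrix(stats::rgamma(k * n_samples, shape = alpha),
                              nrow = k))
  p <- sweep(g, 2, colSums(g), "/")
  proportion_matrix(p, cell_type_ids = cell_type_ids,
                    sample_ids = paste0("S", seq_len(n_samples)))
}

#' Specification of a rare-component gradient
#'
#' @param levels spiked proportions, strictly increasing, all in (0, 1).
#'   The default gradient is 0.001, 0.003, 0.005, 0.008, 0.01, 0.03, 0.05.
#' @param target_types cell types to spike, one at a time (`NULL` = all).
#' @param n_per_level samples per (target type, level) pair; default 50.
#' @param background how the remaining mass 1 - level is shared among the
#'   other types: proportional to fresh normalized uniforms, or `"equal"`.
#' @return a `rare_gradient_spec` list.
#' @export
rare_gradient_spec <- function(levels = c(0.001, 0.003, 0.005, 0.008,
                                          0.01, 0.03, 0.05),
                               target_types = NULL, n_per_level = 50L,
                               background = c("uniform", "equal")) {
  background <- match.arg(background)
  if (any(levels >= 1) || any(levels <= 0)) stop("levels must be in (0, 1)")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be strictly increasing")
  if (n_per_level < 1) stop("n_per_level must be >= 1")
  list(levels = levels, target_types = target_types,
       n_per_level = as.integer(n_per_level), background = background)
}

#' Rare-component ground-truth proportions
#'
#' For each (target type, level, replicate) a sample is generated whose
#' spiked entry equals the level exactly; the remaining mass 1 - level is
#' distributed over the other types per `spec$background`. The annotation
#' records which type was spiked at which level in each sample.
#'
#' @param spec a [rare_gradient_spec()].
#' @param cell_type_ids all cell-type identifiers.
#' @param seed integer RNG seed.
#' @return list with `proportions` (a `proportion_matrix`) and `annotation`
#'   (data.frame: sample_id, spiked_type, level).
#' @export
gen_proportions_rare <- function(spec = rare_gradient_spec(), cell_type_ids,
                                 seed = 1L) {
  targets <- spec$target_types %||% cell_type_ids
  if (!all(targets %in% cell_type_ids))
    stop("target type(s) not in cell_type_ids: ",
         paste(setdiff(targets, cell_type_ids), collapse = ", "))
  if (length(cell_type_ids) < 2)
    stop("rare-component spiking needs at least 2 cell types")
  k <- length(cell_type_ids)
  cols <- list(); ann <- list(); s <- 0L
  for (ti in seq_along(targets)) for (li in seq_along(spec$levels)) {
    lev <- spec$levels[li]
    others <- setdiff(cell_type_ids, targets[ti])
    bg <- with_seed(derive_seed(seed, ti, li), {
      if (spec$background == "uniform")
        matrix(stats::runif((k - 1) * spec$n_per_level), nrow = k - 1)
      else matrix(1, nrow = k - 1, ncol = spec$n_per_level)
    })
    bg <- sweep(bg, 2, colSums(bg), "/") * (1 - lev)
    for (r in seq_len(spec$n_per_level)) {
      s <- s + 1L
      col <- stats::setNames(numeric(k), cell_type_ids)
      col[targets[ti]] <- lev
      col[others] <- bg[, r]
      cols[[s]] <- col
      ann[[s]] <- data.frame(sample_id = paste0("S", s),
                             spiked_type = targets[ti], level = lev,
                             stringsAsFactors = FALSE)
    }
  }
  p <- do.call(cbind, cols)
  colnames(p) <- paste0("S", seq_len(ncol(p)))
  list(proportions = proportion_matrix(p),
       annotation = do.call(rbind, ann))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
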