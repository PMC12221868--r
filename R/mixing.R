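#' Mixture synthesis from bulk references or single cells
#'
#' Two routes to a pseudo-bulk mixture with known ground truth: a numerical
#' linear combination of per-type bulk profiles (`mix_bulk`), or sampling
#' single cells per type and summing their count vectors (`pseudobulk_sc`).
#'
#' @name mixing
NULL

#' Mix bulk profiles linearly
#'
#' The clean mixture is `reference %*% proportions`: each sample is the
#' proportion-weighted linear combination of the per-type profiles. Gene ids
#' and the value-space tag are carried over from the reference.
#'
#' @param reference a `reference_profile`.
#' @param proportions a `proportion_matrix` over the same cell types.
#' @param space value-space tag for the output (default `"counts"`).
#' @return an `expression_matrix` (genes x samples).
#' @export
mix_bulk <- function(reference, proportions, space = "counts") {
  stopifnot(inherits(reference, "reference_profile"),
            inherits(proportions, "proportion_matrix"))
  rt <- colnames(reference$values)
  pt <- rownames(proportions$values)
  if (!setequal(rt, pt))
    stop("cell-type mismatch between reference and proportions: ",
         paste(union(setdiff(rt, pt), setdiff(pt, rt)), collapse = ", "))
  mixed <- reference$values %*% proportions$values[rt, , drop = FALSE]
  expression_matrix(mixed, space = space)
}

#' Largest-remainder apportionment
#'
#' Rounds fractional target counts `n * p` to integers that sum to `n`
#' exactly: floors first, then hands the leftover units to the entries with
#' the largest fractional remainders, ties broken by position (cell-type id
#' order).
#'
#' @param n total count to apportion.
#' @param p proportions (summing to 1).
#' @return integer vector summing to `n`.
#' @export
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), abs(sum(p) - 1) < 1e-6)
  quota <- n * p
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    frac <- quota - base
    # order(): ties resolved by index order, i.e. first-listed type wins
    give <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Pseudo-bulk samples from single cells
#'
#' For each sample, the requested total cell number is apportioned across
#' cell types by largest remainder on the target proportions; that many
#' cells are drawn uniformly from each type's pool in `sc_test` and their
#' count vectors are summed gene-wise. Sampling is without replacement
#' unless `replace = TRUE` or a type's pool is smaller than its quota, in
#' which case replacement is used for that stratum and a warning is issued.
#'
#' @param sc_test a `single_cell_dataset` (typically the test partition).
#' @param proportions target `proportion_matrix`; every row's cell type must
#'   exist in `sc_test`.
#' @param n_cells cells per pseudo-bulk sample (>= 1); the standard
#'   evaluation setting uses 3000.
#' @param seed integer RNG seed.
#' @param replace sample cells with replacement.
#' @return list with `mixture` (counts-space `expression_matrix`) and
#'   `realized_counts` (cell types x samples integer matrix actually drawn).
#' @export
pseudobulk_sc <- function(sc_test, proportions, n_cells = 3000L, seed = 1L,
                          replace = FALSE) {
  stopifnot(inherits(sc_test, "single_cell_dataset"),
            inherits(proportions, "proportion_matrix"), n_cells >= 1)
  types <- rownames(proportions$values)
  missing <- setdiff(types, unique(sc_test$cell_types))
  if (length(missing))
    stop("cell type(s) absent from sc_test: ", paste(missing, collapse = ", "))
  pools <- lapply(types, function(ct) which(sc_test$cell_types == ct))
  names(pools) <- types
  n_samples <- ncol(proportions$values)
  out <- matrix(0, nrow = nrow(sc_test$counts), ncol = n_samples,
                dimnames = list(rownames(sc_test$counts),
                                colnames(proportions$values)))
  realized <- matrix(0L, nrow = length(types), ncol = n_samples,
                     dimnames = dimnames(proportions$values))
  for (j in seq_len(n_samples)) {
    quota <- largest_remainder(n_cells, proportions$values[, j])
    realized[, j] <- quota
    drawn <- with_seed(derive_seed(seed, j), {
      unlist(lapply(seq_along(types), function(ti) {
        k <- quota[ti]
        if (k == 0) return(integer(0))
        pool <- pools[[ti]]
        rep_here <- replace || k > length(pool)
        if (rep_here && !replace)
          warning(sprintf(
            "type %s: quota %d exceeds pool size %d; sampling with replacement",
            types[ti], k, length(pool)))
        pool[sample.int(length(pool), k, replace = rep_here)]
      }))
    })
    out[, j] <- rowSums(sc_test$counts[, drawn, drop = FALSE])
  }
  list(mixture = expression_matrix(out, space = "counts"),
       realized_counts = realized)
}
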