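#' Synthetic benchmark scenarios
#'
#' Four generated dataset shapes let every protocol run without any
#' download. They copy the cardinalities and difficulty axes of typical
#' benchmark data -- number of cell types, subtype similarity, and
#' cell-count imbalance -- not any particular tissue's biology:
#' \describe{
#'   \item{`coarse8`}{bulk sample bank, 8 weakly related cell types.}
#'   \item{`fine14`}{bulk sample bank, 14 cell types arranged as 7
#'     correlated subtype pairs (harder to separate).}
#'   \item{`tissue7`}{single-cell counts, 7 well-separated types with a
#'     generous 1500 cells each.}
#'   \item{`pbmc13`}{single-cell counts, 13 types (6 correlated pairs plus
#'     one singleton) with strongly imbalanced cell counts (50..3000),
#'     exercising the sampling-with-replacement fallback.}
#' }
#' Each cell type gets an expression program: a shared gene baseline
#' (log-normal across genes), type-specific log-normal variation, and a
#' block of exclusive marker genes up-shifted by `marker_log2fc` doublings.
#' Correlated subtypes blend a common parent program with their own.
#' Observed counts are negative binomial around program x library size.
#'
#' @name fixtures
NULL

.scenario_n_types <- c(coarse8 = 8L, fine14 = 14L, tissue7 = 7L,
                       pbmc13 = 13L)
.scenario_kind <- c(coarse8 = "bulk", fine14 = "bulk", tissue7 = "sc",
                    pbmc13 = "sc")

#' Scenario specification
#'
#' @param name one of `coarse8`, `fine14`, `tissue7`, `pbmc13`.
#' @param n_genes genes simulated; default 2000.
#' @param n_markers_per_type exclusive marker genes per type; default 30.
#' @param marker_log2fc marker up-shift in log2 units; default 4 (16-fold).
#' @param subtype_correlation blend weight of the shared parent program for
#'   correlated subtype pairs, in \[0, 1); default 0.8.
#' @param cells_per_type cells simulated per type (single-cell scenarios):
#'   scalar or per-type vector. Defaults: 1500 for `tissue7`, a log-spaced
#'   50..3000 imbalance for `pbmc13`.
#' @param n_samples_per_type bulk bank replicates per type (bulk
#'   scenarios); default 20.
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (`size = 1/dispersion`); default 0.3.
#' @param cell_library_size mean per-cell depth (single-cell scenarios);
#'   default 5000.
#' @param bulk_library_size per-sample depth of bulk bank replicates;
#'   default 1e6.
#' @param seed integer RNG seed.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(name = c("coarse8", "fine14", "tissue7", "pbmc13"),
                          n_genes = 2000L, n_markers_per_type = 30L,
                          marker_log2fc = 4.0, subtype_correlation = 0.8,
                          cells_per_type = NULL, n_samples_per_type = 20L,
                          nb_dispersion = 0.3, cell_library_size = 5000,
                          bulk_library_size = 1e6, seed = 1L) {
  name <- match.arg(name)
  k <- .scenario_n_types[[name]]
  if (marker_log2fc < 0) stop("marker_log2fc must be >= 0")
  if (subtype_correlation < 0 || subtype_correlation >= 1)
    stop("subtype_correlation must be in [0, 1)")
  if (is.null(cells_per_type)) {
    cells_per_type <- switch(name,
      tissue7 = rep(1500L, k),
      pbmc13 = as.integer(round(exp(seq(log(50), log(3000), length.out = k)))),
      rep(200L, k))
  } else if (length(cells_per_type) == 1) {
    cells_per_type <- rep(as.integer(cells_per_type), k)
  }
  if (any(cells_per_type < 2)) stop("cells_per_type must be >= 2 per type")
  if (n_genes < k * n_markers_per_type)
    stop("n_genes too small to host disjoint marker blocks")
  list(name = name, n_types = k, n_genes = as.integer(n_genes),
       n_markers_per_type = as.integer(n_markers_per_type),
       marker_log2fc = marker_log2fc,
       subtype_correlation = subtype_correlation,
       cells_per_type = cells_per_type,
       n_samples_per_type = as.integer(n_samples_per_type),
       nb_dispersion = nb_dispersion,
       cell_library_size = cell_library_size,
       bulk_library_size = bulk_library_size, seed = as.integer(seed))
}

# subtype pairing plan: list of parent-sharing index pairs
.subtype_pairs <- function(name, k) {
  switch(name,
         fine14 = lapply(seq_len(7), function(i) c(2 * i - 1, 2 * i)),
         pbmc13 = lapply(seq_len(6), function(i) c(2 * i - 1, 2 * i)),
         list())
}

#' Generate a benchmark scenario
#'
#' @param spec a [scenario_spec()].
#' @return list with:
#'   `reference` -- ground-truth `reference_profile` of the planted
#'   per-type programs (CPM scale);
#'   `sc` -- a `single_cell_dataset` (single-cell scenarios, else NULL);
#'   `bulk` -- an `expression_matrix` sample bank and `bulk_labels`
#'   (bulk scenarios, else NULL);
#'   `markers` -- named list of the planted exclusive marker genes;
#'   `spec` -- the input spec.
#' @export
make_scenario <- function(spec = scenario_spec()) {
  k <- spec$n_types
  types <- paste0("CT", seq_len(k))
  genes <- paste0("G", seq_len(spec$n_genes))
  pairs <- .subtype_pairs(spec$name, k)
  programs <- with_seed(spec$seed, {
    base_log <- stats::rnorm(spec$n_genes, mean = log(5), sd = 1)
    eps <- matrix(stats::rnorm(spec$n_genes * k, 0, 0.4), ncol = k)
    # correlated subtype pairs share a parent's log-deviations: blending in
    # log space keeps the planted correlation visible on any scale
    for (pr in pairs) {
      parent_eps <- stats::rnorm(spec$n_genes, 0, 0.4)
      for (t in pr)
        eps[, t] <- spec$subtype_correlation * parent_eps +
          (1 - spec$subtype_correlation) * eps[, t]
    }
    exp(base_log + eps)
  })
  markers <- lapply(seq_len(k), function(t)
    genes[((t - 1) * spec$n_markers_per_type + 1):(t * spec$n_markers_per_type)])
  names(markers) <- types
  for (t in seq_len(k)) {
    idx <- ((t - 1) * spec$n_markers_per_type + 1):(t * spec$n_markers_per_type)
    programs[idx, t] <- programs[idx, t] * 2^spec$marker_log2fc
  }
  rel <- sweep(programs, 2, colSums(programs), "/")
  dimnames(rel) <- list(genes, types)
  truth_ref <- reference_profile(rel * 1e6)
  out <- list(reference = truth_ref, sc = NULL, bulk = NULL,
              bulk_labels = NULL, markers = markers, spec = spec)
  disp_size <- 1 / spec$nb_dispersion
  if (.scenario_kind[[spec$name]] == "sc") {
    total <- sum(spec$cells_per_type)
    counts <- matrix(0L, nrow = spec$n_genes, ncol = total)
    labels <- character(total)
    j <- 0L
    with_seed(derive_seed(spec$seed, 101L), {
      for (t in seq_len(k)) {
        n <- spec$cells_per_type[t]
        libs <- stats::rlnorm(n, meanlog = log(spec$cell_library_size),
                              sdlog = 0.3)
        mu <- outer(rel[, t], libs)
        counts[, (j + 1):(j + n)] <-
          stats::rnbinom(length(mu), mu = mu, size = disp_size)
        labels[(j + 1):(j + n)] <- types[t]
        j <- j + n
      }
    })
    colnames(counts) <- paste0("cell", seq_len(total))
    rownames(counts) <- genes
    out$sc <- single_cell_dataset(counts, cell_types = labels)
  } else {
    n <- spec$n_samples_per_type
    samples <- matrix(0, nrow = spec$n_genes, ncol = n * k)
    labels <- character(n * k)
    with_seed(derive_seed(spec$seed, 202L), {
      for (t in seq_len(k)) {
        mu <- rel[, t] * spec$bulk_library_size
        block <- stats::rnbinom(spec$n_genes * n, mu = rep(mu, n),
                                size = disp_size)
        samples[, ((t - 1) * n + 1):(t * n)] <- block
        labels[((t - 1) * n + 1):(t * n)] <- types[t]
      }
    })
    ids <- paste0(rep(types, each = n), "_rep", rep(seq_len(n), times = k))
    dimnames(samples) <- list(genes, ids)
    out$bulk <- expression_matrix(samples, space = "counts")
    out$bulk_labels <- stats::setNames(labels, ids)
  }
  out
}

#' Sanity report for a generated scenario
#'
#' Checks that the generator's planted structure is recoverable by the rest
#' of the pipeline: an empirical reference is built from the scenario data,
#' signature selection is compared against the planted markers, per-type
#' profiles are correlated with the planted programs, and NNLS is run on
#' clean pseudo-bulk mixtures of the data.
#'
#' @param scenario output of [make_scenario()].
#' @param n_eval_samples mixtures used for the recovery check; default 10.
#' @param seed RNG seed for the recovery mixtures.
#' @return list with `marker_recovery` (fraction of planted markers found
#'   among the selected signatures), `program_pcc` (per-type correlation of
#'   empirical vs planted profiles), and `nnls_mean_abs_error`.
#' @export
scenario_sanity <- function(scenario, n_eval_samples = 10L, seed = 1L) {
  spec <- scenario$spec
  emp_ref <- if (!is.null(scenario$sc))
    build_reference_sc(scenario$sc, normalize = "cpm_mean")
  else build_reference_bulk(scenario$bulk, scenario$bulk_labels)
  sel <- select_signature_genes(
    emp_ref, signature_spec(k_per_type = spec$n_markers_per_type,
                            min_expression = 0))
  planted <- unlist(scenario$markers, use.names = FALSE)
  marker_recovery <- mean(planted %in% sel)
  truth <- scenario$reference$values
  types <- colnames(truth)
  program_pcc <- vapply(types, function(ct)
    suppressWarnings(metric_pcc(emp_ref$values[, ct], truth[, ct])),
    numeric(1))
  props <- gen_proportions_uniform(n_eval_samples, types, seed = seed)
  mix <- if (!is.null(scenario$sc))
    suppressWarnings(pseudobulk_sc(scenario$sc, props, n_cells = 500L,
                                   seed = seed, replace = TRUE))$mixture
  else mix_bulk(emp_ref, props)
  pred <- deconvolve_nnls(mix, emp_ref)
  err <- mean(abs(pred$values - props$values))
  list(marker_recovery = marker_recovery, program_pcc = program_pcc,
       nnls_mean_abs_error = err)
}
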