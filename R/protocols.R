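#' Standardized evaluation protocols
#'
#' Three protocol designs stress different failure modes of deconvolution
#' methods: graded Gamma-Poisson noise (NL_0..NL_10, 50 mixtures per
#' condition), a rare-component proportion gradient (0.001..0.05), and a
#' sweep over the number of cells used to build training pseudo-bulks
#' (100..5000, evaluated against a fixed test set of 50 pseudo-bulks of
#' 3000 cells). All protocols emit tidy [results_table()]s and are
#' deterministic given the config seed; per-condition seeds are derived
#' from it so conditions are independent yet reproducible.
#'
#' @name protocols
NULL

#' Protocol configuration
#'
#' Defaults are the standard evaluation design: 50 samples per condition,
#' the 11-level noise grid, the 7-level rare gradient, training cell
#' numbers 100/500/1000/2000/3000/4000/5000, and a fixed test set of 50
#' pseudo-bulk samples of 3000 cells each.
#'
#' @param n_samples_per_condition mixtures generated per condition.
#' @param noise_grid data.frame of (label, pt) rows; see
#'   [noise_level_grid()].
#' @param rare_spec a [rare_gradient_spec()].
#' @param cellnum_train_grid training pseudo-bulk cell numbers to sweep.
#' @param cellnum_test_grid test pseudo-bulk cell numbers (for sweeps over
#'   the test side).
#' @param n_test_samples size of the fixed test set in the cell-number
#'   protocol.
#' @param test_n_cells cells per fixed-test pseudo-bulk sample.
#' @param n_train_samples training pseudo-bulks generated per grid point.
#' @param shared_proportions reuse one proportion set across noise levels
#'   instead of regenerating per level.
#' @param seed master RNG seed.
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(n_samples_per_condition = 50L,
                            noise_grid = noise_level_grid(),
                            rare_spec = rare_gradient_spec(),
                            cellnum_train_grid = c(100L, 500L, 1000L, 2000L,
                                                   3000L, 4000L, 5000L),
                            cellnum_test_grid = c(100L, 300L, 500L, 700L,
                                                  1000L, 3000L),
                            n_test_samples = 50L, test_n_cells = 3000L,
                            n_train_samples = 50L,
                            shared_proportions = FALSE, seed = 1L) {
  stopifnot(n_samples_per_condition >= 1, n_test_samples >= 1,
            test_n_cells >= 1, n_train_samples >= 1,
            all(cellnum_train_grid >= 1), all(cellnum_test_grid >= 1))
  list(n_samples_per_condition = as.integer(n_samples_per_condition),
       noise_grid = noise_grid, rare_spec = rare_spec,
       cellnum_train_grid = as.integer(cellnum_train_grid),
       cellnum_test_grid = as.integer(cellnum_test_grid),
       n_test_samples = as.integer(n_test_samples),
       test_n_cells = as.integer(test_n_cells),
       n_train_samples = as.integer(n_train_samples),
       shared_proportions = isTRUE(shared_proportions),
       seed = as.integer(seed))
}

# run one method defensively: a failing method degrades to NaN rows rather
# than aborting the sweep (external adapters are expected to be flaky)
.run_method_safely <- function(spec, mixture, reference, truth, by, scenario,
                               noise_level, cfg_metric = metric_config()) {
  .current_truth$truth <- truth
  pred <- tryCatch(run_method(spec, mixture, reference), error = function(e) {
    message(sprintf("method '%s' failed at %s/%s: %s", spec$name, scenario,
                    noise_level, conditionMessage(e)))
    NULL
  })
  if (is.null(pred)) {
    units <- rownames(truth$values)
    return(results_table(
      method = spec$name, scenario = scenario, noise_level = noise_level,
      cell_type = rep(units, each = 6),
      metric = rep(c("PCC", "RMSE", "MAPE", "sMAPE", "SSIM", "JS"),
                   times = length(units)),
      value = NaN, replicate = 1L))
  }
  evaluate_proportions(pred, truth, by = by, cfg = cfg_metric,
                       method = spec$name, scenario = scenario,
                       noise_level = noise_level)
}

#' Noise-robustness protocol
#'
#' For every level of the noise grid: draw ground-truth proportions
#' (uniform by default), mix them through the reference, inject
#' Gamma-Poisson noise at that level, run every method against the clean
#' reference, and score per cell type across the condition's samples.
#'
#' @param reference the `reference_profile` used both to mix and to
#'   deconvolve (methods see the reference, not the truth).
#' @param methods list of [method_spec()]s.
#' @param cfg a [protocol_config()].
#' @param scenario label recorded in the output.
#' @param prop_generator `function(n, cell_type_ids, seed)` returning a
#'   `proportion_matrix`; default [gen_proportions_uniform()].
#' @return a [results_table()].
#' @export
run_noise_protocol <- function(reference, methods, cfg = protocol_config(),
                               scenario = "scenario",
                               prop_generator = gen_proportions_uniform) {
  stopifnot(length(methods) >= 1)
  types <- colnames(reference$values)
  shared <- if (cfg$shared_proportions)
    prop_generator(cfg$n_samples_per_condition, types,
                   derive_seed(cfg$seed, 0L))
  out <- list()
  for (li in seq_len(nrow(cfg$noise_grid))) {
    label <- cfg$noise_grid$label[li]
    pt <- cfg$noise_grid$pt[li]
    truth <- if (cfg$shared_proportions) shared
      else prop_generator(cfg$n_samples_per_condition, types,
                          derive_seed(cfg$seed, li))
    clean <- mix_bulk(reference, truth)
    noisy <- add_noise(clean, noise_params(pt = pt,
                                           seed = derive_seed(cfg$seed, li,
                                                              7L)))$mixture
    for (spec in methods)
      out[[length(out) + 1L]] <- .run_method_safely(
        spec, noisy, reference, truth, by = "cell_type",
        scenario = scenario, noise_level = label)
  }
  do.call(bind_results, out)
}

#' Rare-component sensitivity protocol
#'
#' Mixtures are generated from the rare gradient (one cell type spiked at
#' each level, remaining mass spread over the others). Besides the
#' per-cell-type metrics at each level, the table carries `"SPIKED"` rows:
#' metrics restricted to the spiked entries (truth = the level) across that
#' level's samples, with sMAPE as the headline score since MAPE degenerates
#' at near-zero truths.
#'
#' @inheritParams run_noise_protocol
#' @param noise_pt optional noise level applied to the rare mixtures
#'   (default 0, clean).
#' @return a [results_table()].
#' @export
run_rare_protocol <- function(reference, methods, cfg = protocol_config(),
                              scenario = "scenario", noise_pt = 0) {
  stopifnot(length(methods) >= 1)
  types <- colnames(reference$values)
  rare <- gen_proportions_rare(cfg$rare_spec, types,
                               seed = derive_seed(cfg$seed, 11L))
  truth_all <- rare$proportions
  ann <- rare$annotation
  clean <- mix_bulk(reference, truth_all)
  mixed <- if (noise_pt > 0)
    add_noise(clean, noise_params(pt = noise_pt,
                                  seed = derive_seed(cfg$seed, 13L)))$mixture
  else clean
  out <- list()
  for (spec in methods) {
    .current_truth$truth <- truth_all
    pred <- tryCatch(run_method(spec, mixed, reference), error = function(e) {
      message(sprintf("method '%s' failed: %s", spec$name,
                      conditionMessage(e)))
      NULL
    })
    for (lev in cfg$rare_spec$levels) {
      lev_label <- format(lev, scientific = FALSE, trim = TRUE)
      samples <- ann$sample_id[ann$level == lev]
      if (is.null(pred)) {
        out[[length(out) + 1L]] <- results_table(
          method = spec$name, scenario = scenario, noise_level = lev_label,
          cell_type = c(rep("ALL", 6), "SPIKED", "SPIKED"),
          metric = c("PCC", "RMSE", "MAPE", "sMAPE", "SSIM", "JS",
                     "sMAPE", "RMSE"),
          value = NaN, replicate = 1L)
        next
      }
      t_sub <- proportion_matrix(truth_all$values[, samples, drop = FALSE])
      p_sub <- proportion_matrix(pred$values[, samples, drop = FALSE],
                                 strict = FALSE)
      overall <- evaluate_proportions(p_sub, t_sub, by = "overall",
                                      method = spec$name,
                                      scenario = scenario,
                                      noise_level = lev_label)
      spiked_t <- vapply(samples, function(s)
        truth_all$values[ann$spiked_type[ann$sample_id == s], s], numeric(1))
      spiked_p <- vapply(samples, function(s)
        pred$values[ann$spiked_type[ann$sample_id == s], s], numeric(1))
      spiked <- results_table(
        method = spec$name, scenario = scenario, noise_level = lev_label,
        cell_type = "SPIKED", metric = c("sMAPE", "RMSE"),
        value = c(metric_smape(spiked_t, spiked_p),
                  metric_rmse(spiked_t, spiked_p)),
        replicate = 1L)
      out[[length(out) + 1L]] <- bind_results(overall, spiked)
    }
  }
  do.call(bind_results, out)
}

#' Training cell-number protocol
#'
#' The single-cell dataset is split 70/30 by cells. A fixed test set of
#' `n_test_samples` pseudo-bulks at `test_n_cells` cells each is built once
#' from the test split (its seed path does not depend on the grid point, so
#' it is bit-identical across the sweep). For each training cell number,
#' `n_train_samples` training pseudo-bulks are generated from the train
#' split and handed to the `trainer`, which returns a deconvolver; the
#' returned method is scored on the fixed test set.
#'
#' @param sc_dataset a `single_cell_dataset`.
#' @param trainer `function(train_mixture, train_props, sc_train)`
#'   returning `function(mixture) -> proportion_matrix`. The default
#'   ([trainer_nnls_reference()]) rebuilds a signature from the training
#'   pseudo-bulks by per-gene least squares and deconvolves with NNLS,
#'   standing in for reference-based (non-trained) methods.
#' @param cfg a [protocol_config()].
#' @param scenario label recorded in the output.
#' @param method_name method label for the output rows.
#' @return a [results_table()] with one `noise_level` label per training
#'   cell number (`"cells_<n>"`).
#' @export
run_cellnum_protocol <- function(sc_dataset, trainer = trainer_nnls_reference,
                                 cfg = protocol_config(),
                                 scenario = "scenario",
                                 method_name = "trained") {
  stopifnot(inherits(sc_dataset, "single_cell_dataset"))
  parts <- split_train_test(sc_dataset,
                            split_spec(0.7, seed = derive_seed(cfg$seed, 3L),
                                       unit = "cells"))
  types <- sort(unique(sc_dataset$cell_types))
  test_props <- gen_proportions_uniform(cfg$n_test_samples, types,
                                        seed = derive_seed(cfg$seed, 5L))
  test_mix <- suppressWarnings(
    pseudobulk_sc(parts$test, test_props, n_cells = cfg$test_n_cells,
                  seed = derive_seed(cfg$seed, 6L)))$mixture
  out <- list()
  for (gi in seq_along(cfg$cellnum_train_grid)) {
    n_cells <- cfg$cellnum_train_grid[gi]
    train_props <- gen_proportions_uniform(
      cfg$n_train_samples, types, seed = derive_seed(cfg$seed, 20L, gi))
    train_mix <- suppressWarnings(
      pseudobulk_sc(parts$train, train_props, n_cells = n_cells,
                    seed = derive_seed(cfg$seed, 21L, gi),
                    replace = TRUE))$mixture
    deconvolver <- trainer(train_mix, train_props, parts$train)
    pred <- tryCatch(deconvolver(test_mix), error = function(e) {
      message(sprintf("trainer failed at %d cells: %s", n_cells,
                      conditionMessage(e)))
      NULL
    })
    label <- paste0("cells_", n_cells)
    if (is.null(pred)) {
      out[[length(out) + 1L]] <- results_table(
        method = method_name, scenario = scenario, noise_level = label,
        cell_type = rep(types, each = 6),
        metric = rep(c("PCC", "RMSE", "MAPE", "sMAPE", "SSIM", "JS"),
                     times = length(types)),
        value = NaN, replicate = 1L)
      next
    }
    out[[length(out) + 1L]] <- evaluate_proportions(
      pred, test_props, by = "cell_type", method = method_name,
      scenario = scenario, noise_level = label)
  }
  do.call(bind_results, out)
}

#' Default trainer: signature regression + NNLS
#'
#' Estimates a signature matrix `S` from training pseudo-bulks with known
#' proportions by per-gene least squares (`X ~ S P`, negatives clipped to
#' zero) and returns an NNLS deconvolver against that signature. This
#' emulates a reference-based method whose reference is rebuilt from the
#' generated training set at each grid point.
#'
#' @param train_mixture training pseudo-bulk `expression_matrix`.
#' @param train_props their ground-truth `proportion_matrix`.
#' @param sc_train the training `single_cell_dataset` (unused here; part of
#'   the trainer contract).
#' @return `function(mixture) -> proportion_matrix`.
#' @export
trainer_nnls_reference <- function(train_mixture, train_props, sc_train) {
  X <- train_mixture$values
  P <- train_props$values
  # least-squares signature: S = X P' (P P')^{-1}, clipped at zero
  PPt <- tcrossprod(P)
  S <- X %*% t(P) %*% solve(PPt + diag(1e-10, nrow(PPt)))
  S[S < 0] <- 0
  keep <- rowSums(S) > 0
  ref <- reference_profile(S[keep, , drop = FALSE],
                           cell_type_ids = rownames(P))
  function(mixture) deconvolve_nnls(mixture, ref)
}

#' Echo-truth trainer for end-to-end sentinels
#'
#' Returns a deconvolver that looks up the fixed test truth; used to verify
#' that the cell-number protocol's bookkeeping (sample alignment, fixed
#' test set) is exact.
#'
#' @param test_props the `proportion_matrix` the protocol will evaluate
#'   against.
#' @return a trainer suitable for [run_cellnum_protocol()].
#' @export
trainer_echo <- function(test_props) {
  function(train_mixture, train_props, sc_train) {
    function(mixture)
      proportion_matrix(
        test_props$values[, colnames(mixture$values), drop = FALSE])
  }
}
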