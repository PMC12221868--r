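small_cfg <- function(...) protocol_config(n_samples_per_condition = 6L,
                                           rare_spec = rare_gradient_spec(
                                             n_per_level = 3L,
                                             target_types = "CT1"),
                                           n_test_samples = 4L,
                                           test_n_cells = 120L,
                                           n_train_samples = 8L,
                                           cellnum_train_grid = c(60L, 150L),
                                           seed = 101L, ...)

test_that("the noise protocol sweeps all conditions and the sentinel is perfect", {
  ref <- tiny_reference()
  methods <- list(make_echo_method(), method_spec("nnls", "builtin_nnls"))
  res <- run_noise_protocol(ref, methods, small_cfg(), scenario = "toy")
  expect_equal(sort(unique(res$noise_level)), sort(paste0("NL_", 0:10)))
  echo <- res[res$method == "echo_truth", ]
  expect_true(all(echo$value[echo$metric %in% c("RMSE", "MAPE", "sMAPE",
                                                "JS")] == 0))
  expect_true(all(abs(echo$value[echo$metric %in% c("PCC", "SSIM")] - 1)
                  < 1e-12))
  # every (method, condition, cell type, metric) cell appears exactly once
  expect_equal(nrow(res), 2 * 11 * ncol(ref$values) * 6)
  # NNLS at NL_0 solves the clean linear system essentially exactly
  nl0 <- res[res$method == "nnls" & res$noise_level == "NL_0", ]
  expect_lt(max(nl0$value[nl0$metric == "RMSE"]), 1e-6)
})

test_that("protocol runs are deterministic given the config seed", {
  ref <- tiny_reference()
  methods <- list(method_spec("nnls", "builtin_nnls"))
  cfg <- small_cfg()
  grid3 <- noise_level_grid()[1:3, ]
  cfg$noise_grid <- grid3
  r1 <- run_noise_protocol(ref, methods, cfg)
  r2 <- run_noise_protocol(ref, methods, cfg)
  expect_identical(r1, r2)
})

test_that("a failing method degrades to NaN rows instead of aborting", {
  ref <- tiny_reference()
  boom <- method_spec("boom", "custom", fn = function(m, r) stop("nope"))
  cfg <- small_cfg()
  cfg$noise_grid <- noise_level_grid()[1:2, ]
  expect_message(res <- run_noise_protocol(ref, list(boom), cfg), "failed")
  expect_true(all(is.nan(res$value)))
  expect_equal(nrow(res), 2 * ncol(ref$values) * 6)
})

test_that("the rare protocol reports every gradient level and spiked-component sMAPE", {
  ref <- tiny_reference()
  zero_cfg <- small_cfg()
  zeroer <- method_spec("zeroer", "custom", fn = function(m, r) {
    # predicts nothing for CT1, renormalizing the rest: the spiked
    # component is always missed entirely
    tr <- deconbench:::.current_truth$truth
    v <- tr$values[, colnames(m$values), drop = FALSE]
    v["CT1", ] <- 0
    proportion_matrix(sweep(v, 2, colSums(v), "/"))
  })
  res <- run_rare_protocol(ref, list(make_echo_method(), zeroer), zero_cfg,
                           scenario = "toy")
  levs <- c("0.001", "0.003", "0.005", "0.008", "0.01", "0.03", "0.05")
  expect_setequal(unique(res$noise_level), levs)
  spiked <- res[res$cell_type == "SPIKED" & res$metric == "sMAPE", ]
  expect_equal(nrow(spiked), 2 * 7)
  expect_true(all(spiked$value[spiked$method == "echo_truth"] == 0))
  expect_true(all(spiked$value[spiked$method == "zeroer"] == 2))
})

test_that("the cell-number protocol keeps a bit-identical test set across the grid", {
  sc <- make_scenario(scenario_spec("tissue7", n_genes = 250,
                                    cells_per_type = 40, seed = 3))$sc
  cfg <- small_cfg()
  seen <- list()
  spy_trainer <- function(train_mixture, train_props, sc_train) {
    function(mixture) {
      seen[[length(seen) + 1]] <<- mixture$values
      types <- sort(unique(sc_train$cell_types))
      proportion_matrix(matrix(1 / length(types), length(types),
                               ncol(mixture$values),
                               dimnames = list(types,
                                               colnames(mixture$values))))
    }
  }
  res <- run_cellnum_protocol(sc, spy_trainer, cfg, method_name = "spy")
  expect_length(seen, 2)
  expect_identical(seen[[1]], seen[[2]])
  expect_setequal(unique(res$noise_level), c("cells_60", "cells_150"))

  # echo trainer: zero error end to end
  types <- sort(unique(sc$cell_types))
  test_props <- gen_proportions_uniform(cfg$n_test_samples, types,
                                        seed = deconbench:::derive_seed(
                                          cfg$seed, 5L))
  res2 <- run_cellnum_protocol(sc, trainer_echo(test_props), cfg)
  expect_true(all(res2$value[res2$metric %in% c("RMSE", "MAPE", "sMAPE",
                                                "JS")] == 0))

  # the default trainer recovers reasonable proportions at moderate depth
  res3 <- run_cellnum_protocol(sc, trainer_nnls_reference, cfg)
  rmse_hi <- res3$value[res3$noise_level == "cells_150" &
                          res3$metric == "RMSE"]
  expect_lt(median(rmse_hi), 0.1)
})
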