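test_that("vector metrics satisfy their boundary identities", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(metric_pcc(x, x), 1.0)
  expect_equal(metric_pcc(x, -x), -1.0)
  expect_warning(flat <- metric_pcc(rep(1, 4), x), "zero-variance")
  expect_true(is.nan(flat))

  expect_equal(metric_rmse(x, x), 0)
  expect_equal(metric_rmse(c(0.2, 0.8), c(0.4, 0.6)), 0.2)
  expect_error(metric_rmse(x, x[-1]), "length")

  expect_equal(as.numeric(metric_mape(x, x)), 0)
  expect_equal(as.numeric(metric_mape(0.5, 0.25)), 0.5)
  skipped <- suppressWarnings(metric_mape(c(0, 0), c(1, 1)))
  expect_true(is.nan(as.numeric(skipped)))
  expect_equal(attr(skipped, "n_skipped"), 2)

  expect_equal(metric_smape(x, x), 0)
  expect_equal(metric_smape(0.01, 0), 2)       # zero-prediction bound
  expect_equal(metric_smape(c(0, 0.5), c(0, 0.5)), 0)  # 0/0 terms are 0
  expect_error(metric_smape(-1, 1), "nonnegative")

  expect_equal(metric_ssim(x, x), 1.0)
  expect_equal(metric_ssim(x, 10 * x), 1.0)    # max-scaling => scale-free
  expect_warning(z <- metric_ssim(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 1)

  expect_equal(metric_js(x, x), 0)
  expect_equal(metric_js(c(1, 0), c(0, 1)), 1.0)   # disjoint, base 2
  expect_error(metric_js(c(0, 0), c(1, 0)), "zero-sum")
})

test_that("metrics agree with independent brute-force implementations", {
  withr::with_seed(13, {
    for (i in 1:200) {
      x <- runif(50); y <- runif(50)
      expect_lt(abs(metric_pcc(x, y) - cor(x, y)), 1e-12)
      expect_lt(abs(metric_rmse(x, y) - sqrt(sum((x - y)^2) / 50)), 1e-12)
      expect_lt(abs(as.numeric(metric_mape(x, y)) -
                    mean(abs(x - y) / x)), 1e-12)
      expect_lt(abs(metric_ssim(x, y) - ssim_oracle(x, y)), 1e-10)
      js <- metric_js(x, y)
      expect_lt(abs(js - js_oracle(x, y)), 1e-12)
      expect_lt(abs(js - metric_js(y, x)), 1e-14)  # symmetry
      expect_true(js >= 0 && js <= 1)
      expect_true(metric_ssim(x, y) >= -1 && metric_ssim(x, y) <= 1)
    }
  })
})

test_that("the accuracy score is a weighted rank sum, lower is better", {
  one <- list(m1 = c(PCC = 0.9, RMSE = 0.1, MAPE = 0.2, SSIM = 0.8))
  expect_equal(accuracy_score(one)$AS, 4)  # four rank-1s at unit weight

  two <- list(A = c(PCC = 0.95, RMSE = 0.05, MAPE = 0.1, SSIM = 0.9),
              B = c(PCC = 0.80, RMSE = 0.20, MAPE = 0.3, SSIM = 0.7))
  as2 <- accuracy_score(two)
  expect_equal(as2$AS[as2$method == "A"], 4)
  expect_equal(as2$AS[as2$method == "B"], 8)
  expect_equal(as2$method[1], "A")   # sorted ascending by AS

  # ties share the mean rank
  tie <- list(A = c(PCC = 0.9, RMSE = 0.1, MAPE = 0.1, SSIM = 0.8),
              B = c(PCC = 0.9, RMSE = 0.1, MAPE = 0.1, SSIM = 0.8))
  expect_equal(accuracy_score(tie)$AS, c(6, 6))

  expect_error(accuracy_score(list(A = c(PCC = 1, RMSE = 0, MAPE = 0))),
               "SSIM")

  # custom weights follow the config
  w <- metric_config(as_weights = c(PCC = 2, RMSE = 1, MAPE = 1, SSIM = 0))
  asw <- accuracy_score(two, w)
  expect_equal(asw$AS[asw$method == "A"], 4)   # 2*1 + 1 + 1 + 0
})

test_that("AS depends on metric values only through their ranks", {
  withr::with_seed(17, {
    vals <- replicate(6, c(PCC = runif(1), RMSE = runif(1),
                           MAPE = runif(1), SSIM = runif(1)),
                      simplify = FALSE)
    names(vals) <- paste0("m", 1:6)
    base_order <- accuracy_score(vals)$method
    for (rep in 1:20) {
      # strictly monotone per-metric transforms must not change the ordering
      const <- runif(1, 1, 2)
      trans <- list(PCC = function(v) v^3,
                    RMSE = function(v) exp(v) * const,
                    MAPE = function(v) log1p(v),
                    SSIM = function(v) 5 * v - 2)
      tv <- lapply(vals, function(m)
        sapply(names(m), function(k) trans[[k]](m[[k]])))
      expect_identical(accuracy_score(tv)$method, base_order)
    }
  })
})

test_that("evaluate_proportions reproduces hand-computed per-row metrics", {
  withr::with_seed(19, {
    truth <- gen_proportions_uniform(5, c("A", "B", "C"), seed = 1)
    off <- truth$values + matrix(runif(15, -0.02, 0.02), 3, 5)
    off <- pmax(off, 0)
    pred <- proportion_matrix(sweep(off, 2, colSums(off), "/"))
  })
  tab <- evaluate_proportions(pred, truth, by = "cell_type",
                              method = "m", scenario = "sc")
  for (ct in c("A", "B", "C")) {
    t <- truth$values[ct, ]; p <- pred$values[ct, ]
    expect_equal(tab$value[tab$cell_type == ct & tab$metric == "RMSE"],
                 metric_rmse(t, p))
    expect_equal(tab$value[tab$cell_type == ct & tab$metric == "PCC"],
                 metric_pcc(t, p))
    expect_equal(tab$value[tab$cell_type == ct & tab$metric == "JS"],
                 metric_js(t, p))
  }
  # perfect prediction: errors 0, similarities maximal
  perfect <- evaluate_proportions(truth, truth, by = "cell_type")
  expect_true(all(perfect$value[perfect$metric %in%
                                  c("RMSE", "MAPE", "sMAPE", "JS")] == 0))
  expect_true(all(perfect$value[perfect$metric %in% c("PCC", "SSIM")] == 1))

  # permuting samples in both inputs leaves every metric unchanged
  perm <- sample(colnames(truth$values))
  tab2 <- evaluate_proportions(
    proportion_matrix(pred$values[, perm]),
    proportion_matrix(truth$values[, perm]),
    by = "cell_type", method = "m", scenario = "sc")
  expect_equal(tab$value, tab2$value)

  # overall mode flattens the matrices under the ALL sentinel
  tov <- evaluate_proportions(pred, truth, by = "overall")
  expect_equal(unique(tov$cell_type), "ALL")
  expect_equal(tov$value[tov$metric == "RMSE"],
               metric_rmse(as.numeric(truth$values), as.numeric(pred$values)))
})
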