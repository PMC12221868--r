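test_that("the dispersion scale follows its stated formula", {
  p1 <- noise_params(pt = 0.1)
  expect_lt(abs(compute_sigma(1e12, p1, delta = 0) - 0.18), 1e-9)
  expect_equal(compute_sigma(1, noise_params(pt = 1), delta = 0), 2.8)
  # monotone: increasing in pt, decreasing in mu0
  expect_gt(compute_sigma(10, noise_params(pt = 0.8), 0),
            compute_sigma(10, noise_params(pt = 0.2), 0))
  expect_gt(compute_sigma(1, p1, 0), compute_sigma(100, p1, 0))
  expect_error(compute_sigma(0, p1), "mu0")
  # delta enters as exp(delta/2) by default; alternates are selectable
  expect_equal(compute_sigma(1, noise_params(pt = 1), delta = 2),
               2.8 * exp(1))
  expect_equal(compute_sigma(1, noise_params(pt = 1,
                                             delta_exponent = "identity"),
                             delta = 2), 2.8 * exp(2))
})

test_that("pt = 0 is a bit-exact identity (noise level NL_0)", {
  withr::with_seed(2, {
    mix <- expression_matrix(matrix(rpois(60, 30), 10, 6,
                                    dimnames = list(paste0("g", 1:10),
                                                    paste0("s", 1:6))))
  })
  out <- add_noise(mix, noise_params(pt = 0, seed = 1))
  expect_identical(out$mixture$values, mix$values)
})

test_that("the Gamma stage preserves the mean and zeros pass through", {
  m <- matrix(c(50, 0, 10, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  mix <- expression_matrix(m)
  out <- add_noise(mix, noise_params(pt = 0.5, seed = 3))
  expect_true(all(out$mixture$values[m == 0] == 0))
  expect_true(all(out$mixture$values == round(out$mixture$values)))
  # mu0 reconstructed inside the realization equals the input bit-exactly
  expect_identical(out$realization$mu0, m)
})

test_that("noisy counts match the Gamma-Poisson moment oracles", {
  mu <- 50; pt <- 0.3; n <- 1e5
  mix <- expression_matrix(matrix(mu, 1, n,
                                  dimnames = list("g",
                                                  paste0("s", seq_len(n)))))
  v <- add_noise(mix, noise_params(pt = pt, seed = 11))$mixture$values[1, ]
  expect_lt(abs(mean(v) - mu) / mu, 0.01)
  # law of total variance, delta integrated out numerically:
  # Var = mu + mu^2 * E[sigma(delta)^2]
  integrand <- function(d)
    ((1.8 * pt + 1 / mu) * exp(d / 2))^2 * dnorm(d, 0, sqrt(0.25))
  e_sigma2 <- integrate(integrand, -6, 6)$value
  target_var <- mu + mu^2 * e_sigma2
  expect_lt(abs(var(v) - target_var) / target_var, 0.05)
})

test_that("with fixed delta the marginal is negative binomial", {
  mu <- 20; pt <- 0.5; n <- 1e5
  mix <- expression_matrix(matrix(mu, 1, n,
                                  dimnames = list("g",
                                                  paste0("s", seq_len(n)))))
  # delta_var = 0 freezes delta at 0 so sigma is a known constant
  v <- add_noise(mix, noise_params(pt = pt, delta_var = 0,
                                   seed = 21))$mixture$values[1, ]
  sigma <- (1.8 * pt + 1 / mu)
  size <- 1 / sigma^2
  expect_lt(abs(mean(v) - mu) / mu, 0.02)
  expect_lt(abs(var(v) - (mu + mu^2 * sigma^2)) / (mu + mu^2 * sigma^2), 0.05)
  # chi-square goodness of fit against the NB pmf (bins 0..59 plus tail)
  obs <- c(tabulate(v + 1, nbins = 60), sum(v >= 60))
  pr <- c(dnbinom(0:59, size = size, mu = mu),
          pnbinom(59, size = size, mu = mu, lower.tail = FALSE))
  keep <- pr * n >= 5
  stat <- sum((obs[keep] - n * pr[keep])^2 / (n * pr[keep]))
  pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("as sigma shrinks the output approaches Poisson", {
  mu <- 1000; n <- 2e4
  mix <- expression_matrix(matrix(mu, 1, n,
                                  dimnames = list("g",
                                                  paste0("s", seq_len(n)))))
  v <- add_noise(mix, noise_params(pt = 1e-4, delta_var = 0,
                                   seed = 31))$mixture$values[1, ]
  ratio <- var(v) / mean(v)
  sigma2 <- (1.8e-4 + 1 / mu)^2
  # Fano factor of the NB is 1 + mu*sigma^2; with these parameters ~1.001
  mc_se <- sqrt(2 / n)   # approximate SE of a variance ratio
  expect_lt(abs(ratio - (1 + mu * sigma2)), 3 * mc_se)
})

test_that("per-gene delta scope reuses one draw per gene across samples", {
  withr::with_seed(5, {
    mix <- expression_matrix(matrix(rpois(40, 50) + 1, 8, 5,
                                    dimnames = list(paste0("g", 1:8),
                                                    paste0("s", 1:5))))
  })
  out <- add_noise(mix, noise_params(pt = 0.4, delta_scope = "per_gene",
                                     seed = 2))
  d <- out$realization$delta
  expect_true(all(d == d[, 1]))
  out2 <- add_noise(mix, noise_params(pt = 0.4, seed = 2))
  expect_false(all(out2$realization$delta == out2$realization$delta[, 1]))
})

test_that("noise perturbs column sums but keeps their expectation", {
  withr::with_seed(6, {
    mix <- expression_matrix(matrix(rpois(3000, 100), 100, 30,
                                    dimnames = list(paste0("g", 1:100),
                                                    paste0("s", 1:30))))
  })
  out <- add_noise(mix, noise_params(pt = 0.3, seed = 4))$mixture
  expect_false(any(colSums(out$values) == colSums(mix$values)))
  expect_lt(abs(sum(out$values) - sum(mix$values)) / sum(mix$values), 0.05)
})

test_that("the noise-level grid spans NL_0..NL_10 in steps of 0.1", {
  grid <- noise_level_grid()
  expect_equal(nrow(grid), 11)
  expect_equal(grid$pt, seq(0, 1, by = 0.1))
  expect_equal(grid$label, paste0("NL_", 0:10))
})
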