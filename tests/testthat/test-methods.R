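recovery_setup <- function(n_genes = 200, k = 5, n_samples = 10, seed = 23) {
  withr::with_seed(seed, {
    R <- matrix(rlnorm(n_genes * k, 2, 1), n_genes, k,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("T", seq_len(k))))
  })
  ref <- reference_profile(R)
  truth <- gen_proportions_uniform(n_samples, colnames(R), seed = seed + 1)
  list(ref = ref, truth = truth, mix = mix_bulk(ref, truth))
}

test_that("NNLS recovers known proportions from noise-free mixtures", {
  s <- recovery_setup()
  pred <- deconvolve_nnls(s$mix, s$ref)
  expect_lt(max(abs(pred$values - s$truth$values)), 1e-6)
  expect_true(all(pred$values >= 0))
  expect_true(all(abs(colSums(pred$values) - 1) < 1e-8))

  # a mixture equal to one reference column maps to the unit vector
  col_mix <- expression_matrix(s$ref$values[, 3, drop = FALSE],
                               sample_ids = "s")
  e3 <- deconvolve_nnls(col_mix, s$ref)
  expect_lt(max(abs(e3$values - c(0, 0, 1, 0, 0))), 1e-6)
})

test_that("simplex-constrained LS matches NNLS recovery and dominates its objective", {
  s <- recovery_setup()
  cls <- deconvolve_cls(s$mix, s$ref)
  expect_lt(max(abs(cls$values - s$truth$values)), 1e-6)

  # single cell type: the only feasible weight is 1
  one_ref <- reference_profile(s$ref$values[, 1, drop = FALSE])
  one_mix <- expression_matrix(s$ref$values[, 1, drop = FALSE] * 0.5,
                               sample_ids = "s")
  expect_equal(as.numeric(deconvolve_cls(one_mix, one_ref)$values), 1)

  # on noisy data the CLS objective must not exceed the normalized-NNLS one
  noisy <- add_noise(s$mix, noise_params(pt = 0.5, seed = 3))$mixture
  al <- validate_pair(s$ref, noisy)
  w_cls <- deconvolve_cls(noisy, s$ref)$values
  w_nnls <- deconvolve_nnls(noisy, s$ref)$values
  for (j in seq_len(ncol(w_cls))) {
    obj <- function(w) sum((al$reference$values %*% w -
                              al$mixture$values[, j])^2)
    expect_lte(obj(w_cls[, j]), obj(w_nnls[, j]) + 1e-8 * obj(w_nnls[, j]))
  }
})

test_that("builtin methods are permutation-equivariant in the reference columns", {
  s <- recovery_setup(n_samples = 4)
  perm <- c(4, 2, 5, 1, 3)
  ref_perm <- reference_profile(s$ref$values[, perm])
  for (f in list(deconvolve_nnls, deconvolve_cls)) {
    w <- f(s$mix, s$ref)$values
    w_perm <- f(s$mix, ref_perm)$values
    expect_equal(w_perm, w[perm, ], tolerance = 1e-7)
  }
})

test_that("recovered proportions converge to truth as additive noise shrinks", {
  s <- recovery_setup(n_samples = 5)
  errs <- sapply(c(1e-1, 1e-2, 1e-3), function(scale) {
    noisy_vals <- withr::with_seed(31, {
      pmax(s$mix$values * (1 + matrix(rnorm(length(s$mix$values), 0, scale),
                                      nrow(s$mix$values))), 0)
    })
    noisy <- expression_matrix(noisy_vals)
    max(abs(deconvolve_nnls(noisy, s$ref)$values - s$truth$values))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("duplicate reference columns warn but do not abort", {
  s <- recovery_setup(k = 3, n_samples = 2)
  dup_vals <- cbind(s$ref$values, T9 = s$ref$values[, 1])
  expect_warning(deconvolve_nnls(s$mix, reference_profile(dup_vals)),
                 "duplicate")
})

test_that("the external adapter round-trips through the shell contract", {
  s <- recovery_setup(n_samples = 3)
  wd <- withr::local_tempdir()
  truth_file <- file.path(wd, "truth.tsv")
  write_proportion_matrix(s$truth, truth_file)

  echo <- method_spec("echo", "external",
                      command = sprintf("cp %s {output} # {reference} {mixture}",
                                        truth_file))
  pred <- run_external(echo, s$mix, s$ref, workdir = file.path(wd, "run1"))
  expect_equal(pred$values, s$truth$values, tolerance = 1e-12)

  # unnormalized output columns are renormalized leniently with a warning
  unnorm <- proportion_matrix(s$truth$values)
  unnorm$values <- unnorm$values * 3
  raw_file <- file.path(wd, "unnorm.tsv")
  deconbench:::.write_tsv_matrix(unnorm$values, raw_file)
  spec_un <- method_spec("unnorm", "external",
                         command = sprintf("cp %s {output} # {reference} {mixture}",
                                           raw_file))
  expect_warning(pred_un <- run_external(spec_un, s$mix, s$ref,
                                         workdir = file.path(wd, "run2")),
                 "renormalized")
  expect_equal(pred_un$values, s$truth$values, tolerance = 1e-12)

  # wrong cell-type set is an error naming the symmetric difference
  wrong <- s$truth$values
  rownames(wrong) <- c("T1", "T2", "T3", "T4", "WRONG")
  wrong_file <- file.path(wd, "wrong.tsv")
  deconbench:::.write_tsv_matrix(wrong, wrong_file)
  spec_w <- method_spec("wrong", "external",
                        command = sprintf("cp %s {output} # {reference} {mixture}",
                                          wrong_file))
  expect_error(run_external(spec_w, s$mix, s$ref,
                            workdir = file.path(wd, "run3")), "WRONG")

  # nonzero exit and missing output are reported as errors
  fail <- method_spec("fail", "external",
                      command = "false # {reference} {mixture} {output}")
  expect_error(run_external(fail, s$mix, s$ref,
                            workdir = file.path(wd, "run4")), "status")
  silent <- method_spec("silent", "external",
                        command = "true # {reference} {mixture} {output}")
  expect_error(run_external(silent, s$mix, s$ref,
                            workdir = file.path(wd, "run5")), "no output")

  expect_error(method_spec("bad", "external", command = "cmd {reference}"),
               "placeholder")
})
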