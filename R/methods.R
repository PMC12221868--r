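#' Baseline deconvolvers and the external-method adapter
#'
#' Two built-in baselines make every protocol runnable end-to-end: NNLS
#' (non-negative least squares per sample, then normalize to the simplex)
#' and CLS (least squares constrained to the simplex during the solve).
#' Published third-party methods connect through a command-template adapter
#' that exchanges the package's TSV dialects.
#'
#' @name methods-module
NULL

# registry through which protocols expose the current ground truth to the
# echo-truth sentinel (test-only method)
.current_truth <- new.env(parent = emptyenv())

#' Describe a deconvolution method
#'
#' @param name unique display name.
#' @param kind `"builtin_nnls"`, `"builtin_cls"`, `"external"` (command
#'   template), or `"custom"` (an R function
#'   `function(mixture, reference) -> proportion_matrix`).
#' @param command for `"external"`: a shell command template containing
#'   `{reference}`, `{mixture}`, and `{output}` placeholders.
#' @param fn for `"custom"`: the deconvolver function.
#' @param normalize apply column-TPM scaling to both inputs before solving.
#' @return a `method_spec` list.
#' @export
method_spec <- function(name, kind = c("builtin_nnls", "builtin_cls",
                                       "external", "custom"),
                        command = NULL, fn = NULL, normalize = FALSE) {
  kind <- match.arg(kind)
  if (kind == "external") {
    if (is.null(command)) stop("external method needs a command template")
    for (ph in c("{reference}", "{mixture}", "{output}"))
      if (!grepl(ph, command, fixed = TRUE))
        stop("command template is missing placeholder ", ph)
  }
  if (kind == "custom" && !is.function(fn))
    stop("custom method needs fn(mixture, reference)")
  structure(list(name = name, kind = kind, command = command, fn = fn,
                 normalize = normalize), class = "method_spec")
}

.tpm_scale <- function(m) sweep(m, 2, colSums(m) / 1e6, "/")

.prep_pair <- function(mixture, reference, normalize) {
  al <- validate_pair(reference, mixture)
  R <- al$reference$values
  Y <- al$mixture$values
  if (normalize) {
    R <- .tpm_scale(R)
    Y <- .tpm_scale(Y)
  }
  dup <- duplicated(t(R))
  if (any(dup))
    warning("reference has duplicate column(s): ",
            paste(colnames(R)[dup], collapse = ", "))
  list(R = R, Y = Y)
}

#' Deconvolve by non-negative least squares
#'
#' Per sample solves `min ||R w - y||^2, w >= 0` (Lawson-Hanson NNLS) and
#' normalizes the solution to sum 1. An all-zero solution falls back to the
#' uniform vector with a warning.
#'
#' @param mixture an `expression_matrix`.
#' @param reference a `reference_profile` (gene-aligned internally via
#'   [validate_pair()]).
#' @param normalize apply column-TPM scaling to both inputs first.
#' @return a `proportion_matrix` (cell types x samples).
#' @export
deconvolve_nnls <- function(mixture, reference, normalize = FALSE) {
  pr <- .prep_pair(mixture, reference, normalize)
  k <- ncol(pr$R)
  W <- apply(pr$Y, 2, function(y) {
    w <- pracma::lsqnonneg(pr$R, y)$x
    s <- sum(w)
    if (s <= 0) {
      warning("all-zero NNLS solution; returning uniform proportions")
      rep(1 / k, k)
    } else w / s
  })
  W <- matrix(W, nrow = k,
              dimnames = list(colnames(pr$R), colnames(pr$Y)))
  proportion_matrix(W)
}

#' Deconvolve by simplex-constrained least squares
#'
#' Per sample solves the quadratic program
#' `min ||R w - y||^2, w >= 0, sum(w) = 1` with an active-set KKT solver
#' (tolerance 1e-9), i.e. the sum-to-one constraint is enforced during the
#' solve rather than by post-normalization.
#'
#' @inheritParams deconvolve_nnls
#' @return a `proportion_matrix`.
#' @export
deconvolve_cls <- function(mixture, reference, normalize = FALSE) {
  pr <- .prep_pair(mixture, reference, normalize)
  W <- apply(pr$Y, 2, function(y) simplex_ls(pr$R, y))
  W <- matrix(W, nrow = ncol(pr$R),
              dimnames = list(colnames(pr$R), colnames(pr$Y)))
  proportion_matrix(W)
}

#' Run an external deconvolution tool
#'
#' Writes the aligned reference and mixture as TSV into `workdir`,
#' substitutes the `{reference}`/`{mixture}`/`{output}` placeholders of the
#' command template, invokes the command through the shell, and parses the
#' output TSV (cell types x samples). Output columns are renormalized
#' leniently (many tools return unnormalized weights); a wrong cell-type
#' set is an error naming the symmetric difference.
#'
#' @param spec an external [method_spec()].
#' @param mixture an `expression_matrix`.
#' @param reference a `reference_profile`.
#' @param workdir exchange directory (created if missing).
#' @return a `proportion_matrix`; captured stdout/stderr is attached as
#'   attribute `"log"`.
#' @export
run_external <- function(spec, mixture, reference,
                         workdir = tempfile("extmethod")) {
  stopifnot(inherits(spec, "method_spec"), spec$kind == "external")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  al <- validate_pair(reference, mixture)
  ref_path <- file.path(workdir, "reference.tsv")
  mix_path <- file.path(workdir, "mixture.tsv")
  out_path <- file.path(workdir, "proportions.tsv")
  write_reference_profile(al$reference, ref_path)
  write_expression_matrix(al$mixture, mix_path)
  cmd <- spec$command
  cmd <- gsub("{reference}", ref_path, cmd, fixed = TRUE)
  cmd <- gsub("{mixture}", mix_path, cmd, fixed = TRUE)
  cmd <- gsub("{output}", out_path, cmd, fixed = TRUE)
  log <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(log, "status") %||% 0L
  if (status != 0)
    stop(sprintf("external method '%s' exited with status %d; log:\n%s",
                 spec$name, status, paste(log, collapse = "\n")))
  if (!file.exists(out_path))
    stop(sprintf("external method '%s' produced no output file; log:\n%s",
                 spec$name, paste(log, collapse = "\n")))
  pred <- read_proportion_matrix(out_path, strict = FALSE)
  want <- colnames(al$reference$values)
  got <- rownames(pred$values)
  if (!setequal(want, got))
    stop(sprintf("external method '%s': cell-type mismatch (%s)", spec$name,
                 paste(union(setdiff(want, got), setdiff(got, want)),
                       collapse = ", ")))
  pred <- proportion_matrix(pred$values[want, , drop = FALSE])
  attr(pred, "log") <- log
  pred
}

#' Dispatch any method spec on a (mixture, reference) pair
#'
#' @param spec a [method_spec()].
#' @param mixture an `expression_matrix`.
#' @param reference a `reference_profile`.
#' @return a `proportion_matrix`.
#' @export
run_method <- function(spec, mixture, reference) {
  switch(spec$kind,
         builtin_nnls = deconvolve_nnls(mixture, reference, spec$normalize),
         builtin_cls = deconvolve_cls(mixture, reference, spec$normalize),
         external = run_external(spec, mixture, reference),
         custom = {
           p <- spec$fn(mixture, reference)
           stopifnot(inherits(p, "proportion_matrix"))
           p
         })
}

#' Echo-truth sentinel method
#'
#' A test-only "method" that ignores its inputs and returns the ground
#' truth for the samples being queried. Running it through a protocol must
#' yield zero error and maximal similarity everywhere, which makes it an
#' end-to-end correctness sentinel for the whole pipeline.
#'
#' @param truth_env an environment with a `truth` field, kept current by
#'   the protocols (`make_echo_method` reads `truth_env$truth` at call
#'   time). The default is the package-internal registry the protocols
#'   update before each method call.
#' @param name method display name.
#' @return a [method_spec()] of kind `"custom"`.
#' @export
make_echo_method <- function(truth_env = .current_truth,
                             name = "echo_truth") {
  method_spec(name, kind = "custom", fn = function(mixture, reference) {
    tr <- truth_env$truth
    proportion_matrix(tr$values[, colnames(mixture$values), drop = FALSE])
  })
}
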