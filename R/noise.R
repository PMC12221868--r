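#' Gamma-Poisson (negative binomial) noise model
#'
#' Clean mixtures are perturbed with a calibrated negative-binomial noise
#' model: each entry's expected count `mu0 = r0 * L` (relative expression
#' times library size) is given a dispersion scale
#' `sigma = (base * pt + 1/mu0) * exp(delta/2)` with `delta ~ N(0, 0.25)`,
#' a Gamma draw `mu ~ Gamma(shape = 1/sigma^2, scale = mu0 * sigma^2)`
#' preserves the mean, and the observed count is `v ~ Poisson(mu)`.
#' Marginally `v` is negative binomial with mean `mu0` and variance
#' `mu0 + mu0^2 * sigma^2`. The scalar `pt` in \[0, 1\] grades the noise;
#' `pt = 0` (level NL_0) means no noise is applied at all.
#'
#' @name noise-model
NULL

#' Noise model parameters
#'
#' @param pt noise level in \[0, 1\]; 0 encodes NL_0 (identity).
#' @param base scale coefficient on `pt` in the dispersion formula;
#'   default 1.8.
#' @param delta_var variance of the log-normal perturbation `delta`;
#'   default 0.25 (i.e. sd 0.5).
#' @param delta_scope draw one `delta` per matrix entry (default) or one per
#'   gene, reused across samples.
#' @param delta_exponent how `delta` enters the dispersion scale:
#'   `"half"` (default, `exp(delta/2)`), `"identity"` (`exp(delta)`), or
#'   `"square"` (`exp(delta^2)`). Alternatives are provided because the
#'   published rendering of the formula is typographically ambiguous.
#' @param seed integer RNG seed.
#' @return a `noise_params` list.
#' @export
noise_params <- function(pt, base = 1.8, delta_var = 0.25,
                         delta_scope = c("per_entry", "per_gene"),
                         delta_exponent = c("half", "identity", "square"),
                         seed = 1L) {
  delta_scope <- match.arg(delta_scope)
  delta_exponent <- match.arg(delta_exponent)
  if (pt < 0 || pt > 1) stop("pt must be in [0, 1]")
  if (delta_var < 0) stop("delta_var must be >= 0")
  if (base <= 0) stop("base must be > 0")
  list(pt = pt, base = base, delta_var = delta_var,
       delta_scope = delta_scope, delta_exponent = delta_exponent,
       seed = as.integer(seed))
}

.delta_factor <- function(delta, exponent) {
  switch(exponent,
         half = exp(delta / 2),
         identity = exp(delta),
         square = exp(delta^2))
}

#' Dispersion scale of the noise model
#'
#' `sigma = (base * pt + 1/mu0) * exp(delta/2)` under the default exponent:
#' strictly increasing in `pt`, decreasing in `mu0` (low-expression entries
#' are noisier), with `exp(delta/2)` injecting gene-level variability.
#'
#' @param mu0 expected count, > 0 (vectorized).
#' @param params a [noise_params()].
#' @param delta value(s) of the normal perturbation (default 0).
#' @return sigma, same length as `mu0`.
#' @export
compute_sigma <- function(mu0, params, delta = 0) {
  if (any(mu0 <= 0)) stop("mu0 must be > 0")
  (params$base * params$pt + 1 / mu0) *
    .delta_factor(delta, params$delta_exponent)
}

#' Inject Gamma-Poisson noise into a mixture
#'
#' With `pt = 0` the input is returned unchanged (noise level NL_0).
#' Otherwise every positive entry is replaced by a negative-binomial draw as
#' described in [noise-model]; zero entries pass through as zero. Library
#' sizes default to the column sums of the input. Output column sums are
#' random (not renormalized), but their expectations equal the input's.
#'
#' @param mixture a nonnegative `expression_matrix`.
#' @param params a [noise_params()].
#' @param library_sizes optional per-sample library-size override.
#' @return list with `mixture` (counts-space `expression_matrix` of noisy
#'   draws) and `realization` (the intermediate quantities: `r0`, `L`,
#'   `mu0`, `delta`, `sigma`, `mu_gamma`, `counts`).
#' @export
add_noise <- function(mixture, params, library_sizes = NULL) {
  stopifnot(inherits(mixture, "expression_matrix"))
  x <- mixture$values
  if (any(x < 0)) stop("mixture must be nonnegative")
  if (params$pt == 0) {
    return(list(mixture = mixture, realization = NULL))
  }
  L <- library_sizes %||% colSums(x)
  if (length(L) != ncol(x)) stop("library_sizes must have one entry per sample")
  if (any(L <= 0)) stop("library sizes must be positive")
  r0 <- sweep(x, 2, colSums(x), "/")
  mu0 <- sweep(r0, 2, L, "*")
  n <- length(mu0)
  res <- with_seed(params$seed, {
    delta <- if (params$delta_scope == "per_entry") {
      matrix(stats::rnorm(n, 0, sqrt(params$delta_var)),
             nrow = nrow(mu0))
    } else {
      matrix(rep(stats::rnorm(nrow(mu0), 0, sqrt(params$delta_var)),
                 times = ncol(mu0)), nrow = nrow(mu0))
    }
    pos <- mu0 > 0
    sigma <- matrix(NA_real_, nrow(mu0), ncol(mu0))
    sigma[pos] <- compute_sigma(mu0[pos], params, delta[pos])
    shape <- 1 / sigma[pos]^2
    mu_gamma <- matrix(0, nrow(mu0), ncol(mu0))
    # scale = mu0/shape keeps E[Gamma] = shape * scale = mu0 bit-exactly
    mu_gamma[pos] <- stats::rgamma(sum(pos), shape = shape,
                                   scale = mu0[pos] / shape)
    counts <- matrix(0, nrow(mu0), ncol(mu0))
    counts[pos] <- stats::rpois(sum(pos), mu_gamma[pos])
    list(delta = delta, sigma = sigma, mu_gamma = mu_gamma, counts = counts)
  })
  dimnames(res$counts) <- dimnames(x)
  noisy <- expression_matrix(res$counts, space = "counts")
  realization <- list(r0 = r0, L = L, mu0 = mu0, delta = res$delta,
                      sigma = res$sigma, mu_gamma = res$mu_gamma,
                      counts = res$counts)
  list(mixture = noisy, realization = realization)
}

#' The graded noise-level grid
#'
#' Eleven conditions NL_0 .. NL_10: NL_0 is the no-noise identity (pt = 0)
#' and NL_1 .. NL_10 set pt = 0.1 .. 1.0 in steps of 0.1.
#'
#' @return data.frame with columns `label` and `pt`.
#' @export
noise_level_grid <- function() {
  data.frame(label = paste0("NL_", 0:10), pt = seq(0, 1, by = 0.1),
             stringsAsFactors = FALSE)
}
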