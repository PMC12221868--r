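# shared generators for small in-code fixtures

tiny_reference <- function(n_genes = 60, k = 4, seed = 42) {
  withr::with_seed(seed, {
    vals <- matrix(rlnorm(n_genes * k, meanlog = 2, sdlog = 1),
                   nrow = n_genes,
                   dimnames = list(paste0("G", seq_len(n_genes)),
                                   paste0("CT", seq_len(k))))
    reference_profile(vals)
  })
}

tiny_sc <- function(n_genes = 40, types = c("A", "B", "C"),
                    cells_per_type = 15, seed = 7) {
  withr::with_seed(seed, {
    total <- length(types) * cells_per_type
    counts <- matrix(rpois(n_genes * total, lambda = 5), nrow = n_genes,
                     dimnames = list(paste0("G", seq_len(n_genes)),
                                     paste0("c", seq_len(total))))
    # give each type a distinct expression shift so profiles are separable
    for (t in seq_along(types)) {
      cols <- ((t - 1) * cells_per_type + 1):(t * cells_per_type)
      boost <- ((t - 1) * 10 + 1):(t * 10)
      counts[boost, cols] <- counts[boost, cols] + rpois(10 * cells_per_type, 20)
    }
    single_cell_dataset(counts,
                        cell_types = rep(types, each = cells_per_type))
  })
}

# independent single-window SSIM, coded separately from the package version
ssim_oracle <- function(x, y, c1 = 0.01^2, c2 = 0.03^2) {
  if (max(x) > 0) x <- x / max(x)
  if (max(y) > 0) y <- y / max(y)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# JS divergence through the entropy identity H(M) - (H(P) + H(Q))/2
js_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  H((p + q) / 2) - (H(p) + H(q)) / 2
}
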