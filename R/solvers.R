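# Simplex-constrained least squares via a primal active-set method.
#
# Solves min ||A w - y||^2  subject to  sum(w) = 1, w >= 0.
# Variables in the active set are pinned at zero; the free block is solved
# through the KKT system of the equality-constrained subproblem, and
# Lagrange multipliers of the pinned bounds decide which constraint to
# release. Small problems only (k = number of cell types), so dense solves
# are fine.
simplex_ls <- function(A, y, tol = 1e-9, max_iter = NULL) {
  k <- ncol(A)
  if (k == 1) return(1)
  max_iter <- max_iter %||% (50L * k)
  G <- crossprod(A)          # k x k
  b <- crossprod(A, y)       # k
  active <- rep(FALSE, k)    # TRUE = pinned at zero
  scale <- mean(diag(G))          # condition the KKT system on G's scale
  G <- G / scale
  b <- b / scale
  solve_free <- function(active) {
    f <- which(!active)
    kf <- length(f)
    ridge <- 0
    repeat {
      KKT <- rbind(cbind(2 * (G[f, f, drop = FALSE] + diag(ridge, kf)),
                         rep(1, kf)),
                   c(rep(1, kf), 0))
      rhs <- c(2 * b[f], 1)
      sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
      if (!is.null(sol)) break
      # singular free block: escalate a (relative) ridge until solvable
      ridge <- if (ridge == 0) 1e-12 else ridge * 100
      if (ridge > 1e-2) stop("simplex LS: free block numerically singular")
    }
    w <- numeric(k)
    w[f] <- sol[seq_len(kf)]
    list(w = w, lambda = sol[kf + 1])
  }
  sol <- solve_free(active)
  for (it in seq_len(max_iter)) {
    w <- sol$w
    if (min(w) < -tol) {
      # pin the most negative free variable
      cand <- which(!active & w < -tol)
      active[cand[which.min(w[cand])]] <- TRUE
      if (all(active)) stop("simplex LS: all variables pinned; no feasible solve")
      sol <- solve_free(active)
      next
    }
    w[w < 0] <- 0
    # KKT: multiplier of a pinned bound is grad_i + lambda; must be >= 0
    grad <- 2 * (G %*% w - b)
    mult <- grad + sol$lambda
    viol <- which(active & mult < -tol)
    if (!length(viol)) {
      w <- pmax(w, 0)
      return(w / sum(w))
    }
    active[viol[which.min(mult[viol])]] <- FALSE
    sol <- solve_free(active)
  }
  stop(sprintf("simplex LS did not converge in %d active-set iterations; residual %.3g",
               max_iter, sqrt(sum((A %*% pmax(sol$w, 0) - y)^2))))
}
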