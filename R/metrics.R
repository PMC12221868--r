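#' Evaluation metrics
#'
#' Seven scores compare predicted with true cell-type proportions:
#' Pearson correlation (PCC) and root mean square error (RMSE) for the
#' overall linear relationship; mean absolute percentage error (MAPE) and
#' its symmetric variant (sMAPE, each term bounded by 2 and tolerant of
#' zeros, hence its use for rare components); the structural similarity
#' index (SSIM) combining means, variances, and covariance of max-scaled
#' vectors; the Jensen-Shannon divergence (JS, base-2, range \[0, 1\]);
#' and a rank-based composite accuracy score (AS) that sums per-metric
#' method rankings.
#'
#' @name metrics
NULL

#' Metric configuration
#'
#' @param ssim_c1,ssim_c2 SSIM stabilizing constants; defaults 0.01^2 and
#'   0.03^2 (the standard single-window convention for data scaled to
#'   \[0, 1\]).
#' @param mape_epsilon truth entries at or below this are skipped by MAPE.
#' @param as_weights named weights for the composite accuracy score; the
#'   default gives PCC, RMSE, MAPE, and SSIM unit weight.
#' @return a `metric_config` list.
#' @export
metric_config <- function(ssim_c1 = 0.01^2, ssim_c2 = 0.03^2,
                          mape_epsilon = 1e-12,
                          as_weights = c(PCC = 1, RMSE = 1, MAPE = 1,
                                         SSIM = 1)) {
  if (any(as_weights < 0) || !any(as_weights > 0))
    stop("as_weights must be nonnegative with at least one positive")
  list(ssim_c1 = ssim_c1, ssim_c2 = ssim_c2, mape_epsilon = mape_epsilon,
       as_weights = as_weights)
}

#' Pearson correlation coefficient
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\]; NaN (with a warning) when either input
#'   has zero variance.
#' @export
metric_pcc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; PCC undefined")
    return(NaN)
  }
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Root mean square error
#' @param truth,pred numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
metric_rmse <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  sqrt(mean((truth - pred)^2))
}

#' Mean absolute percentage error
#'
#' Mean of `|truth - pred| / truth` over entries with `truth > eps`; near-
#' zero truths are skipped (they make the ratio explode, which is why the
#' rare-component protocol reports sMAPE instead).
#'
#' @param truth,pred numeric vectors of equal length.
#' @param eps skip threshold on the truth.
#' @return list-free scalar; attribute `n_skipped` counts skipped entries.
#' @export
metric_mape <- function(truth, pred, eps = 1e-12) {
  if (length(truth) != length(pred)) stop("length mismatch")
  use <- truth > eps
  if (!any(use)) {
    warning("all entries skipped (truth <= eps); MAPE undefined")
    return(structure(NaN, n_skipped = length(truth)))
  }
  structure(mean(abs(truth[use] - pred[use]) / truth[use]),
            n_skipped = sum(!use))
}

#' Symmetric mean absolute percentage error
#'
#' Mean of `2 |t - p| / (t + p)`; a term with `t + p = 0` contributes 0 by
#' convention. Each term is bounded by 2, so a zero prediction for a
#' present component scores exactly 2.
#'
#' @param truth,pred nonnegative numeric vectors of equal length.
#' @return scalar in \[0, 2\].
#' @export
metric_smape <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  if (any(truth < 0) || any(pred < 0)) stop("sMAPE requires nonnegative inputs")
  denom <- truth + pred
  term <- ifelse(denom == 0, 0, 2 * abs(truth - pred) / denom)
  mean(term)
}

#' Structural similarity index (single window)
#'
#' Each vector is scaled by its own maximum into \[0, 1\] (so the score is
#' scale-invariant), then the standard single-window SSIM with population
#' moments is returned:
#' `((2 mx my + C1)(2 cov + C2)) / ((mx^2 + my^2 + C1)(sx^2 + sy^2 + C2))`.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @param cfg a [metric_config()].
#' @return scalar in \[-1, 1\]; two all-zero inputs return 1 with a warning.
#' @export
metric_ssim <- function(x, y, cfg = metric_config()) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("SSIM requires nonnegative inputs")
  if (max(x) == 0 && max(y) == 0) {
    warning("both inputs all-zero; SSIM = 1 by convention")
    return(1)
  }
  if (max(x) > 0) x <- x / max(x)
  if (max(y) > 0) y <- y / max(y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)   # population moments
  cv <- mean((x - mx) * (y - my))
  ((2 * mx * my + cfg$ssim_c1) * (2 * cv + cfg$ssim_c2)) /
    ((mx^2 + my^2 + cfg$ssim_c1) * (vx + vy + cfg$ssim_c2))
}

#' Jensen-Shannon divergence (base 2)
#'
#' Inputs are normalized to probability distributions; the divergence is
#' `0.5 KL(P || M) + 0.5 KL(Q || M)` with `M = (P + Q)/2` and base-2 logs,
#' giving a symmetric score in \[0, 1\] (1 for disjoint supports).
#' `0 * log 0` terms are 0.
#'
#' @param p,q nonnegative numeric vectors of equal length with positive sum.
#' @return scalar in \[0, 1\].
#' @export
metric_js <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  if (any(p < 0) || any(q < 0)) stop("JS requires nonnegative inputs")
  if (sum(p) == 0 || sum(q) == 0) stop("zero-sum vector")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    use <- a > 0
    sum(a[use] * log2(a[use] / b[use]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Rank-based composite accuracy score
#'
#' Methods are ranked within each of PCC, RMSE, MAPE, and SSIM (rank 1 =
#' best: larger is better for PCC/SSIM, smaller for RMSE/MAPE; ties share
#' the mean rank). AS is the weighted sum of a method's four ranks, so it
#' depends on the metric values only through their within-metric ranks;
#' lower AS = better.
#'
#' @param per_method_metrics named list: method -> named numeric vector
#'   containing PCC, RMSE, MAPE, SSIM.
#' @param cfg a [metric_config()]; `as_weights` names select the metrics.
#' @return data.frame (method, AS, rank columns) sorted ascending by AS.
#' @export
accuracy_score <- function(per_method_metrics, cfg = metric_config()) {
  if (!length(per_method_metrics)) stop("need at least one method")
  methods <- names(per_method_metrics)
  wanted <- names(cfg$as_weights)
  for (m in methods) {
    miss <- setdiff(wanted, names(per_method_metrics[[m]]))
    if (length(miss))
      stop(sprintf("method %s is missing metric(s): %s", m,
                   paste(miss, collapse = ", ")))
  }
  higher_better <- c(PCC = TRUE, RMSE = FALSE, MAPE = FALSE, sMAPE = FALSE,
                     SSIM = TRUE, JS = FALSE)
  ranks <- sapply(wanted, function(met) {
    v <- vapply(per_method_metrics, function(x) x[[met]], numeric(1))
    if (isTRUE(higher_better[[met]])) v <- -v
    rank(v, ties.method = "average")
  })
  ranks <- matrix(ranks, nrow = length(methods),
                  dimnames = list(methods, wanted))
  as_val <- as.numeric(ranks %*% cfg$as_weights[wanted])
  out <- data.frame(method = methods, AS = as_val, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ranks))
  out[order(out$AS, out$method), , drop = FALSE]
}

#' Score a prediction against the ground truth
#'
#' Computes PCC, RMSE, MAPE, sMAPE, SSIM, and JS in one of three
#' aggregation modes: `"cell_type"` (each metric across samples, per cell
#' type -- the standard protocol view), `"sample"` (across cell types, per
#' sample), or `"overall"` (on the flattened matrices, reported under the
#' cell-type sentinel `"ALL"`).
#'
#' @param pred,truth `proportion_matrix` objects with identical ids.
#' @param by aggregation mode.
#' @param cfg a [metric_config()].
#' @param method,scenario,noise_level,replicate annotation carried into the
#'   output rows.
#' @return a [results_table()].
#' @export
evaluate_proportions <- function(pred, truth,
                                 by = c("cell_type", "sample", "overall"),
                                 cfg = metric_config(), method = "method",
                                 scenario = "scenario", noise_level = "NA",
                                 replicate = 1L) {
  by <- match.arg(by)
  stopifnot(inherits(pred, "proportion_matrix"),
            inherits(truth, "proportion_matrix"))
  if (!identical(dimnames(truth$values), dimnames(pred$values))) {
    if (!setequal(rownames(pred$values), rownames(truth$values)) ||
        !setequal(colnames(pred$values), colnames(truth$values)))
      stop("id mismatch between prediction and truth")
    pred <- proportion_matrix(
      pred$values[rownames(truth$values), colnames(truth$values)])
  }
  score_vec <- function(t, p) c(
    PCC = suppressWarnings(metric_pcc(t, p)),
    RMSE = metric_rmse(t, p),
    MAPE = as.numeric(suppressWarnings(metric_mape(t, p, cfg$mape_epsilon))),
    sMAPE = metric_smape(t, p),
    SSIM = suppressWarnings(metric_ssim(t, p, cfg)),
    JS = metric_js(t, p))
  units <- switch(by,
    cell_type = rownames(truth$values),
    sample = colnames(truth$values),
    overall = "ALL")
  rows <- lapply(units, function(u) {
    t <- switch(by, cell_type = truth$values[u, ],
                sample = truth$values[, u],
                overall = as.numeric(truth$values))
    p <- switch(by, cell_type = pred$values[u, ],
                sample = pred$values[, u],
                overall = as.numeric(pred$values))
    s <- score_vec(t, p)
    results_table(method = method, scenario = scenario,
                  noise_level = noise_level, cell_type = u,
                  metric = names(s), value = unname(s),
                  replicate = replicate)
  })
  do.call(bind_results, rows)
}
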